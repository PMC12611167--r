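# ZINB reconstruction likelihood, spatial regularization constraint, and
# the combined training objective.

EPS <- 1e-10
MU_CLIP <- 12  # bound on the log-mean pre-activation (exp(12) ~ 1.6e5)

# ZINB head parameters: three parallel affine maps from the latent space
init_zinb_params <- function(d, m_genes, seed = 0L, w_scale = 0.1) {
  with_seed(seed, {
    s <- w_scale * sqrt(2 / (d + m_genes))
    list(W_pi = matrix(stats::rnorm(d * m_genes, sd = s), d, m_genes),
         b_pi = numeric(m_genes),
         W_mu = matrix(stats::rnorm(d * m_genes, sd = s), d, m_genes),
         b_mu = numeric(m_genes),
         W_theta = matrix(stats::rnorm(d * m_genes, sd = s), d, m_genes),
         b_theta = numeric(m_genes))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' ZINB decoder: map a latent embedding to per-entry ZINB parameters
#'
#' Three parallel affine heads on the latent matrix `Z` produce the
#' zero-inflation probability (logistic link), the mean (exponential link
#' with a bounded pre-activation), and the dispersion (softplus link).
#'
#' @param Z N x d latent matrix.
#' @param weights Head parameters (`W_pi`, `b_pi`, `W_mu`, `b_mu`,
#'   `W_theta`, `b_theta`); `NULL` initializes for `m_genes` outputs.
#' @param m_genes Number of genes when `weights` is `NULL`.
#' @param seed Seed for random initialization.
#' @return List of class `zinb_params` with N x M matrices `pi` (in (0,1)),
#'   `mu` (> 0), `theta` (> 0).
#' @export
zinb_decode <- function(Z, weights = NULL, m_genes = NULL, seed = 0L) {
  Z <- as.matrix(Z)
  if (is.null(weights)) {
    if (is.null(m_genes)) stop("m_genes required when weights is NULL")
    weights <- init_zinb_params(ncol(Z), m_genes, seed = seed)
  }
  fw <- zinb_decode_forward(Z, weights)
  out <- structure(list(pi = fw$pi, mu = fw$mu, theta = fw$theta),
                   class = "zinb_params")
  for (nm in c("pi", "mu", "theta"))
    if (!all(is.finite(out[[nm]])))
      stop("non-finite values in ZINB head '", nm, "'")
  out
}

zinb_decode_forward <- function(Z, w) {
  n <- nrow(Z)
  pre_pi <- Z %*% w$W_pi + rep(w$b_pi, each = n)
  pre_mu <- Z %*% w$W_mu + rep(w$b_mu, each = n)
  pre_th <- Z %*% w$W_theta + rep(w$b_theta, each = n)
  mu_clipped <- pmin(pmax(pre_mu, -MU_CLIP), MU_CLIP)
  list(pi = sigmoid(pre_pi),
       mu = exp(mu_clipped),
       theta = softplus(pre_th) + EPS,
       pre_pi = pre_pi, pre_mu = pre_mu, pre_th = pre_th)
}

# chain gradients wrt (pi, mu, theta) back to Z and the head weights
zinb_decode_backward <- function(fw, Z, w, d_pi, d_mu, d_theta) {
  d_pre_pi <- d_pi * fw$pi * (1 - fw$pi)
  in_range <- (fw$pre_mu > -MU_CLIP & fw$pre_mu < MU_CLIP) * 1
  d_pre_mu <- d_mu * fw$mu * in_range
  d_pre_th <- d_theta * sigmoid(fw$pre_th)
  dZ <- d_pre_pi %*% t(w$W_pi) + d_pre_mu %*% t(w$W_mu) +
    d_pre_th %*% t(w$W_theta)
  list(dZ = dZ,
       dParams = list(W_pi = crossprod(Z, d_pre_pi),
                      b_pi = colSums(d_pre_pi),
                      W_mu = crossprod(Z, d_pre_mu),
                      b_mu = colSums(d_pre_mu),
                      W_theta = crossprod(Z, d_pre_th),
                      b_theta = colSums(d_pre_th)))
}

#' Zero-inflated negative binomial negative log-likelihood
#'
#' The canonical ZINB mixture: `P(0) = pi + (1 - pi) NB(0 | mu, theta)`
#' and `P(x > 0) = (1 - pi) NB(x | mu, theta)` with the NB kernel
#' `Gamma(x + theta) / (Gamma(x + 1) Gamma(theta)) *
#' (theta / (theta + mu))^theta (mu / (theta + mu))^x`.
#' Returns the mean of `-log P` over all entries, computed in log space
#' with epsilon guards.
#'
#' @param X N x M matrix of non-negative counts (rounded normalized values
#'   are accepted; non-integer input is used as-is in the continuous
#'   extension of the kernel).
#' @param params A `zinb_params` object (or list with `pi`, `mu`, `theta`).
#' @return Non-negative scalar mean NLL.
#' @export
zinb_nll <- function(X, params) {
  zinb_nll_fb(X, params$pi, params$mu, params$theta)$loss
}

# forward + backward via the fused C++ kernel (src/zinb.cpp)
zinb_nll_fb <- function(X, pi, mu, theta) {
  X <- as.matrix(X)
  pi <- as.matrix(pi); mu <- as.matrix(mu); theta <- as.matrix(theta)
  loss <- .zinb_nll_grad_cpp(X, pi, mu, theta, FALSE)$loss
  grad <- function() {
    g <- .zinb_nll_grad_cpp(X, pi, mu, theta, TRUE)
    list(d_pi = g$d_pi, d_mu = g$d_mu, d_theta = g$d_theta)
  }
  list(loss = loss, grad = grad)
}

#' Build a spatial regularization specification
#'
#' Collects each spot's neighbour set (default: the union of the KNN and
#' radius graphs) and samples a fixed set of non-neighbour negatives per
#' spot.
#'
#' @param A_union Binary symmetric adjacency whose nonzeros define the
#'   neighbour pairs.
#' @param n_neg Negative samples per spot (default 5).
#' @param seed Seed for the negative sampling.
#' @return List with integer matrices `pos` (npos x 2) and `neg`
#'   (nneg x 2) of index pairs.
#' @export
spatial_reg_spec <- function(A_union, n_neg = 5L, seed = 0L) {
  n <- nrow(A_union)
  pos <- which(upper.tri(A_union) & A_union != 0, arr.ind = TRUE)
  colnames(pos) <- NULL
  neg <- with_seed(seed, {
    out <- matrix(0L, 0L, 2L)
    for (i in seq_len(n)) {
      non <- which(A_union[i, ] == 0)
      non <- non[non != i]
      if (length(non) == 0L) next
      j <- non[sample.int(length(non), size = min(n_neg, length(non)))]
      out <- rbind(out, cbind(i, j))
    }
    out
  })
  if (nrow(pos) == 0L) stop("no neighbour pairs: empty spatial graphs")
  list(pos = pos, neg = neg)
}

#' Spatial regularization constraint
#'
#' Pulls spatially neighbouring spots together and pushes sampled
#' non-neighbours apart in the latent space:
#' `-1/2 [ mean_pos log(sigma(cos_ij)) + mean_neg log(1 - sigma(cos_ij)) ]`
#' with `cos` the cosine similarity of embedding rows and `sigma` the
#' logistic function. Strictly positive for finite embeddings.
#'
#' @param H N x d embedding.
#' @param spec Pair specification from [spatial_reg_spec()].
#' @return Positive scalar.
#' @export
spatial_reg_loss <- function(H, spec) {
  spatial_reg_fb(H, spec)$loss
}

spatial_reg_fb <- function(H, spec) {
  H <- as.matrix(H)
  rn <- row_normalize(H)
  Ht <- rn$Zt
  sp <- rowSums(Ht[spec$pos[, 1], , drop = FALSE] *
                  Ht[spec$pos[, 2], , drop = FALSE])
  sn <- rowSums(Ht[spec$neg[, 1], , drop = FALSE] *
                  Ht[spec$neg[, 2], , drop = FALSE])
  sig_p <- sigmoid(sp); sig_n <- sigmoid(sn)
  loss <- -0.5 * (mean(log(sig_p + EPS)) + mean(log(1 - sig_n + EPS)))
  grad <- function() {
    d_sp <- -0.5 * (1 - sig_p) / length(sp)
    d_sn <- 0.5 * sig_n / length(sn)
    # scatter-add gradients of the pair dot products on normalized rows
    ii <- c(spec$pos[, 1], spec$neg[, 1])
    jj <- c(spec$pos[, 2], spec$neg[, 2])
    w <- c(d_sp, d_sn)
    dHt <- matrix(0, nrow(Ht), ncol(Ht))
    a1 <- rowsum(w * Ht[jj, , drop = FALSE], ii)
    r1 <- as.integer(rownames(a1))
    dHt[r1, ] <- dHt[r1, ] + a1
    a2 <- rowsum(w * Ht[ii, , drop = FALSE], jj)
    r2 <- as.integer(rownames(a2))
    dHt[r2, ] <- dHt[r2, ] + a2
    row_normalize_backward(dHt, H, rn)
  }
  list(loss = loss, grad = grad)
}

#' Combined training objective
#'
#' Weighted sum of the four loss terms:
#' `lambda[1] L_zinb + lambda[2] L_com + lambda[3] L_con + lambda[4] L_reg`.
#'
#' @param L_zinb,L_com,L_con,L_reg Scalar loss values.
#' @param lambda Four non-negative weights (default all 1).
#' @return Scalar total loss.
#' @export
total_loss <- function(L_zinb, L_com, L_con, L_reg, lambda = c(1, 1, 1, 1)) {
  stopifnot(length(lambda) == 4, all(lambda >= 0))
  lambda[1] * L_zinb + lambda[2] * L_com + lambda[3] * L_con +
    lambda[4] * L_reg
}
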