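# Multi-view weighted-fusion GCN encoder: spatial convolution over the two
# spatial graphs, feature convolution over the feature graph, shared-weight
# co-convolution over all three, cross-view Gram consistency, and per-spot
# view-level attention fusion.

#' Spatial convolution over the two spatial graphs
#'
#' Runs stacked ReLU GCN layers on the KNN graph and the radius graph with
#' separate weights, and returns both embeddings plus their elementwise
#' mean (the joint spatial embedding).
#'
#' @param X N x M input features (clean expression).
#' @param A_knn_norm,A_radius_norm Normalized adjacencies.
#' @param weights List with stacks `s` and `s_a` (from the trainer); `NULL`
#'   initializes randomly.
#' @param dims Hidden layer widths used when `weights` is `NULL`.
#' @param seed Seed for random initialization.
#' @return List `Zs`, `Zs_a`, `Zs_joint`, each N x d.
#' @export
spatial_conv <- function(X, A_knn_norm, A_radius_norm, weights = NULL,
                         dims = c(64L, 64L), seed = 0L) {
  X <- as.matrix(X)
  if (is.null(weights)) {
    weights <- list(
      s = init_stack(c(ncol(X), dims), "relu", seed),
      s_a = init_stack(c(ncol(X), dims), "relu", seed + 1L))
  }
  fs <- stack_forward(X, A_knn_norm, weights$s)
  fa <- stack_forward(X, A_radius_norm, weights$s_a)
  Zs <- fs$H[[length(fs$H)]]
  Zs_a <- fa$H[[length(fa$H)]]
  list(Zs = Zs, Zs_a = Zs_a, Zs_joint = (Zs + Zs_a) / 2)
}

#' Feature convolution over the feature graph
#'
#' Stacked ReLU GCN layers on the cosine feature graph. The input is, by
#' default, the latent representation produced by the contrastive encoder
#' (see the package vignette for the rationale and the `corrupted`
#' alternative).
#'
#' @param X_in N x d_in input features.
#' @param A_f_norm Normalized feature-graph adjacency.
#' @param weights A stack (list `W`, `b`, `act`); `NULL` initializes.
#' @param dims Hidden widths when `weights` is `NULL`.
#' @param seed Seed for random initialization.
#' @return N x d embedding `Zf`.
#' @export
feature_conv <- function(X_in, A_f_norm, weights = NULL,
                         dims = c(64L, 64L), seed = 0L) {
  X_in <- as.matrix(X_in)
  if (is.null(weights))
    weights <- init_stack(c(ncol(X_in), dims), "relu", seed)
  f <- stack_forward(X_in, A_f_norm, weights)
  f$H[[length(f$H)]]
}

#' Shared-weight co-convolution over all three graphs
#'
#' One weight set is applied to the KNN, radius, and feature graphs
#' (parameter sharing extracts a co-embedding of expression and spatial
#' structure); the joint embedding is the elementwise mean of the three
#' branch outputs.
#'
#' @param X_in N x d_in input features (same input to all branches).
#' @param A_knn_norm,A_radius_norm,A_f_norm Normalized adjacencies.
#' @param shared_weights A single stack applied to every branch; `NULL`
#'   initializes.
#' @param dims Hidden widths when `shared_weights` is `NULL`.
#' @param seed Seed for random initialization.
#' @return List `Zsc`, `Zs_ac`, `Zfc`, `Zc_joint`.
#' @export
co_conv <- function(X_in, A_knn_norm, A_radius_norm, A_f_norm,
                    shared_weights = NULL, dims = c(64L, 64L), seed = 0L) {
  X_in <- as.matrix(X_in)
  if (is.null(shared_weights))
    shared_weights <- init_stack(c(ncol(X_in), dims), "relu", seed)
  f1 <- stack_forward(X_in, A_knn_norm, shared_weights)
  f2 <- stack_forward(X_in, A_radius_norm, shared_weights)
  f3 <- stack_forward(X_in, A_f_norm, shared_weights)
  Zsc <- f1$H[[length(f1$H)]]
  Zs_ac <- f2$H[[length(f2$H)]]
  Zfc <- f3$H[[length(f3$H)]]
  list(Zsc = Zsc, Zs_ac = Zs_ac, Zfc = Zfc,
       Zc_joint = (Zsc + Zs_ac + Zfc) / 3)
}

# row-L2 normalization with backward
row_normalize <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm == 0))
    stop("zero-norm row(s) in embedding: ",
         paste(which(nrm == 0), collapse = ", "))
  list(Zt = Z / nrm, nrm = nrm)
}

row_normalize_backward <- function(dZt, Z, rn) {
  # z~ = z/|z|; dz = (dz~ - (z~ . dz~) z~)/|z|
  proj <- rowSums(rn$Zt * dZt)
  (dZt - proj * rn$Zt) / rn$nrm
}

#' Cross-view consistency loss
#'
#' Row-normalizes each co-embedding, forms the N x N Gram (cosine
#' similarity) matrices, and penalizes squared Frobenius differences:
#' `||G_sc - G_s_ac||^2 + ||G_sc - G_fc||^2`. Zero iff the normalized Gram
#' matrices coincide.
#'
#' @param Zsc,Zs_ac,Zfc N x d co-embeddings.
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(Zsc, Zs_ac, Zfc) {
  consistency_loss_fb(Zsc, Zs_ac, Zfc)$loss
}

consistency_loss_fb <- function(Zsc, Zs_ac, Zfc) {
  fb <- consistency_list_fb(list(Zsc, Zs_ac, Zfc))
  list(loss = fb$loss, grad = function() {
    g <- fb$grad()
    list(dZsc = g[[1L]], dZs_ac = g[[2L]], dZfc = g[[3L]])
  })
}

# attention parameter block: shared two-layer scoring map + projection
init_attention_params <- function(d, h = 32L, h2 = 16L, seed = 0L) {
  with_seed(seed, {
    list(W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / (d + h))), d, h),
         b1 = numeric(h),
         W2 = matrix(stats::rnorm(h * h2, sd = sqrt(2 / (h + h2))), h, h2),
         b2 = numeric(h2),
         v = stats::rnorm(h2, sd = sqrt(1 / h2)))
  })
}

#' View-level attention fusion
#'
#' Scores each view embedding per spot with a shared two-layer map
#' (`v' (W2' tanh(W1' z + b1) + b2)`), softmaxes the three scores across
#' views so each spot's weights sum to one, and returns the weighted sum
#' of the views. With `equal_weights = TRUE` the learned weights are
#' replaced by exact (1/3, 1/3, 1/3) mean fusion (the attention-ablation
#' mode).
#'
#' @param Zs_joint,Zc_joint,Zf N x d view embeddings.
#' @param params Attention parameters from `init_attention_params`; `NULL`
#'   initializes with `seed`.
#' @param equal_weights Use fixed 1/3 weights instead of learned scores.
#' @param seed Seed for random initialization.
#' @return List `weights` (N x 3, rows sum to 1) and `Z` (N x d fusion).
#' @export
view_attention <- function(Zs_joint, Zc_joint, Zf, params = NULL,
                           equal_weights = FALSE, seed = 0L) {
  if (is.null(params))
    params <- init_attention_params(ncol(Zs_joint), seed = seed)
  fw <- attention_forward(list(Zs_joint, Zc_joint, Zf), params,
                          equal_weights)
  list(weights = fw$Wt, Z = fw$Z)
}

# forward over a list of V >= 2 views (ablations may drop a view upstream;
# fusion always sees the three canonical views in the full model)
attention_forward <- function(views, params, equal_weights = FALSE) {
  nv <- length(views)
  n <- nrow(views[[1L]])
  if (equal_weights) {
    Wt <- matrix(1 / nv, n, nv)
    Z <- Reduce(`+`, views) / nv
    return(list(Z = Z, Wt = Wt, views = views, equal = TRUE))
  }
  U <- vector("list", nv); S <- vector("list", nv)
  E <- matrix(0, n, nv)
  for (v in seq_len(nv)) {
    pre <- sweep(views[[v]] %*% params$W1, 2, params$b1, `+`)
    U[[v]] <- tanh(pre)
    S[[v]] <- sweep(U[[v]] %*% params$W2, 2, params$b2, `+`)
    E[, v] <- S[[v]] %*% params$v
  }
  Emax <- apply(E, 1, max)
  We <- exp(E - Emax)
  Wt <- We / rowSums(We)
  Z <- matrix(0, n, ncol(views[[1L]]))
  for (v in seq_len(nv)) Z <- Z + Wt[, v] * views[[v]]
  list(Z = Z, Wt = Wt, U = U, S = S, E = E, views = views, equal = FALSE)
}

# backward through attention fusion given dZ; returns per-view gradients
# and parameter gradients
attention_backward <- function(fw, params, dZ) {
  views <- fw$views
  nv <- length(views)
  n <- nrow(dZ)
  dViews <- vector("list", nv)
  if (isTRUE(fw$equal)) {
    for (v in seq_len(nv)) dViews[[v]] <- dZ / nv
    return(list(dViews = dViews, dParams = NULL))
  }
  dWt <- matrix(0, n, nv)
  for (v in seq_len(nv)) {
    dViews[[v]] <- fw$Wt[, v] * dZ
    dWt[, v] <- rowSums(dZ * views[[v]])
  }
  # softmax backward per row
  dE <- fw$Wt * (dWt - rowSums(fw$Wt * dWt))
  dW1 <- params$W1 * 0; db1 <- params$b1 * 0
  dW2 <- params$W2 * 0; db2 <- params$b2 * 0
  dv <- params$v * 0
  for (v in seq_len(nv)) {
    dS <- outer(dE[, v], params$v)
    dv <- dv + crossprod(fw$S[[v]], dE[, v])[, 1L]
    dU <- dS %*% t(params$W2)
    dW2 <- dW2 + crossprod(fw$U[[v]], dS)
    db2 <- db2 + colSums(dS)
    dPre <- dU * (1 - fw$U[[v]]^2)
    dW1 <- dW1 + crossprod(views[[v]], dPre)
    db1 <- db1 + colSums(dPre)
    dViews[[v]] <- dViews[[v]] + dPre %*% t(params$W1)
  }
  list(dViews = dViews,
       dParams = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, v = dv))
}
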