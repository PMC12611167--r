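# Graph-embedded contrastive encoder: feature corruption, GCN encoder,
# GDN decoder, and the triplet contrastive loss on latent representations.

#' Corrupt an expression matrix for contrastive learning
#'
#' Default corruption permutes the rows of `X` (every node receives another
#' node's full expression vector) while the neighbourhood graph is left
#' untouched — the classic topology-preserving corruption of graph
#' contrastive learning. `feature_mask` instead zeroes a random 20% of the
#' columns. The multiset of rows (mode `row_shuffle`) is preserved exactly.
#'
#' @param X N x M matrix.
#' @param seed Integer seed; the permutation is reproducible.
#' @param mode `"row_shuffle"` (default) or `"feature_mask"`.
#' @return A corrupted copy of `X`.
#' @export
corrupt_features <- function(X, seed = 0L, mode = c("row_shuffle",
                                                    "feature_mask")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (mode == "row_shuffle") {
    if (n == 1L) return(X)
    p <- with_seed(seed, sample.int(n))
    X[p, , drop = FALSE]
  } else {
    m <- ncol(X)
    drop <- with_seed(seed, sample.int(m, size = max(1L, round(0.2 * m))))
    X[, drop] <- 0
    X
  }
}

# row-wise cosine similarity between two matrices, with backward pass
row_cosine <- function(U, V) {
  nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
  if (any(nu == 0) || any(nv == 0))
    stop("zero-norm row in cosine similarity: spot index ",
         paste(which(nu == 0 | nv == 0), collapse = ", "))
  s <- rowSums(U * V) / (nu * nv)
  list(s = s, nu = nu, nv = nv)
}

# gradients of per-row cosine wrt U and V given upstream ds (length N)
row_cosine_backward <- function(ds, U, V, cc) {
  dU <- ds * (V / (cc$nu * cc$nv) - cc$s * U / cc$nu^2)
  dV <- ds * (U / (cc$nu * cc$nv) - cc$s * V / cc$nv^2)
  list(dU = dU, dV = dV)
}

#' Contrastive (triplet) loss on latent representations
#'
#' Per node, cosine similarities to a positive and a negative sample are
#' combined into the hinged triplet objective
#' `mean(max(0, alpha - s_pos + s_neg))`, which pulls the positive pair
#' together and pushes the negative pair apart with margin `alpha`. The
#' `literal` form `mean(s_pos - s_neg + alpha)` (no hinge; positive
#' similarity *penalized* when minimized) is retained for audit only.
#'
#' @param h_orig N x d anchor embeddings.
#' @param h_pos N x d positive embeddings.
#' @param h_neg N x d negative embeddings.
#' @param alpha Non-negative margin (default 0.5).
#' @param form `"hinge"` (default) or `"literal"`.
#' @return Scalar loss (non-negative for `"hinge"`).
#' @export
contrastive_loss <- function(h_orig, h_pos, h_neg, alpha = 0.5,
                             form = c("hinge", "literal")) {
  form <- match.arg(form)
  contrastive_loss_fb(h_orig, h_pos, h_neg, alpha, form)$loss
}

# forward + backward for the contrastive loss
contrastive_loss_fb <- function(h_orig, h_pos, h_neg, alpha, form = "hinge") {
  stopifnot(alpha >= 0)
  n <- nrow(h_orig)
  cp <- row_cosine(h_orig, h_pos)
  cn <- row_cosine(h_orig, h_neg)
  margin <- alpha - cp$s + cn$s
  if (form == "hinge") {
    active <- (margin > 0) * 1
    loss <- mean(pmax(margin, 0))
    d_sp <- -active / n
    d_sn <- active / n
  } else {
    loss <- mean(cp$s - cn$s) + alpha
    d_sp <- rep(1 / n, n)
    d_sn <- rep(-1 / n, n)
  }
  grad <- function() {
    gp <- row_cosine_backward(d_sp, h_orig, h_pos, cp)
    gn <- row_cosine_backward(d_sn, h_orig, h_neg, cn)
    list(d_orig = gp$dU + gn$dU, d_pos = gp$dV, d_neg = gn$dV)
  }
  list(loss = loss, grad = grad)
}

# parameter block for the contrastive encoder/decoder (two streams, per the
# two weight sets the model keeps for X and its corrupted copy)
init_contrastive_params <- function(m_genes, dims = c(128L, 64L), seed = 0L) {
  enc_dims <- c(m_genes, dims)
  dec_dims <- rev(enc_dims)
  L <- length(dims)
  enc_act <- c(rep("relu", L - 1L), "identity")
  dec_act <- c(rep("relu", L - 1L), "identity")
  list(
    enc0 = init_stack(enc_dims, enc_act, seed),
    enc1 = init_stack(enc_dims, enc_act, seed + 1L),
    dec0 = init_stack(dec_dims, dec_act, seed + 2L),
    dec1 = init_stack(dec_dims, dec_act, seed + 3L))
}

#' Run the graph-embedded contrastive encoder
#'
#' Encodes the clean matrix `X` and its corrupted copy `X_corrupt` with
#' GCN stacks over the feature graph, reconstructs both with GDN decoder
#' stacks, and computes the contrastive loss with anchor = clean latent,
#' positive = the anchor's decoder-roundtrip latent (the clean
#' reconstruction re-encoded; a self-consistency target), and negative =
#' the corrupted-view latent.
#'
#' @param X N x M clean feature matrix.
#' @param X_corrupt N x M corrupted matrix from [corrupt_features()].
#' @param A_f_norm Normalized feature-graph adjacency.
#' @param params Parameter block from the trainer (encoder/decoder stacks);
#'   `NULL` initializes randomly with `seed`.
#' @param alpha Contrastive margin.
#' @param form Loss form, see [contrastive_loss()].
#' @param dims Encoder layer widths when `params` is `NULL`.
#' @param seed Seed for random initialization.
#' @return List with `H_orig`, `H_aug` (N x d latents), `recon_orig`,
#'   `recon_aug` (N x M reconstructions), and the scalar `L_com`.
#' @export
run_contrastive_encoder <- function(X, X_corrupt, A_f_norm, params = NULL,
                                    alpha = 0.5, form = "hinge",
                                    dims = c(128L, 64L), seed = 0L) {
  X <- as.matrix(X); X_corrupt <- as.matrix(X_corrupt)
  if (is.null(params))
    params <- init_contrastive_params(ncol(X), dims = dims, seed = seed)
  fw <- contrastive_forward(X, X_corrupt, A_f_norm, params, alpha, form)
  list(H_orig = fw$h0, H_aug = fw$h1,
       recon_orig = fw$r0, recon_aug = fw$r1, L_com = fw$L_com)
}

# full forward pass of the contrastive block, caching everything backward
# needs. P_d is the deconvolution operator built once from A_f_norm.
# recon_aug feeds no loss, so the trainer skips the corrupted-stream
# decoder (need_recon_aug = FALSE); the user-facing op computes it.
contrastive_forward <- function(X, Xc, A_f_norm, params, alpha,
                                form = "hinge", need_recon_aug = TRUE) {
  P_d <- gdn_operator(A_f_norm)
  f_enc0 <- stack_forward(X, A_f_norm, params$enc0)
  f_enc1 <- stack_forward(Xc, A_f_norm, params$enc1)
  h0 <- f_enc0$H[[length(f_enc0$H)]]
  h1 <- f_enc1$H[[length(f_enc1$H)]]
  f_dec0 <- stack_forward(h0, P_d, params$dec0)
  f_dec1 <- if (need_recon_aug) stack_forward(h1, P_d, params$dec1)
  r0 <- f_dec0$H[[length(f_dec0$H)]]
  r1 <- if (need_recon_aug) f_dec1$H[[length(f_dec1$H)]]
  # positive: clean reconstruction re-encoded through the clean encoder
  f_enc0p <- stack_forward(r0, A_f_norm, params$enc0)
  p0 <- f_enc0p$H[[length(f_enc0p$H)]]
  cl <- contrastive_loss_fb(h0, p0, h1, alpha, form)
  list(h0 = h0, h1 = h1, p0 = p0, r0 = r0, r1 = r1,
       L_com = cl$loss, cl = cl,
       f_enc0 = f_enc0, f_enc1 = f_enc1, f_dec0 = f_dec0, f_dec1 = f_dec1,
       f_enc0p = f_enc0p, P_d = P_d)
}

# backward through the contrastive block.
#   d_h0_extra / d_h1_extra: gradients flowing into the latents from
#   downstream consumers (the multi-view encoder), may be NULL.
#   scale: multiplier on L_com (the loss weight lambda).
# Returns gradients for the four stacks plus dX / dXc.
contrastive_backward <- function(fw, X, Xc, A_f_norm, params, scale = 1,
                                 d_h0_extra = NULL, d_h1_extra = NULL) {
  g <- fw$cl$grad()
  d_h0 <- scale * g$d_orig
  d_p0 <- scale * g$d_pos
  d_h1 <- scale * g$d_neg
  if (!is.null(d_h1_extra)) d_h1 <- d_h1 + d_h1_extra
  # positive branch: back through enc0 applied to r0, then through dec0
  bk_enc0p <- stack_backward(fw$f_enc0p, A_f_norm, params$enc0, d_p0)
  bk_dec0 <- stack_backward(fw$f_dec0, fw$P_d, params$dec0, bk_enc0p$dH0)
  d_h0 <- d_h0 + bk_dec0$dH0
  if (!is.null(d_h0_extra)) d_h0 <- d_h0 + d_h0_extra
  bk_enc0 <- stack_backward(fw$f_enc0, A_f_norm, params$enc0, d_h0)
  bk_enc1 <- stack_backward(fw$f_enc1, A_f_norm, params$enc1, d_h1)
  list(
    enc0 = add_stack_grads(bk_enc0p[c("dW", "db")], bk_enc0[c("dW", "db")]),
    enc1 = bk_enc1[c("dW", "db")],
    dec0 = bk_dec0[c("dW", "db")],
    dec1 = zero_like_stack(params$dec1),  # recon_aug feeds no loss
    dX = bk_enc0$dH0, dXc = bk_enc1$dH0)
}
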