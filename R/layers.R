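# Graph-convolution layer primitives with hand-derived backpropagation.
# A "stack" is list(W = list, b = list, act = character); a layer computes
# act(P %*% H %*% W + b) where P is the propagation operator: the
# symmetrically normalized adjacency for convolution (p_c = I - L) and its
# first-order Neumann inverse 2I - A_norm for deconvolution (p_d = I + L).

act_fun <- function(x, act) {
  switch(act,
         relu = x * (x > 0),
         identity = x,
         tanh = tanh(x),
         stop("unknown activation: ", act))
}

act_grad <- function(pre, act) {
  switch(act,
         relu = (pre > 0) * 1,
         identity = array(1, dim = dim(pre)),
         tanh = 1 - tanh(pre)^2,
         stop("unknown activation: ", act))
}

#' Graph convolution layer
#'
#' Computes `activation(A_norm %*% H %*% W + b)`, the standard GCN
#' propagation rule with the self-loop-normalized adjacency as operator.
#'
#' @param H N x d input features.
#' @param A_norm N x N normalized adjacency (see [normalize_adjacency()]).
#' @param W d x d' weight matrix.
#' @param b Length-d' bias vector.
#' @param activation `"relu"`, `"identity"`, or `"tanh"`.
#' @return N x d' output features.
#' @export
gcn_layer <- function(H, A_norm, W, b = NULL, activation = "relu") {
  layer_forward(H, A_norm, W, b, activation)$out
}

#' Graph deconvolution layer
#'
#' Same contract as [gcn_layer()] but with the deconvolution operator
#' `2I - A_norm` (the first-order inverse of the convolution smoothing
#' filter), used by the decoder to undo over-smoothing.
#'
#' @inheritParams gcn_layer
#' @return N x d' output features.
#' @export
gdn_layer <- function(H, A_norm, W, b = NULL, activation = "relu") {
  P <- gdn_operator(A_norm)
  layer_forward(H, P, W, b, activation)$out
}

# deconvolution propagation operator p_d = I + L = 2I - A_norm
# (works for base and sparse Matrix adjacencies)
gdn_operator <- function(A_norm) {
  P <- -A_norm
  Matrix::diag(P) <- Matrix::diag(P) + 2
  P
}

# one layer, keeping the pre-activation for backprop; P may be a base
# matrix or a sparse Matrix (training uses sparse adjacencies)
layer_forward <- function(H, P, W, b, act) {
  H <- as.matrix(H)
  if (nrow(P) != nrow(H)) stop("operator/feature shape mismatch: ",
                               nrow(P), " vs ", nrow(H))
  if (ncol(H) != nrow(W)) stop("feature/weight shape mismatch: ",
                               ncol(H), " vs ", nrow(W))
  pre <- as.matrix(P %*% H) %*% W
  if (!is.null(b) && any(b != 0))
    pre <- pre + rep(b, each = nrow(pre))
  list(out = act_fun(pre, act), pre = pre)
}

# backward through one layer given upstream gradient dOut.
# pre = P H W + b with P symmetric:
#   dW = H^T (P dPre), db = colSums(dPre), dH = P dPre W^T
layer_backward <- function(dOut, H, P, W, pre, act) {
  dPre <- dOut * act_grad(pre, act)
  PdPre <- as.matrix(P %*% dPre)
  list(dW = crossprod(H, PdPre),
       db = colSums(dPre),
       dH = PdPre %*% t(W))
}

# forward through a stack of layers over a fixed operator P
stack_forward <- function(H0, P, stack) {
  L <- length(stack$W)
  H <- vector("list", L + 1L)
  pre <- vector("list", L)
  H[[1L]] <- as.matrix(H0)
  for (l in seq_len(L)) {
    f <- layer_forward(H[[l]], P, stack$W[[l]], stack$b[[l]], stack$act[[l]])
    H[[l + 1L]] <- f$out
    pre[[l]] <- f$pre
  }
  list(H = H, pre = pre)
}

# backward through a stack; returns per-layer gradients and dH0
stack_backward <- function(fw, P, stack, dOut) {
  L <- length(stack$W)
  dW <- vector("list", L); db <- vector("list", L)
  d <- dOut
  for (l in rev(seq_len(L))) {
    bk <- layer_backward(d, fw$H[[l]], P, stack$W[[l]], fw$pre[[l]],
                         stack$act[[l]])
    dW[[l]] <- bk$dW
    db[[l]] <- bk$db
    d <- bk$dH
  }
  list(dW = dW, db = db, dH0 = d)
}

# Glorot-scaled random stack initializer
init_stack <- function(dims, act, seed, w_scale = 1) {
  L <- length(dims) - 1L
  if (length(act) == 1L) act <- rep(act, L)
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      s <- w_scale * sqrt(2 / (dims[l] + dims[l + 1L]))
      matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = s),
             dims[l], dims[l + 1L])
    })
    b <- lapply(seq_len(L), function(l) numeric(dims[l + 1L]))
    list(W = W, b = b, act = act)
  })
}

# zero-filled gradient container matching a stack
zero_like_stack <- function(stack) {
  list(dW = lapply(stack$W, function(w) w * 0),
       db = lapply(stack$b, function(b) b * 0))
}

add_stack_grads <- function(g1, g2) {
  list(dW = Map(`+`, g1$dW, g2$dW), db = Map(`+`, g1$db, g2$db))
}
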