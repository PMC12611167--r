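#' Mutual K-nearest-neighbour spatial adjacency
#'
#' Builds the binary adjacency with A[i,j] = A[j,i] = 1 iff spots i and j
#' are each within the other's k nearest neighbours (mutual-KNN). Distance
#' ties are broken by ascending spot index so the graph is deterministic.
#' A union-mode symmetrization (edge if EITHER spot lists the other) is
#' available because many toolkits symmetrize by OR.
#'
#' Neighbour search uses a k-d tree (RANN) when available and an exact
#' dense search otherwise; both give identical graphs.
#'
#' @param coords N x 2 coordinate matrix.
#' @param k Number of nearest neighbours, 1 <= k < N.
#' @param mode `"mutual"` (default) or `"union"`.
#' @return N x N binary symmetric matrix with zero diagonal.
#' @export
knn_adjacency <- function(coords, k, mode = c("mutual", "union")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(k >= 1)
  if (k >= n) stop("k must be smaller than the number of spots (k=", k,
                   ", N=", n, ")")
  nn <- knn_index(coords, k)
  A <- matrix(0, n, n)
  idx <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  A[idx] <- 1
  A <- if (mode == "mutual") A * t(A) else pmin(A + t(A), 1)
  diag(A) <- 0
  A
}

# k nearest neighbour indices (excluding self), ties by ascending index.
# RANN::nn2 (k-d tree) when present; exact dense search otherwise. RANN
# breaks exact-distance ties arbitrarily, so rows whose k-th and (k+1)-th
# distances tie are re-resolved by the deterministic dense rule.
knn_index <- function(coords, k) {
  n <- nrow(coords)
  if (requireNamespace("RANN", quietly = TRUE)) {
    res <- RANN::nn2(coords, k = min(k + 2L, n))
    nn <- res$nn.idx
    d <- res$nn.dists
    # column 1 is self (distance 0) unless exact duplicates reorder it
    out <- matrix(0L, n, k)
    ok <- rep(TRUE, n)
    for (i in seq_len(n)) {
      row <- nn[i, ]
      di <- d[i, ]
      keep <- row != i
      row <- row[keep]; di <- di[keep]
      if (length(row) < k) { ok[i] <- FALSE; next }
      # ambiguous if the boundary distance is tied
      if (length(di) > k && isTRUE(all.equal(di[k], di[k + 1L]))) {
        ok[i] <- FALSE
      } else {
        out[i, ] <- row[seq_len(k)]
      }
    }
    if (!all(ok)) {
      dense <- knn_index_dense(coords[, , drop = FALSE], k, which = which(!ok))
      out[!ok, ] <- dense
    }
    out
  } else {
    knn_index_dense(coords, k)
  }
}

# exact O(N^2) neighbour search with index tie-breaking
knn_index_dense <- function(coords, k, which = NULL) {
  n <- nrow(coords)
  rows <- if (is.null(which)) seq_len(n) else which
  D <- as.matrix(stats::dist(coords))
  out <- matrix(0L, length(rows), k)
  for (r in seq_along(rows)) {
    i <- rows[r]
    d <- D[i, ]
    d[i] <- Inf
    out[r, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

#' Radius spatial adjacency
#'
#' A[i,j] = 1 iff 0 < d(i,j) <= r (Euclidean). Symmetric, zero diagonal.
#' An empty graph (r below the minimum pairwise distance) is allowed but
#' warned about.
#'
#' @param coords N x 2 coordinate matrix.
#' @param r Radius, > 0.
#' @return N x N binary symmetric matrix.
#' @export
radius_adjacency <- function(coords, r) {
  stopifnot(r > 0)
  coords <- as.matrix(coords)
  D <- as.matrix(stats::dist(coords))
  A <- (D > 0 & D <= r) * 1
  diag(A) <- 0
  if (sum(A) == 0) warning("radius graph is empty (r = ", r, ")")
  A
}

#' Default radius from data resolution
#'
#' Heuristic: 1.2 times the median nearest-neighbour distance, which on a
#' regular lattice connects exactly the first neighbour shell.
#'
#' @param coords N x 2 coordinate matrix.
#' @param scale Multiplier on the median nearest-neighbour distance.
#' @return Positive scalar radius.
#' @export
default_radius <- function(coords, scale = 1.2) {
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  scale * stats::median(apply(D, 1, min))
}

#' Cosine-similarity feature graph
#'
#' Connects every spot to its `k_f` most cosine-similar spots in expression
#' space, symmetrized by OR. Only neighbours with strictly positive cosine
#' similarity are connected (orthogonal expression profiles share no
#' signal). Self-similarity is excluded; similarity ties are broken by
#' ascending spot index.
#'
#' @param X N x M expression matrix; rows must have positive norm.
#' @param k_f Neighbours per spot (default 15).
#' @return N x N binary symmetric matrix with zero diagonal.
#' @export
feature_adjacency <- function(X, k_f = 15L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k_f >= 1, k_f < n)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("zero-norm expression row(s): spot index ",
         paste(which(nrm == 0), collapse = ", "))
  Xn <- X / nrm
  S <- tcrossprod(Xn)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    top <- order(-s, seq_len(n))[seq_len(k_f)]
    A[i, top[s[top] > 0]] <- 1
  }
  A <- pmin(A + t(A), 1)
  diag(A) <- 0
  A
}

#' Symmetric GCN normalization of an adjacency matrix
#'
#' Returns `D^(-1/2) (A + I) D^(-1/2)` where `D` is the degree matrix of
#' `A + I` (self-loops are added here, never stored in the binary
#' adjacency). An isolated node maps to 1 on the diagonal. The result is
#' symmetric with spectral radius <= 1.
#'
#' @param A Square symmetric binary (or weighted, non-negative) matrix with
#'   zero diagonal.
#' @return Real symmetric matrix of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!isSymmetric(unname(A), tol = 1e-12)) stop("adjacency must be symmetric")
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  dinv <- 1 / sqrt(d)
  At * outer(dinv, dinv)
}

#' Bundle of spatial and feature graphs
#'
#' Convenience constructor building the mutual-KNN graph, the radius graph,
#' the cosine feature graph, and their GCN-normalized forms.
#'
#' @param ds A [spot_dataset()] (expression should already be normalized).
#' @param k KNN parameter (default 6, the first neighbour shell of a hex
#'   lattice).
#' @param r Radius; `NULL` uses [default_radius()].
#' @param k_f Feature-graph neighbours (default 15).
#' @param knn_mode Symmetrization for the KNN graph.
#' @return A list of class `graph_set` with `A_knn`, `A_radius`, `A_feat`,
#'   their `_norm` counterparts, and the `k`, `r`, `k_f` used.
#' @export
build_graphs <- function(ds, k = 6L, r = NULL, k_f = 15L,
                         knn_mode = "mutual") {
  validate_spot_dataset(ds)
  if (is.null(r)) r <- default_radius(ds$coords)
  A_knn <- knn_adjacency(ds$coords, k, mode = knn_mode)
  A_radius <- radius_adjacency(ds$coords, r)
  A_feat <- feature_adjacency(ds$counts, k_f = min(k_f, nrow(ds$counts) - 1L))
  structure(list(
    A_knn = A_knn, A_radius = A_radius, A_feat = A_feat,
    A_knn_norm = normalize_adjacency(A_knn),
    A_radius_norm = normalize_adjacency(A_radius),
    A_feat_norm = normalize_adjacency(A_feat),
    k = k, r = r, k_f = k_f), class = "graph_set")
}

#' Select the KNN parameter k by an unsupervised score
#'
#' For each candidate k the mutual-KNN graph is built and scored. The
#' default score embeds the normalized adjacency spectrally (top
#' eigenvectors) and takes the mean silhouette width of a seeded k-means
#' clustering of that embedding; `score = "ari"` instead scores against
#' `ds$true_labels` (benchmarking only). Ties go to the smallest k.
#'
#' @param ds A [spot_dataset()].
#' @param k_grid Candidate k values (default 1:20).
#' @param score `"silhouette"` (default, unsupervised) or `"ari"`.
#' @param n_clusters Number of clusters used by the score (default: number
#'   of true labels if present, else 4).
#' @param n_eig Spectral embedding dimension (default 8).
#' @param seed Seed for the k-means used in scoring.
#' @return The selected k (integer).
#' @export
select_k <- function(ds, k_grid = 1:20, score = c("silhouette", "ari"),
                     n_clusters = NULL, n_eig = 8L, seed = 0L) {
  score <- match.arg(score)
  validate_spot_dataset(ds)
  n <- nrow(ds$counts)
  stopifnot(length(k_grid) >= 1, all(k_grid < n))
  if (is.null(n_clusters)) {
    n_clusters <- if (!is.null(ds$true_labels))
      length(unique(ds$true_labels)) else 4L
  }
  if (score == "ari" && is.null(ds$true_labels))
    stop("score = 'ari' requires true_labels")
  vals <- vapply(k_grid, function(k) {
    A <- normalize_adjacency(knn_adjacency(ds$coords, k))
    E <- spectral_embedding(A, n_eig)
    lab <- cluster_embedding(E, n_clusters, seed = seed)
    if (score == "ari") {
      ari(ds$true_labels, lab)
    } else {
      if (length(unique(lab)) < 2L) return(-1)
      mean(cluster::silhouette(lab, stats::dist(E))[, 3])
    }
  }, numeric(1))
  k_grid[which.max(vals)]  # which.max takes the first (smallest k) on ties
}

# top-q eigenvectors of a symmetric matrix, deterministic sign convention
spectral_embedding <- function(A, q) {
  q <- min(q, nrow(A) - 1L)
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors[, seq_len(q), drop = FALSE]
  # fix sign: largest-magnitude entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Export a graph as an edge list
#'
#' Writes a TSV with columns `spot_i`, `spot_j`, `weight` for the upper
#' triangle of `A`.
#'
#' @param A Square symmetric matrix.
#' @param spot_ids Identifiers for the rows of `A`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(A, spot_ids, path) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  df <- data.frame(spot_i = spot_ids[idx[, 1]],
                   spot_j = spot_ids[idx[, 2]],
                   weight = A[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
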