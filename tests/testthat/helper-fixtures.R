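# Shared fixtures and independent oracles for the test suite.

# small deterministic dataset: 5 spots x 4 genes on a line
toy_dataset <- function() {
  counts <- rbind(
    c(0, 1, 5, 2),
    c(0, 2, 0, 3),
    c(3, 0, 1, 4),
    c(0, 1, 0, 5),
    c(0, 3, 2, 6))
  spot_dataset(counts, cbind(seq_len(5), 0))
}

# a small preprocessed simulated tissue for trainer tests
small_sim <- function(seed = 0L, n_rows = 10L, n_cols = 12L) {
  ds <- simulate_tissue(sim_spec(n_rows = n_rows, n_cols = n_cols,
                                 n_domains = 3L, n_genes = 60L,
                                 n_markers_per_domain = 6L,
                                 marker_fold = 6, pi0 = 0.1,
                                 seed = seed))
  ds <- filter_genes(ds, min_spots = 2L)
  suppressWarnings(ds <- select_hvg(ds, n_top = 60L))
  normalize_total(ds, 1e4)
}

# --- independent oracles --------------------------------------------------

# ARI by exhaustive pair counting over all C(N,2) pairs
ari_oracle <- function(truth, pred) {
  n <- length(truth)
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- truth[i] == truth[j]
      sp <- pred[i] == pred[j]
      if (st && sp) tp <- tp + 1
      else if (!st && !sp) tn <- tn + 1
      else if (!st && sp) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  a <- tp + fn  # same-truth pairs
  b <- tp + fp  # same-pred pairs
  tot <- tp + tn + fp + fn
  expected <- a * b / tot
  maxi <- (a + b) / 2
  if (maxi == expected) return(ifelse(tp == expected, 1, 0))
  (tp - expected) / (maxi - expected)
}

# NMI from explicit probability tables
nmi_oracle <- function(truth, pred) {
  n <- length(truth)
  tu <- unique(truth); pu <- unique(pred)
  pw <- vapply(tu, function(w) mean(truth == w), numeric(1))
  pv <- vapply(pu, function(v) mean(pred == v), numeric(1))
  hw <- -sum(pw * log(pw)); hv <- -sum(pv * log(pv))
  if (hw == 0 || hv == 0) return(0)
  mi <- 0
  for (a in seq_along(tu)) {
    for (b in seq_along(pu)) {
      pj <- mean(truth == tu[a] & pred == pu[b])
      if (pj > 0) mi <- mi + pj * log(pj / (pw[a] * pv[b]))
    }
  }
  mi / sqrt(hw * hv)
}

# mutual-KNN adjacency by per-pair enumeration (no shared code with the
# implementation's vectorized/k-d-tree paths)
knn_oracle <- function(coords, k, mode = "mutual") {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  lists <- lapply(seq_len(n), function(i) {
    d <- D[i, ]; d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  })
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      in_i <- j %in% lists[[i]]
      in_j <- i %in% lists[[j]]
      if ((mode == "mutual" && in_i && in_j) ||
          (mode == "union" && (in_i || in_j))) A[i, j] <- 1
    }
  }
  A
}

radius_oracle <- function(coords, r) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= r) A[i, j] <- 1
    }
  }
  A
}

# Eq-style dense normalization oracle using explicit matrix inverses
normalize_oracle <- function(A) {
  At <- A + diag(nrow(A))
  Dm <- diag(rowSums(At))
  Ds <- diag(1 / sqrt(diag(Dm)), nrow(A))
  Ds %*% At %*% Ds
}
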