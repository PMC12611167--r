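#' Filter genes by the number of expressing spots
#'
#' Keeps genes with nonzero expression in at least `min_spots` spots. The
#' default of 100 matches common practice for Visium-scale data; synthetic
#' or small datasets should lower it.
#'
#' @param ds A [spot_dataset()].
#' @param min_spots Minimum number of spots a gene must be detected in
#'   (default 100).
#' @return A `spot_dataset` with the gene subset, order preserved.
#' @export
filter_genes <- function(ds, min_spots = 100L) {
  validate_spot_dataset(ds)
  stopifnot(min_spots >= 0)
  n_expressing <- colSums(ds$counts > 0)
  keep <- n_expressing >= min_spots
  if (!any(keep))
    stop("empty gene set: no gene is expressed in >= ", min_spots, " spots")
  subset_genes(ds, keep)
}

#' Select highly variable genes
#'
#' Ranks genes by mean-binned normalized dispersion (the classic
#' dispersion-based HVG criterion): per-gene mean and dispersion
#' (variance/mean) are computed, genes are grouped into `n_bins` equal-count
#' bins of mean expression, and the dispersion is z-scored within each bin.
#' The top `n_top` genes by normalized dispersion are kept.
#'
#' @param ds A [spot_dataset()].
#' @param n_top Number of genes to keep (default 3000).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return A `spot_dataset` restricted to the selected genes, ranked by
#'   decreasing normalized dispersion. Deterministic given the input.
#' @export
select_hvg <- function(ds, n_top = 3000L, n_bins = 20L) {
  validate_spot_dataset(ds)
  stopifnot(n_top >= 1)
  m <- ncol(ds$counts)
  if (n_top > m) {
    warning("n_top (", n_top, ") exceeds number of genes (", m,
            "); keeping all genes")
    n_top <- m
  }
  score <- hvg_score(ds$counts, n_bins = n_bins)
  # ties broken by original column index for determinism
  ord <- order(-score, seq_len(m))
  subset_genes(ds, sort(ord[seq_len(n_top)]))
}

#' Mean-binned normalized dispersion score
#'
#' @param counts Spots x genes matrix.
#' @param n_bins Number of mean bins.
#' @return Numeric vector of per-gene scores (z-scored dispersion within
#'   mean bins); higher is more variable.
#' @export
hvg_score <- function(counts, n_bins = 20L) {
  mu <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  m <- length(mu)
  n_bins <- max(1L, min(n_bins, m))
  # equal-count bins over the mean; rank-based so constant shifts are safe
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- numeric(m)
  for (b in unique(bins)) {
    i <- bins == b
    mu_b <- mean(disp[i])
    sd_b <- stats::sd(disp[i])
    if (!is.finite(sd_b) || sd_b == 0) sd_b <- 1
    z[i] <- (disp[i] - mu_b) / sd_b
  }
  z
}

#' Total-count normalization
#'
#' Scales each spot so its total expression equals `target`:
#' x'_ij = x_ij / sum_j(x_ij) * target. Spots with zero total are dropped
#' with a warning.
#'
#' @param ds A [spot_dataset()].
#' @param target Per-spot total after scaling (default 1e4).
#' @param log1p Also apply log(1 + x) after scaling (default FALSE; the
#'   downstream ZINB decoder consumes counts-like data).
#' @return A `spot_dataset` with normalized expression in `counts`.
#' @export
normalize_total <- function(ds, target = 1e4, log1p = FALSE) {
  validate_spot_dataset(ds)
  stopifnot(target > 0)
  rs <- rowSums(ds$counts)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " spot(s) with zero total count dropped")
    ds <- subset_spots(ds, rs > 0)
    rs <- rs[rs > 0]
  }
  ds$counts <- ds$counts / rs * target
  if (log1p) ds$counts <- log1p(ds$counts)
  ds
}

#' Add scaled Gaussian noise to expression values
#'
#' Robustness utility: perturbs each gene with zero-mean Gaussian noise
#' whose standard deviation is `fraction` times that gene's empirical
#' standard deviation. Negative results are clipped to zero so the matrix
#' stays valid expression data.
#'
#' @param ds A [spot_dataset()].
#' @param fraction Noise level in `[0, 1]`; e.g. 0.1, 0.2, 0.3 for the
#'   10/20/30 percent regimes.
#' @param seed Integer seed; same seed gives identical output.
#' @return A perturbed copy of `ds`.
#' @export
add_gaussian_noise <- function(ds, fraction, seed = 0L) {
  validate_spot_dataset(ds)
  stopifnot(fraction >= 0)
  if (fraction == 0) return(ds)
  n <- nrow(ds$counts); m <- ncol(ds$counts)
  sds <- apply(ds$counts, 2, stats::sd)
  eps <- with_seed(seed, matrix(stats::rnorm(n * m), n, m))
  ds$counts <- pmax(ds$counts + sweep(eps, 2, fraction * sds, `*`), 0)
  ds
}

# Seed bracketing: functions taking an explicit `seed` must not disturb the
# caller's RNG stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with a local seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  expr
}
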