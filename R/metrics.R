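# Clustering agreement metrics: adjusted Rand index and normalized mutual
# information (geometric-mean normalization).

#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement between two partitions, via the
#' contingency-table form. 1 iff the partitions are identical up to
#' relabeling; 0 in expectation for independent random labelings.
#'
#' @param truth,pred Equal-length label vectors (any atomic type).
#' @return Scalar in `[-1, 1]`.
#' @export
ari <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label vectors must have equal length")
  tab <- table(truth, pred)
  n <- length(truth)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  exp_ij <- a * b / choose(n, 2)
  max_ij <- (a + b) / 2
  if (max_ij == exp_ij) return(ifelse(sum_ij == exp_ij, 1, 0))
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the geometric
#' mean of their entropies, `MI / sqrt(H(W) H(V))`. Degenerate cases where
#' either partition has a single cluster return 0 by convention.
#'
#' @param truth,pred Equal-length label vectors.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label vectors must have equal length")
  n <- length(truth)
  joint <- table(truth, pred) / n
  pw <- rowSums(joint)
  pv <- colSums(joint)
  hw <- -sum(pw[pw > 0] * log(pw[pw > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hw == 0 || hv == 0) return(0)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pw, pv)[nz]))
  mi / sqrt(hw * hv)
}
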