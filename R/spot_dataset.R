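#' Spot-level spatial expression dataset
#'
#' The central container of the package: a spots-by-genes count matrix with
#' per-spot 2-D coordinates, identifiers, and optional ground-truth domain
#' labels. All preprocessing and graph-construction functions consume and
#' return this class.
#'
#' @param counts Numeric matrix, N spots x M genes, non-negative and finite.
#' @param coords Numeric matrix or data.frame, N x 2 spatial positions
#'   (platform units).
#' @param spot_ids Character vector of N unique spot identifiers. Defaults to
#'   rownames of `counts` or `spot_1..N`.
#' @param gene_ids Character vector of M unique gene identifiers. Defaults to
#'   colnames of `counts` or `gene_1..M`.
#' @param true_labels Optional integer/factor vector of N domain labels.
#'
#' @return An object of class `spot_dataset`: a list with elements `counts`,
#'   `coords`, `spot_ids`, `gene_ids`, `true_labels`.
#' @export
#' @examples
#' ds <- spot_dataset(matrix(rpois(20, 2), 5, 4), cbind(1:5, 0))
#' dim(ds$counts)
spot_dataset <- function(counts, coords, spot_ids = NULL, gene_ids = NULL,
                         true_labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(spot_ids)) {
    spot_ids <- rownames(counts)
    if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(counts)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  }
  if (!is.null(true_labels)) {
    true_labels <- as.integer(as.factor(true_labels))
  }
  ds <- structure(
    list(counts = counts, coords = coords,
         spot_ids = as.character(spot_ids),
         gene_ids = as.character(gene_ids),
         true_labels = true_labels),
    class = "spot_dataset")
  validate_spot_dataset(ds)
  ds
}

#' Validate a spot_dataset
#'
#' Checks the class invariants: non-negative finite counts, finite
#' coordinates, unique identifiers, at least 2 spots and 1 gene.
#'
#' @param ds A `spot_dataset`.
#' @return `ds`, invisibly; errors if an invariant is violated.
#' @export
validate_spot_dataset <- function(ds) {
  stopifnot(inherits(ds, "spot_dataset"))
  n <- nrow(ds$counts); m <- ncol(ds$counts)
  if (n < 2L) stop("spot_dataset needs at least 2 spots")
  if (m < 1L) stop("spot_dataset needs at least 1 gene")
  if (!all(is.finite(ds$counts))) stop("counts must be finite")
  if (any(ds$counts < 0)) stop("counts must be non-negative")
  if (!all(is.finite(ds$coords))) stop("coords must be finite")
  if (nrow(ds$coords) != n || ncol(ds$coords) != 2L)
    stop("coords must be N x 2")
  if (length(ds$spot_ids) != n) stop("spot_ids length mismatch")
  if (anyDuplicated(ds$spot_ids)) stop("duplicate spot_ids")
  if (length(ds$gene_ids) != m) stop("gene_ids length mismatch")
  if (!is.null(ds$true_labels) && length(ds$true_labels) != n)
    stop("true_labels length mismatch")
  invisible(ds)
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  coords range: x [%.3g, %.3g], y [%.3g, %.3g]\n",
              min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  if (!is.null(x$true_labels))
    cat(sprintf("  true_labels: %d domains\n",
                length(unique(x$true_labels))))
  invisible(x)
}

# internal: subset genes by logical/integer index, keeping order
subset_genes <- function(ds, idx) {
  ds$counts <- ds$counts[, idx, drop = FALSE]
  ds$gene_ids <- ds$gene_ids[idx]
  ds
}

# internal: subset spots
subset_spots <- function(ds, idx) {
  ds$counts <- ds$counts[idx, , drop = FALSE]
  ds$coords <- ds$coords[idx, , drop = FALSE]
  ds$spot_ids <- ds$spot_ids[idx]
  if (!is.null(ds$true_labels)) ds$true_labels <- ds$true_labels[idx]
  ds
}
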