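# Readers and writers: 10x-style MTX triplet directories, plain CSV, and
# (when rhdf5 is available) minimal h5ad-style containers.

#' Read a spots-by-genes CSV plus a coordinate CSV
#'
#' @param counts_csv CSV with spot ids in the first column and genes in
#'   the remaining columns (spots x genes).
#' @param coords_csv CSV with columns `spot_id`, `x`, `y` and optionally
#'   `label` (ground-truth domain).
#' @return A [spot_dataset()].
#' @export
read_spot_csv <- function(counts_csv, coords_csv) {
  cm <- utils::read.csv(counts_csv, check.names = FALSE)
  spot_ids <- as.character(cm[[1L]])
  counts <- as.matrix(cm[, -1L, drop = FALSE])
  rownames(counts) <- spot_ids
  co <- utils::read.csv(coords_csv)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(co)))
    stop("coords CSV must have columns spot_id, x, y")
  i <- match(spot_ids, as.character(co$spot_id))
  if (anyNA(i)) stop("coords CSV is missing ",
                     sum(is.na(i)), " spot id(s)")
  lab <- if ("label" %in% names(co)) co$label[i] else NULL
  spot_dataset(counts, cbind(co$x[i], co$y[i]), spot_ids = spot_ids,
               true_labels = lab)
}

#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx` (genes x spots, MatrixMarket), `barcodes.tsv`,
#' `features.tsv` (or `genes.tsv`), and a coordinate table `coords.csv`
#' with columns `spot_id`, `x`, `y` (optionally `label`) in `dir`, or at
#' `coords_file`.
#'
#' @param dir Directory containing the triplet.
#' @param coords_file Path to the coordinate CSV; default
#'   `file.path(dir, "coords.csv")`.
#' @return A [spot_dataset()].
#' @export
read_10x_mtx <- function(dir, coords_file = file.path(dir, "coords.csv")) {
  mtx <- file.path(dir, "matrix.mtx")
  bc <- file.path(dir, "barcodes.tsv")
  ft <- file.path(dir, "features.tsv")
  if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
  for (f in c(mtx, bc, ft, coords_file))
    if (!file.exists(f)) stop("missing input file: ", f)
  M <- as.matrix(Matrix::readMM(mtx))  # genes x spots per 10x convention
  barcodes <- readLines(bc)
  feats <- utils::read.delim(ft, header = FALSE)
  gene_ids <- as.character(feats[[1L]])
  counts <- t(M)
  rownames(counts) <- barcodes
  colnames(counts) <- gene_ids
  co <- utils::read.csv(coords_file)
  i <- match(barcodes, as.character(co$spot_id))
  if (anyNA(i)) stop("coords file is missing ", sum(is.na(i)),
                     " barcode(s)")
  lab <- if ("label" %in% names(co)) co$label[i] else NULL
  spot_dataset(counts, cbind(co$x[i], co$y[i]), spot_ids = barcodes,
               gene_ids = gene_ids, true_labels = lab)
}

#' Read a minimal h5ad-style container
#'
#' Supports the common AnnData-on-HDF5 layout: `X` stored dense or as a
#' CSR/CSC group (`data`/`indices`/`indptr`), spot names in
#' `obs/_index` (or `obs/index`), gene names in `var/_index`, and
#' spatial coordinates in `obsm/spatial`. Requires the `rhdf5` package.
#'
#' @param path Path to the `.h5ad` file.
#' @param label_key Optional key under `obs/` holding domain labels.
#' @return A [spot_dataset()].
#' @export
read_h5ad <- function(path, label_key = NULL) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("read_h5ad requires the rhdf5 package")
  if (!file.exists(path)) stop("missing input file: ", path)
  ls <- rhdf5::h5ls(path)
  read1 <- function(name) rhdf5::h5read(path, name)
  obs_index <- if (any(ls$group == "/obs" & ls$name == "_index"))
    as.character(read1("obs/_index")) else as.character(read1("obs/index"))
  var_index <- if (any(ls$group == "/var" & ls$name == "_index"))
    as.character(read1("var/_index")) else as.character(read1("var/index"))
  n <- length(obs_index); m <- length(var_index)
  if (any(ls$group == "/X")) {  # sparse group
    dat <- as.numeric(read1("X/data"))
    ind <- as.integer(read1("X/indices"))
    ptr <- as.integer(read1("X/indptr"))
    att <- rhdf5::h5readAttributes(path, "X")
    enc <- if (!is.null(att$`encoding-type`)) att$`encoding-type`
    else "csr_matrix"
    counts <- if (grepl("csr", enc)) {
      # rows = obs; indptr over rows, indices are columns
      as.matrix(Matrix::sparseMatrix(j = ind + 1L, p = ptr, x = dat,
                                     dims = c(n, m)))
    } else {
      as.matrix(Matrix::sparseMatrix(i = ind + 1L, p = ptr, x = dat,
                                     dims = c(n, m)))
    }
  } else {
    X <- read1("X")
    # HDF5 stores row-major; rhdf5 returns genes x spots for AnnData
    counts <- if (nrow(X) == m && ncol(X) == n) t(X) else as.matrix(X)
  }
  sp <- read1("obsm/spatial")
  coords <- if (nrow(sp) == 2L && ncol(sp) == n) t(sp) else as.matrix(sp)
  lab <- NULL
  if (!is.null(label_key)) {
    v <- read1(paste0("obs/", label_key))
    lab <- if (is.list(v) && !is.null(v$codes)) {
      as.integer(v$codes) + 1L  # categorical encoding
    } else as.vector(v)
  }
  spot_dataset(counts, coords[, 1:2, drop = FALSE], spot_ids = obs_index,
               gene_ids = var_index, true_labels = lab)
}

#' Auto-detecting reader
#'
#' Dispatches on the input path: a directory is read as an MTX triplet, a
#' `.h5ad` file via [read_h5ad()], and a `.csv` as counts CSV (with
#' `coords_csv` required).
#'
#' @param path Input path.
#' @param coords_csv Coordinate CSV (CSV input only; for directories the
#'   default `coords.csv` inside is used).
#' @return A [spot_dataset()].
#' @export
read_spots <- function(path, coords_csv = NULL) {
  if (dir.exists(path)) return(read_10x_mtx(path))
  if (grepl("\\.h5ad$", path, ignore.case = TRUE))
    return(read_h5ad(path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (is.null(coords_csv))
      coords_csv <- sub("\\.csv$", "_coords.csv", path)
    return(read_spot_csv(path, coords_csv))
  }
  stop("unrecognized input format: ", path)
}

#' Write a spot_dataset to disk
#'
#' `format = "csv"` writes `counts.csv` (spots x genes) and `coords.csv`;
#' `format = "mtx"` writes the 10x-style triplet (`matrix.mtx` genes x
#' spots, `barcodes.tsv`, `features.tsv`) plus `coords.csv`. True labels,
#' when present, go into the `label` column of `coords.csv` and a
#' separate `truth.csv`.
#'
#' @param ds A [spot_dataset()].
#' @param dir Output directory (created if needed).
#' @param format `"mtx"` (default) or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(ds, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  validate_spot_dataset(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- data.frame(spot_id = ds$spot_ids, x = ds$coords[, 1],
                   y = ds$coords[, 2])
  if (!is.null(ds$true_labels)) {
    co$label <- ds$true_labels
    utils::write.csv(data.frame(spot_id = ds$spot_ids,
                                label = ds$true_labels),
                     file.path(dir, "truth.csv"), row.names = FALSE)
  }
  utils::write.csv(co, file.path(dir, "coords.csv"), row.names = FALSE)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(t(ds$counts),
                                               sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
    utils::write.table(data.frame(ds$gene_ids, ds$gene_ids,
                                  "Gene Expression"),
                       file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(spot_id = ds$spot_ids, ds$counts,
                     check.names = FALSE)
    colnames(df) <- c("spot_id", ds$gene_ids)
    utils::write.csv(df, file.path(dir, "counts.csv"), row.names = FALSE)
  }
  invisible(dir)
}
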