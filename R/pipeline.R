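# End-to-end orchestration: YAML config handling, repeated training runs,
# and on-disk artifacts (labels, embedding, loss trace, metrics, resolved
# config, log).

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config consumed by [run_pipeline()] and
#' the CLI. Every key can be overridden by a user config file; unknown
#' keys are rejected.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    preprocess = list(min_spots = 100L, n_top = 3000L, target = 1e4,
                      log1p = FALSE),
    graphs = list(k = 6L, r = NULL, k_f = 15L, knn_mode = "mutual"),
    contrastive = list(margin = 0.5, mode = "row_shuffle",
                       dims = c(128L, 64L), form = "hinge"),
    multiview = list(layers = 2L, hidden_dim = 64L,
                     attention_hidden = 32L,
                     feature_input = "latent"),
    loss = list(lambda_zinb = 1, lambda_com = 1, lambda_con = 1,
                lambda_reg = 1, neg_samples = 5L),
    train = list(lr = 1e-3, weight_decay = 5e-4, epochs = 200L,
                 seed = 0L, n_clusters = 4L, repeats = 1L,
                 early_stop_patience = 20L, early_stop_tol = 1e-4,
                 cluster_method = "kmeans"),
    ablation = "none")
}

# recursive merge of user config over defaults, erroring on unknown keys
merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base)) stop("unknown config key: ", key)
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a YAML pipeline configuration
#'
#' @param path YAML file; `NULL` returns [default_config()].
#' @return Resolved nested config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

# translate the nested pipeline config into a train_config
as_train_config <- function(cfg, seed = NULL, n_clusters = NULL,
                            ablation = NULL) {
  hv <- cfg$multiview$hidden_dim
  train_config(
    n_clusters = if (is.null(n_clusters)) cfg$train$n_clusters
    else n_clusters,
    lr = cfg$train$lr, weight_decay = cfg$train$weight_decay,
    epochs = cfg$train$epochs,
    seed = if (is.null(seed)) cfg$train$seed else seed,
    k = cfg$graphs$k, r = cfg$graphs$r, k_f = cfg$graphs$k_f,
    knn_mode = cfg$graphs$knn_mode,
    alpha = cfg$contrastive$margin, cl_form = cfg$contrastive$form,
    lambda = c(cfg$loss$lambda_zinb, cfg$loss$lambda_com,
               cfg$loss$lambda_con, cfg$loss$lambda_reg),
    feature_input = cfg$multiview$feature_input,
    corruption = cfg$contrastive$mode,
    n_neg = cfg$loss$neg_samples,
    ablation = if (is.null(ablation)) cfg$ablation else ablation,
    cluster_method = cfg$train$cluster_method,
    early_stop_patience = cfg$train$early_stop_patience,
    early_stop_tol = cfg$train$early_stop_tol,
    dims_contrastive = cfg$contrastive$dims,
    dims_view = rep(hv, cfg$multiview$layers),
    att_h = cfg$multiview$attention_hidden)
}

#' Run the full pipeline and write artifacts
#'
#' Loads the input, preprocesses (gene filter, HVG selection, total-count
#' normalization), trains `repeats` times with seeds `seed, seed+1, ...`,
#' and writes to `outdir`: `labels.csv` (spot_id, x, y, domain — from the
#' master-seed run), `embedding.csv`, `loss_trace.csv`, `metrics.json`
#' (per-run and mean ARI/NMI when truth is available), `config.yaml`
#' (resolved), and `run.log`.
#'
#' @param input Input path ([read_spots()] formats) or a `spot_dataset`.
#' @param outdir Output directory.
#' @param config_path Optional YAML config.
#' @param seed,n_clusters,ablation,repeats Optional overrides of the
#'   config file.
#' @return The `train_result` of the master-seed run, invisibly, with a
#'   `metrics` element attached.
#' @export
run_pipeline <- function(input, outdir, config_path = NULL, seed = NULL,
                         n_clusters = NULL, ablation = NULL,
                         repeats = NULL) {
  cfg <- load_config(config_path)
  if (!is.null(seed)) cfg$train$seed <- as.integer(seed)
  if (!is.null(n_clusters)) cfg$train$n_clusters <- as.integer(n_clusters)
  if (!is.null(ablation)) cfg$ablation <- ablation
  if (!is.null(repeats)) cfg$train$repeats <- as.integer(repeats)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  logmsg <- function(...) cat(sprintf("[%s] %s\n",
                                      format(Sys.time(), "%H:%M:%S"),
                                      sprintf(...)),
                              file = logf, append = TRUE)
  ds <- if (inherits(input, "spot_dataset")) input else read_spots(input)
  logmsg("loaded %d spots x %d genes", nrow(ds$counts), ncol(ds$counts))
  ds <- filter_genes(ds, min_spots = min(cfg$preprocess$min_spots,
                                         nrow(ds$counts)))
  suppressWarnings(ds <- select_hvg(ds, n_top = cfg$preprocess$n_top))
  counts_raw <- ds$counts
  rownames(counts_raw) <- ds$spot_ids
  ds <- normalize_total(ds, target = cfg$preprocess$target,
                        log1p = cfg$preprocess$log1p)
  counts_raw <- counts_raw[ds$spot_ids, , drop = FALSE]
  logmsg("preprocessed to %d spots x %d genes", nrow(ds$counts),
         ncol(ds$counts))
  reps <- max(1L, cfg$train$repeats)
  seeds <- cfg$train$seed + seq_len(reps) - 1L
  runs <- vector("list", reps)
  for (i in seq_len(reps)) {
    tc <- as_train_config(cfg, seed = seeds[i])
    runs[[i]] <- train(ds, tc, counts = counts_raw)
    logmsg("run %d/%d (seed %d): %d epochs, final loss %.4f, ARI %s",
           i, reps, seeds[i], runs[[i]]$epochs_run,
           runs[[i]]$loss_trace$total[runs[[i]]$epochs_run],
           format(runs[[i]]$ari, digits = 3))
  }
  res <- runs[[1L]]
  # artifacts
  utils::write.csv(data.frame(spot_id = ds$spot_ids,
                              x = ds$coords[, 1], y = ds$coords[, 2],
                              domain = res$labels),
                   file.path(outdir, "labels.csv"), row.names = FALSE)
  emb <- data.frame(spot_id = ds$spot_ids, x = ds$coords[, 1],
                    y = ds$coords[, 2], res$Z)
  colnames(emb) <- c("spot_id", "x", "y",
                     paste0("z", seq_len(ncol(res$Z))))
  utils::write.csv(emb, file.path(outdir, "embedding.csv"),
                   row.names = FALSE)
  utils::write.csv(res$loss_trace, file.path(outdir, "loss_trace.csv"),
                   row.names = FALSE)
  metrics <- list(
    per_run = data.frame(seed = seeds,
                         ari = vapply(runs, `[[`, numeric(1), "ari"),
                         nmi = vapply(runs, `[[`, numeric(1), "nmi"),
                         epochs = vapply(runs, `[[`, numeric(1),
                                         "epochs_run")),
    mean_ari = mean(vapply(runs, `[[`, numeric(1), "ari")),
    mean_nmi = mean(vapply(runs, `[[`, numeric(1), "nmi")))
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  cfg_out <- cfg
  cfg_out$graphs$k <- res$k
  cfg_out$graphs$r <- res$r
  yaml::write_yaml(cfg_out, file.path(outdir, "config.yaml"))
  logmsg("done; mean ARI %s, mean NMI %s",
         format(metrics$mean_ari, digits = 3),
         format(metrics$mean_nmi, digits = 3))
  res$metrics <- metrics
  invisible(res)
}

#' Evaluate predicted labels against a truth table
#'
#' @param truth_csv CSV with columns `spot_id` and `label`.
#' @param pred_csv CSV with columns `spot_id` and `domain` (the
#'   `labels.csv` written by [run_pipeline()]).
#' @return List with `ari` and `nmi`.
#' @export
eval_labels <- function(truth_csv, pred_csv) {
  tr <- utils::read.csv(truth_csv)
  pr <- utils::read.csv(pred_csv)
  i <- match(tr$spot_id, pr$spot_id)
  if (anyNA(i)) stop("prediction is missing ", sum(is.na(i)), " spot(s)")
  pred_col <- if ("domain" %in% names(pr)) "domain" else "label"
  list(ari = ari(tr$label, pr[[pred_col]][i]),
       nmi = nmi(tr$label, pr[[pred_col]][i]))
}
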