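# End-to-end training: graph construction, seeded corruption and negative
# sampling, Adam optimization of the combined objective, and clustering of
# the fused embedding.

#' Training configuration
#'
#' Collects every tunable of the trainer with the defaults used throughout
#' the package: Adam with learning rate 1e-3 and weight decay 5e-4, up to
#' `epochs` epochs with plateau early-stopping, margin 0.5 for the
#' contrastive hinge, unit weights on the four loss terms, and mutual-KNN
#' (k = 6) plus 1.2x-median-NN-radius spatial graphs.
#'
#' @param n_clusters Number of spatial domains to extract.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay added to the gradients.
#' @param epochs Maximum number of epochs (>= 1).
#' @param seed Master seed; every stochastic stage (initialization,
#'   corruption, negative sampling, clustering) derives from it.
#' @param k,r,k_f,knn_mode Graph parameters, see [build_graphs()]. `k =
#'   "auto"` selects k over `k_grid` with [select_k()].
#' @param k_grid Candidate grid for `k = "auto"`.
#' @param alpha Contrastive margin.
#' @param cl_form Contrastive loss form (`"hinge"` or `"literal"`).
#' @param lambda Four weights for (ZINB, contrastive, consistency,
#'   regularization).
#' @param feature_input Input to the feature/co-convolutions: the
#'   contrastive latent (`"latent"`, default) or the corrupted matrix
#'   (`"corrupted"`).
#' @param corruption Corruption mode for [corrupt_features()].
#' @param n_neg Negative samples per spot for the spatial regularizer.
#' @param ablation One of `"none"`, `"no_knn"`, `"no_radius"`, `"no_cl"`,
#'   `"no_wfa"`, `"dist"` (distance-similarity matrix replaces both
#'   spatial graphs).
#' @param cluster_method `"kmeans"` (k-means++ init, default) or `"gmm"`.
#' @param early_stop_patience Epochs without improvement before stopping
#'   (0 disables).
#' @param early_stop_tol Minimum improvement of the total loss.
#' @param dims_contrastive,dims_view,att_h,att_h2 Layer widths.
#' @param verbose Print per-epoch losses.
#' @return A list of class `train_config`.
#' @export
train_config <- function(n_clusters = 4L, lr = 1e-3, weight_decay = 5e-4,
                         epochs = 200L, seed = 0L,
                         k = 6L, r = NULL, k_f = 15L, knn_mode = "mutual",
                         k_grid = 1:20,
                         alpha = 0.5, cl_form = "hinge",
                         lambda = c(1, 1, 1, 1),
                         feature_input = c("latent", "corrupted"),
                         corruption = "row_shuffle",
                         n_neg = 5L,
                         ablation = c("none", "no_knn", "no_radius",
                                      "no_cl", "no_wfa", "dist"),
                         cluster_method = c("kmeans", "gmm"),
                         early_stop_patience = 20L, early_stop_tol = 1e-4,
                         dims_contrastive = c(128L, 64L),
                         dims_view = c(64L, 64L),
                         att_h = 32L, att_h2 = 16L,
                         verbose = FALSE) {
  ablation <- match.arg(ablation)
  stopifnot(lr > 0, epochs >= 1, n_clusters >= 1, all(lambda >= 0))
  structure(list(
    n_clusters = as.integer(n_clusters), lr = lr,
    weight_decay = weight_decay, epochs = as.integer(epochs),
    seed = as.integer(seed), k = k, r = r, k_f = k_f,
    knn_mode = knn_mode, k_grid = k_grid,
    alpha = alpha, cl_form = cl_form, lambda = lambda,
    feature_input = match.arg(feature_input), corruption = corruption,
    n_neg = as.integer(n_neg), ablation = ablation,
    no_knn = ablation == "no_knn", no_radius = ablation == "no_radius",
    no_cl = ablation == "no_cl", no_wfa = ablation == "no_wfa",
    distance_matrix_mode = ablation == "dist",
    cluster_method = match.arg(cluster_method),
    early_stop_patience = as.integer(early_stop_patience),
    early_stop_tol = early_stop_tol,
    arch = list(dims_contrastive = as.integer(dims_contrastive),
                dims_view = as.integer(dims_view),
                att_h = as.integer(att_h), att_h2 = as.integer(att_h2)),
    verbose = isTRUE(verbose)), class = "train_config")
}

# thresholded Gaussian distance-similarity graph (the "(w/o)KNN and
# Radius" ablation): exp(-d^2 / 2 sigma^2) with sigma the median
# nearest-neighbour distance, thresholded at its off-diagonal median
distance_similarity_graph <- function(coords) {
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  sigma <- stats::median(apply(D, 1, min))
  S <- exp(-D^2 / (2 * sigma^2))
  thr <- stats::median(S[upper.tri(S)])
  A <- (S > thr) * 1
  A <- pmax(A, t(A))
  diag(A) <- 0
  A
}

#' Train the spatial-domain model
#'
#' Runs the full pipeline on a preprocessed dataset: builds the spatial
#' and feature graphs, corrupts the expression matrix for contrastive
#' learning, optimizes the combined objective (ZINB reconstruction +
#' contrastive + cross-view consistency + spatial regularization) with
#' Adam, clusters the fused embedding, and evaluates against
#' `ds$true_labels` when present. Fully deterministic given `cfg$seed`.
#'
#' @param ds A preprocessed [spot_dataset()] (filtered, HVG-selected,
#'   total-count normalized).
#' @param cfg A [train_config()].
#' @param counts Optional N x M matrix of reconstruction targets for the
#'   ZINB likelihood; defaults to `round(ds$counts)` (rounded normalized
#'   values).
#' @return A list of class `train_result`: `loss_trace` (data.frame, one
#'   row per epoch), `Z` (final fused embedding), `labels` (0-based
#'   integer domains), `att_weights`, `ari`/`nmi` (NA without truth),
#'   `k`, `r`, `epochs_run`, and the `config` echo.
#' @export
train <- function(ds, cfg = train_config(), counts = NULL) {
  validate_spot_dataset(ds)
  if (is.null(counts)) counts <- round(ds$counts)
  stopifnot(nrow(counts) == nrow(ds$counts),
            ncol(counts) == ncol(ds$counts))
  n <- nrow(ds$counts); m <- ncol(ds$counts)

  # --- graphs -------------------------------------------------------------
  k <- cfg$k
  if (identical(k, "auto"))
    k <- select_k(ds, k_grid = cfg$k_grid[cfg$k_grid < n],
                  n_clusters = cfg$n_clusters, seed = cfg$seed)
  r <- if (is.null(cfg$r)) default_radius(ds$coords) else cfg$r
  if (cfg$distance_matrix_mode) {
    A_dist <- normalize_adjacency(distance_similarity_graph(ds$coords))
    A_knn_norm <- A_dist
    A_radius_norm <- A_dist
    A_union <- distance_similarity_graph(ds$coords)
  } else {
    A_knn <- knn_adjacency(ds$coords, k, mode = cfg$knn_mode)
    A_radius <- radius_adjacency(ds$coords, r)
    A_knn_norm <- normalize_adjacency(A_knn)
    A_radius_norm <- normalize_adjacency(A_radius)
    A_union <- pmin(A_knn + A_radius, 1)
  }
  A_feat <- feature_adjacency(ds$counts, k_f = min(cfg$k_f, n - 1L))
  A_f_norm <- normalize_adjacency(A_feat)

  # --- fixed stochastic ingredients ---------------------------------------
  # input features scaled to unit global sd for stable activations; the
  # ZINB targets stay on the count scale
  x_sd <- stats::sd(as.vector(ds$counts))
  if (!is.finite(x_sd) || x_sd == 0) x_sd <- 1
  X <- ds$counts / x_sd
  Xc <- if (cfg$no_cl) X
  else corrupt_features(X, seed = cfg$seed + 1L, mode = cfg$corruption)
  reg_spec <- spatial_reg_spec(A_union, n_neg = cfg$n_neg,
                               seed = cfg$seed + 2L)
  sp <- function(A) methods::as(Matrix::Matrix(A, sparse = TRUE),
                                "generalMatrix")
  data <- list(X = X, Xc = Xc, counts = counts,
               A_knn = sp(A_knn_norm), A_radius = sp(A_radius_norm),
               A_f = sp(A_f_norm), reg_spec = reg_spec)

  # --- optimization -------------------------------------------------------
  params <- init_model_params(m, cfg, seed = cfg$seed + 3L)
  theta <- flatten_numeric(params)
  state <- adam_init(length(theta))
  trace <- matrix(NA_real_, cfg$epochs, 5L,
                  dimnames = list(NULL, c("zinb", "com", "con", "reg",
                                          "total")))
  best <- Inf; best_epoch <- 0L
  fw <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    params <- set_params_flat(params, theta)
    fw <- model_forward(params, data, cfg)
    if (!is.finite(fw$total))
      stop("divergent loss (non-finite) at epoch ", epoch)
    trace[epoch, ] <- c(fw$terms, fw$total)
    if (cfg$verbose)
      message(sprintf("epoch %3d  total %.5f  (zinb %.4f com %.4f con %.4f reg %.4f)",
                      epoch, fw$total, fw$terms[1], fw$terms[2],
                      fw$terms[3], fw$terms[4]))
    if (fw$total < best - cfg$early_stop_tol) {
      best <- fw$total; best_epoch <- epoch
    } else if (cfg$early_stop_patience > 0L &&
               epoch - best_epoch >= cfg$early_stop_patience) {
      trace <- trace[seq_len(epoch), , drop = FALSE]
      break
    }
    grads <- model_backward(fw, params, data, cfg)
    step <- adam_step(theta, flatten_numeric(grads), state,
                      lr = cfg$lr, weight_decay = cfg$weight_decay)
    theta <- step$theta
    state <- step$state
  }
  trace <- trace[!is.na(trace[, "total"]), , drop = FALSE]

  # --- final embedding + clustering ---------------------------------------
  params <- set_params_flat(params, theta)
  fw <- model_forward(params, data, cfg)
  Z <- fw$Z
  labels <- cluster_embedding(Z, cfg$n_clusters, seed = cfg$seed + 4L,
                              method = cfg$cluster_method)
  res_ari <- res_nmi <- NA_real_
  if (!is.null(ds$true_labels)) {
    res_ari <- ari(ds$true_labels, labels)
    res_nmi <- nmi(ds$true_labels, labels)
  }
  structure(list(
    loss_trace = data.frame(epoch = seq_len(nrow(trace)), trace),
    Z = Z, labels = labels, att_weights = fw$att_weights,
    ari = res_ari, nmi = res_nmi, k = k, r = r,
    epochs_run = nrow(trace), config = cfg),
    class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("train_result: %d spots, %d epochs, final loss %.4f\n",
              nrow(x$Z), x$epochs_run,
              x$loss_trace$total[nrow(x$loss_trace)]))
  if (!is.na(x$ari))
    cat(sprintf("  ARI %.3f  NMI %.3f\n", x$ari, x$nmi))
  invisible(x)
}

#' Cluster a latent embedding
#'
#' Default: k-means with k-means++ seeding (deterministic given `seed`).
#' `method = "gmm"` fits a Gaussian mixture (mclust) instead.
#'
#' @param Z N x d embedding matrix.
#' @param n_clusters Number of clusters, `1 <= n_clusters <= N`.
#' @param seed Seed for the initialization.
#' @param method `"kmeans"` or `"gmm"`.
#' @return Integer vector of 0-based cluster labels.
#' @export
cluster_embedding <- function(Z, n_clusters, seed = 0L,
                              method = c("kmeans", "gmm")) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n_clusters > n) stop("n_clusters (", n_clusters,
                           ") exceeds number of spots (", n, ")")
  if (n_clusters == 1L) return(rep(0L, n))
  if (n_clusters == n) return(seq_len(n) - 1L)
  if (method == "gmm") {
    # mclust resolves helper functions on the search path, so its
    # namespace is attached for the duration of the fit
    fit <- with_seed(seed, {
      if (!"package:mclust" %in% search()) {
        suppressMessages(attachNamespace("mclust"))
        on.exit(detach("package:mclust"), add = TRUE)
      }
      mclust::Mclust(Z, G = n_clusters, verbose = FALSE)
    })
    return(as.integer(fit$classification) - 1L)
  }
  centers <- kmeanspp_centers(Z, n_clusters, seed)
  km <- with_seed(seed, stats::kmeans(Z, centers = centers,
                                      iter.max = 100L))
  as.integer(km$cluster) - 1L
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
kmeanspp_centers <- function(Z, k, seed) {
  n <- nrow(Z)
  with_seed(seed, {
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    d2 <- colSums((t(Z) - Z[idx[1L], ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0)
        p <- rep(1 / n, n)
      idx[j] <- sample.int(n, 1L, prob = p)
      d2 <- pmin(d2, colSums((t(Z) - Z[idx[j], ])^2))
    }
    Z[idx, , drop = FALSE] + matrix(stats::rnorm(k * ncol(Z), sd = 1e-9),
                                    k)  # jitter guards duplicate centers
  })
}
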