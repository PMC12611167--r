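test_that("presets define the documented study conditions", {
  pr <- simulate_presets()
  expect_named(pr, c("easy", "medium", "hard"))
  for (p in pr) expect_s3_class(p, "sim_spec")
  expect_equal(pr$easy$n_rows * pr$easy$n_cols, 600)
  expect_equal(pr$easy$n_domains, 4)
  expect_equal(pr$easy$marker_fold, 8); expect_equal(pr$easy$pi0, 0.1)
  expect_equal(pr$medium$marker_fold, 3); expect_equal(pr$medium$pi0, 0.3)
  expect_equal(pr$hard$marker_fold, 2); expect_equal(pr$hard$pi0, 0.5)
  ds <- simulate_tissue(pr$easy)
  expect_equal(nrow(ds$counts), 600)
  expect_equal(length(unique(ds$true_labels)), 4)
})

test_that("simulation is reproducible and validates its spec", {
  s <- sim_spec(seed = 42)
  expect_identical(simulate_tissue(s)$counts, simulate_tissue(s)$counts)
  expect_error(sim_spec(n_domains = 50, n_rows = 10))
  expect_error(sim_spec(marker_fold = 1))
  expect_error(sim_spec(pi0 = 1))
})

test_that("domains are spatially contiguous on the lattice", {
  for (geom in c("horizontal_bands", "concentric")) {
    ds <- simulate_tissue(sim_spec(n_rows = 12, n_cols = 10,
                                   n_domains = 4, geometry = geom,
                                   n_genes = 30,
                                   n_markers_per_domain = 5, seed = 1))
    A <- radius_adjacency(ds$coords, 1.1)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    for (d in unique(ds$true_labels)) {
      sub <- igraph::induced_subgraph(g, which(ds$true_labels == d))
      expect_equal(igraph::components(sub)$no, 1)
    }
  }
})

test_that("the count model matches its stated moments", {
  # Poisson limit: pi0 = 0, huge theta -> variance/mean near 1
  ds <- simulate_tissue(sim_spec(n_rows = 100, n_cols = 100,
                                 n_domains = 2, n_genes = 3,
                                 n_markers_per_domain = 1,
                                 base_mu = 2, theta = 1e6, pi0 = 0,
                                 seed = 2))
  g3 <- ds$counts[, 3]  # non-marker gene
  expect_gt(var(g3) / mean(g3), 0.8)
  expect_lt(var(g3) / mean(g3), 1.25)

  # zero fraction for mu = 1, theta = 1, pi0 = 0.3:
  # 0.3 + 0.7 * NB(0) = 0.3 + 0.7 * 0.5 = 0.65
  x <- spadom:::with_seed(3, spadom:::rzinb(1e4, mu = 1, theta = 1,
                                            pi0 = 0.3))
  expect_equal(mean(x == 0), 0.65, tolerance = 0.02)

  # non-marker empirical mean -> (1 - pi0) * base_mu
  ds2 <- simulate_tissue(sim_spec(n_rows = 100, n_cols = 100,
                                  n_domains = 2, n_genes = 3,
                                  n_markers_per_domain = 1,
                                  base_mu = 2, theta = 2, pi0 = 0.2,
                                  seed = 4))
  expect_equal(mean(ds2$counts[, 3]), 0.8 * 2, tolerance = 0.02 * 1.6)
})

test_that("marker fold-change is recovered at preset sizes", {
  ds <- simulate_tissue(simulate_presets(seed = 5)$easy)
  spec <- simulate_presets(seed = 5)$easy
  nm <- spec$n_markers_per_domain
  for (d in 1:2) {
    g <- (d - 1) * nm + 1  # first marker of domain d
    inside <- mean(ds$counts[ds$true_labels == d, g])
    outside <- mean(ds$counts[ds$true_labels != d, g])
    expect_equal(inside / outside, spec$marker_fold, tolerance = 0.1)
  }
})

test_that("sampled counts are most likely under the true ZINB parameters", {
  hits <- 0; trials <- 40
  for (t in seq_len(trials)) {
    mu <- matrix(runif(200 * 10, 0.5, 5), 200, 10)
    x <- spadom:::with_seed(t, matrix(
      spadom:::rzinb(2000, mu = as.vector(mu), theta = 2, pi0 = 0.2),
      200, 10))
    th <- matrix(2, 200, 10); pim <- matrix(0.2, 200, 10)
    nll_true <- zinb_nll(x, list(pi = pim, mu = mu, theta = th))
    nll_wrong <- zinb_nll(x, list(pi = pim, mu = 2 * mu, theta = th))
    if (nll_true < nll_wrong) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.95)
})
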