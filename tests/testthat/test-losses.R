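test_that("zinb_decode applies the three link functions", {
  set.seed(1)
  n <- 6; d <- 3; m <- 5
  Z <- matrix(rnorm(n * d), n, d)
  w0 <- list(W_pi = matrix(0, d, m), b_pi = numeric(m),
             W_mu = matrix(0, d, m), b_mu = numeric(m),
             W_theta = matrix(0, d, m), b_theta = numeric(m))
  p <- zinb_decode(Z, weights = w0)
  expect_equal(p$pi, matrix(0.5, n, m), ignore_attr = TRUE)
  expect_equal(p$mu, matrix(1, n, m), ignore_attr = TRUE)
  expect_equal(p$theta, matrix(log(2), n, m), tolerance = 1e-6,
               ignore_attr = TRUE)
  # random heads: shapes and link ranges
  pr <- zinb_decode(Z, m_genes = m, seed = 2)
  expect_equal(dim(pr$pi), c(n, m))
  expect_true(all(pr$pi > 0 & pr$pi < 1))
  expect_true(all(pr$mu > 0))
  expect_true(all(pr$theta > 0))
})

test_that("zinb_nll matches hand-derived mixture values", {
  mk <- function(pi, mu, theta) list(pi = matrix(pi), mu = matrix(mu),
                                     theta = matrix(theta))
  # pi=0, x=0, mu=theta=1: NB(0) = 0.5
  expect_equal(zinb_nll(matrix(0), mk(0, 1, 1)), -log(0.5),
               tolerance = 1e-4)
  # pi=0.5, x=0: P = 0.5 + 0.5*0.5 = 0.75
  expect_equal(zinb_nll(matrix(0), mk(0.5, 1, 1)), -log(0.75),
               tolerance = 1e-4)
  # pi=0.5, x=1: P = 0.5 * 0.25
  expect_equal(zinb_nll(matrix(1), mk(0.5, 1, 1)), -log(0.125),
               tolerance = 1e-4)
  expect_error(zinb_nll(matrix(-1), mk(0.1, 1, 1)), "non-negative")
})

test_that("zinb_nll reduces to the NB likelihood as pi -> 0", {
  set.seed(3)
  x <- matrix(rpois(40, 3), 8, 5)
  mu <- matrix(runif(40, 0.5, 6), 8, 5)
  theta <- matrix(runif(40, 0.5, 4), 8, 5)
  ours <- zinb_nll(x, list(pi = mu * 0, mu = mu, theta = theta))
  oracle <- -mean(dnbinom(x, size = theta, mu = mu, log = TRUE))
  expect_equal(ours, oracle, tolerance = 1e-8)
})

test_that("the ZINB mixture is a proper distribution", {
  for (mu in c(0.5, 2, 10)) {
    for (theta in c(0.5, 1, 10)) {
      for (pi in c(0, 0.3, 0.7)) {
        x <- 0:500
        p <- exp(-vapply(x, function(xi)
          zinb_nll(matrix(xi), list(pi = matrix(pi), mu = matrix(mu),
                                    theta = matrix(theta))),
          numeric(1)))
        expect_gte(sum(p), 0.999)
      }
    }
  }
})

test_that("spatial regularization scores neighbour/non-neighbour pairs", {
  # orthonormal embedding rows: every cosine similarity is 0
  H <- diag(4)
  spec <- list(pos = rbind(c(1L, 2L), c(3L, 4L)),
               neg = rbind(c(1L, 3L), c(2L, 4L)))
  expect_equal(spatial_reg_loss(H, spec), log(2), tolerance = 1e-8)
  expect_gt(spatial_reg_loss(matrix(rnorm(12), 4), spec), 0)
  # moving a neighbour pair together decreases the loss
  H2 <- rbind(c(1, 0), c(0.9, 0.1), c(-1, 0.4), c(0.2, -1))
  spec2 <- list(pos = rbind(c(1L, 2L)), neg = rbind(c(1L, 3L)))
  closer <- rbind(c(1, 0), c(0.99, 0.01), c(-1, 0.4), c(0.2, -1))
  expect_lt(spatial_reg_loss(closer, spec2), spatial_reg_loss(H2, spec2))
  expect_error(spatial_reg_loss(rbind(c(0, 0), H2[-1, ]), spec2),
               "zero-norm")
})

test_that("spatial_reg_spec samples seeded non-neighbour pairs", {
  A <- knn_adjacency(cbind(seq_len(10), 0), 2)
  s1 <- spatial_reg_spec(A, n_neg = 3, seed = 4)
  s2 <- spatial_reg_spec(A, n_neg = 3, seed = 4)
  expect_identical(s1, s2)
  # positives are exactly the upper-triangle edges
  expect_equal(nrow(s1$pos), sum(A) / 2)
  # negatives avoid edges and self-pairs
  for (k in seq_len(nrow(s1$neg))) {
    i <- s1$neg[k, 1]; j <- s1$neg[k, 2]
    expect_equal(A[i, j], 0)
    expect_true(i != j)
  }
})

test_that("total_loss is the weighted sum of the four terms", {
  expect_equal(total_loss(0.1, 0.2, 0.3, 0.4), 1.0)
  expect_equal(total_loss(0.7, 9, 9, 9, lambda = c(1, 0, 0, 0)), 0.7)
  expect_equal(total_loss(0, 0, 0, 0), 0)
  expect_error(total_loss(1, 1, 1, 1, lambda = c(-1, 0, 0, 0)))
})
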