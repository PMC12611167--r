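test_that("spatial convolution treats the two graphs symmetrically", {
  set.seed(1)
  n <- 6; m <- 5
  X <- matrix(abs(rnorm(n * m)), n, m)
  A1 <- normalize_adjacency(knn_adjacency(matrix(rnorm(n * 2), n), 2))
  A2 <- normalize_adjacency(radius_adjacency(matrix(rnorm(n * 2), n), 2))
  w <- spadom:::init_stack(c(m, 4L), "relu", seed = 1)
  same <- spatial_conv(X, A1, A1, weights = list(s = w, s_a = w))
  expect_equal(same$Zs, same$Zs_a)
  expect_equal(same$Zs, same$Zs_joint)
  # joint embedding is the elementwise mean
  both <- spatial_conv(X, A1, A2, weights = list(s = w, s_a = w))
  expect_equal(both$Zs_joint, (both$Zs + both$Zs_a) / 2)
})

test_that("one-layer convolutions reduce to explicit matrix products", {
  # isolated nodes + identity weights: Zs = ReLU(X)
  X <- rbind(c(1, -2), c(3, 0.5))
  I2 <- diag(2)
  iso <- spatial_conv(X, I2, I2,
                      weights = list(s = list(W = list(I2), b = list(c(0, 0)),
                                              act = "relu"),
                                     s_a = list(W = list(I2),
                                                b = list(c(0, 0)),
                                                act = "relu")))
  expect_equal(iso$Zs, pmax(X, 0), ignore_attr = TRUE)
  # two-node complete graph averages the pair
  An <- normalize_adjacency(rbind(c(0, 1), c(1, 0)))
  two <- spatial_conv(rbind(1, 3), An, An,
                      weights = list(s = list(W = list(matrix(1)),
                                              b = list(0), act = "relu"),
                                     s_a = list(W = list(matrix(1)),
                                                b = list(0), act = "relu")))
  expect_equal(as.vector(two$Zs), c(2, 2))
})

test_that("feature convolution matches a dense oracle", {
  set.seed(2)
  n <- 15; m <- 8
  X <- matrix(abs(rnorm(n * m)) + 0.1, n, m)
  A <- normalize_adjacency(feature_adjacency(X, 4))
  w <- spadom:::init_stack(c(m, 6L, 4L), "relu", seed = 3)
  Zf <- feature_conv(X, A, weights = w)
  H1 <- pmax(A %*% X %*% w$W[[1]], 0)
  H2 <- pmax(A %*% H1 %*% w$W[[2]], 0)
  expect_equal(Zf, H2, tolerance = 1e-12, ignore_attr = TRUE)
  # permutation equivariance
  p <- sample.int(n)
  expect_equal(feature_conv(X[p, ], A[p, p], weights = w), Zf[p, ],
               tolerance = 1e-12)
})

test_that("co-convolution shares one weight set across graphs", {
  set.seed(3)
  n <- 8; m <- 6
  X <- matrix(abs(rnorm(n * m)), n, m)
  mk <- function(s) normalize_adjacency(
    knn_adjacency(matrix(rnorm(n * 2), n), s))
  A1 <- mk(2); A2 <- mk(3); A3 <- mk(2)
  w <- spadom:::init_stack(c(m, 4L), "relu", seed = 4)
  cc <- co_conv(X, A1, A2, A3, shared_weights = w)
  # identical graphs give identical branches
  same <- co_conv(X, A1, A1, A1, shared_weights = w)
  expect_equal(same$Zsc, same$Zfc)
  expect_equal(same$Zsc, same$Zc_joint)
  # swapping the spatial graphs swaps the branch outputs exactly
  sw <- co_conv(X, A2, A1, A3, shared_weights = w)
  expect_identical(sw$Zsc, cc$Zs_ac)
  expect_identical(sw$Zs_ac, cc$Zsc)
  # each branch equals an independent gcn stack with the shared weights
  expect_equal(cc$Zfc, gcn_layer(X, A3, w$W[[1]], w$b[[1]]),
               tolerance = 1e-12)
  expect_equal(cc$Zc_joint, (cc$Zsc + cc$Zs_ac + cc$Zfc) / 3)
})

test_that("consistency loss compares normalized Gram matrices", {
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(consistency_loss(Z, Z, Z), 0)
  # 2-node 1-dim worked example: Gram difference entries {0, 2}
  expect_equal(consistency_loss(rbind(1, 1), rbind(1, -1), rbind(1, 1)), 8)
  # differing pair structure gives a strictly positive penalty
  Z1 <- rbind(c(1, 0), c(0, 1), c(1, 0))
  Z2 <- rbind(c(1, 0), c(0, 1), c(0, 1))
  expect_gt(consistency_loss(Z1, Z2, Z1), 0)
  # scale invariance: Gram of row-normalized embeddings
  expect_equal(consistency_loss(Z, 5 * Z, Z), 0)
  expect_error(consistency_loss(rbind(c(0, 0), c(1, 0)),
                                rbind(c(1, 0), c(0, 1)),
                                rbind(c(1, 0), c(0, 1))), "zero-norm")
})

test_that("attention weights are a per-spot softmax across views", {
  set.seed(5)
  n <- 50; d <- 4
  V1 <- matrix(rnorm(n * d), n); V2 <- matrix(rnorm(n * d), n)
  V3 <- matrix(rnorm(n * d), n)
  att <- view_attention(V1, V2, V3, seed = 6)
  expect_equal(rowSums(att$weights), rep(1, n))
  expect_true(all(att$weights > 0 & att$weights < 1))
  # zero projection vector: all scores equal, weights exactly 1/3
  p0 <- spadom:::init_attention_params(d, seed = 7)
  p0$v <- p0$v * 0
  att0 <- view_attention(V1, V2, V3, params = p0)
  expect_equal(att0$weights, matrix(1 / 3, n, 3), ignore_attr = TRUE)
  expect_equal(att0$Z, (V1 + V2 + V3) / 3)
  # fused embedding lies in the per-spot convex hull of the views
  lo <- pmin(V1, V2, V3); hi <- pmax(V1, V2, V3)
  expect_true(all(att$Z >= lo - 1e-12 & att$Z <= hi + 1e-12))
})

test_that("hand-computed softmax of scores (1,0,0) is reproduced", {
  # saturated tanh scoring drives per-view scores to (1, 0, 0)
  n <- 3
  V1 <- matrix(20, n, 1); V2 <- matrix(0, n, 1); V3 <- matrix(0, n, 1)
  params <- list(W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0, v = 1)
  att <- view_attention(V1, V2, V3, params = params)
  expect_equal(att$weights[1, ], c(0.5761, 0.2119, 0.2119),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("equal-weight mode reproduces mean fusion bit-exactly", {
  set.seed(8)
  n <- 30; d <- 5
  V <- replicate(3, matrix(rnorm(n * d), n), simplify = FALSE)
  att <- view_attention(V[[1]], V[[2]], V[[3]], equal_weights = TRUE)
  expect_identical(att$Z, (V[[1]] + V[[2]] + V[[3]]) / 3)
  expect_identical(att$weights, matrix(1 / 3, n, 3))
})
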