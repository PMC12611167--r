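test_that("corrupt_features permutes rows reproducibly", {
  set.seed(1)
  X <- matrix(rnorm(50), 10, 5)
  Xc <- corrupt_features(X, seed = 3)
  expect_identical(Xc, corrupt_features(X, seed = 3))
  expect_false(identical(Xc, corrupt_features(X, seed = 4)))
  # multiset of rows and column means preserved exactly
  expect_equal(sort(as.vector(Xc)), sort(as.vector(X)))
  expect_equal(colMeans(Xc), colMeans(X))
  expect_identical(corrupt_features(X[1, , drop = FALSE], 1),
                   X[1, , drop = FALSE])
})

test_that("gcn_layer implements the normalized propagation rule", {
  # isolated node: operator is the 1x1 identity
  expect_equal(gcn_layer(matrix(2), matrix(1), diag(1),
                         activation = "identity"),
               matrix(2), ignore_attr = TRUE)
  # two-node complete graph: normalized operator is 0.5 everywhere
  An <- normalize_adjacency(rbind(c(0, 1), c(1, 0)))
  out <- gcn_layer(rbind(1, 3), An, matrix(1), activation = "identity")
  expect_equal(as.vector(out), c(2, 2))
  # ReLU clamps negatives
  expect_equal(as.vector(gcn_layer(matrix(-1), matrix(1), diag(1))), 0)
})

test_that("gdn_layer applies the inverse smoothing operator", {
  expect_equal(gdn_layer(matrix(2), matrix(1), diag(1),
                         activation = "identity"),
               matrix(2), ignore_attr = TRUE)
  An <- normalize_adjacency(rbind(c(0, 1), c(1, 0)))
  out <- gdn_layer(rbind(1, 3), An, matrix(1), activation = "identity")
  expect_equal(as.vector(out), c(0, 4))  # (2I - A_norm) %*% c(1,3)
})

test_that("deconvolution approximately inverts convolution", {
  set.seed(2)
  for (trial in 1:5) {
    n <- sample(4:12, 1)
    A <- matrix(rbinom(n * n, 1, 0.3), n, n)
    A <- pmin(A + t(A), 1); diag(A) <- 0
    An <- normalize_adjacency(A)
    L <- diag(n) - An
    H <- matrix(rnorm(n * 3), n, 3)
    Hc <- gcn_layer(H, An, diag(3), activation = "identity")
    Hd <- gdn_layer(Hc, An, diag(3), activation = "identity")
    # (I+L)(I-L) = I - L^2: the roundtrip error is bounded by ||L||^2 ||H||
    nrm <- function(M) sqrt(sum(M^2))
    L2 <- max(abs(eigen(L, symmetric = TRUE,
                        only.values = TRUE)$values))
    expect_lte(nrm(Hd - H), L2^2 * nrm(H) + 1e-10)
  }
})

test_that("contrastive loss follows the hinged triplet form", {
  h <- rbind(c(1, 0), c(0, 1))
  h_orth <- rbind(c(0, 1), c(1, 0))
  # positive identical, negative orthogonal: max(0, 0.5 - 1 + 0) = 0
  expect_equal(contrastive_loss(h, h, h_orth, alpha = 0.5), 0)
  # s_pos == s_neg: loss collapses to alpha
  expect_equal(contrastive_loss(h, h_orth, h_orth, alpha = 0.3), 0.3)
  # s_pos = 0, s_neg = 1: 0.5 + 1 = 1.5
  expect_equal(contrastive_loss(h, h_orth, h, alpha = 0.5), 1.5)
  # literal (unhinged) form for audit
  expect_equal(contrastive_loss(h, h, h_orth, alpha = 0.5,
                                form = "literal"), 1.5)
  expect_error(contrastive_loss(rbind(c(0, 0)), rbind(c(1, 0)),
                                rbind(c(0, 1)), 0.5), "zero-norm")
  # non-negativity on random inputs
  set.seed(3)
  for (i in 1:20) {
    a <- matrix(rnorm(12), 4); p <- matrix(rnorm(12), 4)
    ng <- matrix(rnorm(12), 4)
    expect_gte(contrastive_loss(a, p, ng, alpha = 0.5), 0)
  }
})

test_that("the contrastive encoder returns consistent shapes and losses", {
  set.seed(4)
  n <- 8; m <- 12
  X <- matrix(abs(rnorm(n * m)) + 0.1, n, m)
  A <- normalize_adjacency(feature_adjacency(X, 3))
  Xc <- corrupt_features(X, seed = 1)
  res <- run_contrastive_encoder(X, Xc, A, dims = c(6L, 4L), seed = 2)
  expect_equal(dim(res$H_orig), c(n, 4))
  expect_equal(dim(res$H_aug), c(n, 4))
  expect_equal(dim(res$recon_orig), c(n, m))
  expect_gte(res$L_com, 0)
  # when positive and negative similarities collapse the hinge returns
  # the margin exactly, hence 0 at zero margin
  h <- res$H_orig
  expect_equal(contrastive_loss(h, h, h, alpha = 0), 0)
  expect_equal(contrastive_loss(h, h, h, alpha = 0.5), 0.5)
})

test_that("the encoder is permutation-equivariant", {
  set.seed(5)
  n <- 7; m <- 9
  X <- matrix(abs(rnorm(n * m)) + 0.1, n, m)
  A <- normalize_adjacency(feature_adjacency(X, 2))
  p <- sample.int(n)
  params <- spadom:::init_contrastive_params(m, c(5L, 3L), seed = 6)
  H <- spadom:::stack_forward(X, A, params$enc0)
  Hp <- spadom:::stack_forward(X[p, ], A[p, p], params$enc0)
  expect_equal(Hp$H[[3]], H$H[[3]][p, ], tolerance = 1e-12)
})
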