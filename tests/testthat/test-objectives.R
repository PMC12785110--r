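test_that("similarity matrix is a unit-diagonal Gaussian kernel", {
  emb <- rbind(c(0, 0), c(1, 0), c(0, 0))
  S <- similarity_matrix(emb)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 2], exp(-1))   # squared distance 1
  expect_equal(S[1, 3], 1)         # identical embeddings
  expect_identical(S, t(S))
  # euclid variant exponentiates the unsquared distance
  S2 <- similarity_matrix(rbind(c(0, 0), c(2, 0)), similarity = "euclid")
  expect_equal(S2[1, 2], exp(-2))
  expect_error(similarity_matrix(matrix(NaN, 2, 2)), "finite")
})

test_that("clustering divergence loss hits its closed-form anchors", {
  # orthogonal hard assignments with identity similarity: zero loss
  Y <- rbind(c(1, 0), c(0, 1))
  expect_equal(clustering_divergence_loss(Y, diag(2)), 0)
  # identical per-class logit rows: every pairwise ratio is 1 -> (k-1)/2
  set.seed(1)
  emb <- matrix(rnorm(6), 3, 2)
  S <- similarity_matrix(emb)
  for (k in 2:4) {
    Yk <- matrix(rep(rnorm(3), k), 3, k)
    expect_equal(clustering_divergence_loss(Yk, S), (k - 1) / 2)
  }
  # invariant to class relabeling
  set.seed(2)
  Yr <- matrix(rnorm(12), 4, 3)
  Sr <- similarity_matrix(matrix(rnorm(8), 4, 2))
  expect_equal(clustering_divergence_loss(Yr, Sr),
               clustering_divergence_loss(Yr[, c(3, 1, 2)], Sr))
})

test_that("separated clusters assigned to distinct classes lower L1", {
  # two tight, well-separated clusters: class-per-cluster assignment
  # scores below the merged (identical columns) assignment
  emb <- rbind(matrix(rnorm(10, 0, .1), 5, 2),
               matrix(rnorm(10, 10, .1), 5, 2))
  S <- similarity_matrix(emb)
  split <- cbind(c(rep(5, 5), rep(0, 5)), c(rep(0, 5), rep(5, 5)))
  merged <- cbind(rep(5, 10), rep(5, 10))
  expect_lt(clustering_divergence_loss(split, S),
            clustering_divergence_loss(merged, S))
})

test_that("cross-entropy matches hand values and stays non-negative", {
  expect_equal(cross_entropy_loss(matrix(0, 1, 2), matrix(c(1, 0), 1, 2)),
               log(2))
  # confident correct logits drive the loss to zero
  expect_lt(cross_entropy_loss(matrix(c(30, 0), 1, 2),
                               matrix(c(1, 0), 1, 2)), 1e-10)
  set.seed(3)
  for (i in 1:5) {
    L <- matrix(rnorm(12), 4, 3)
    oh <- diag(3)[sample(3, 4, replace = TRUE), ]
    expect_gte(cross_entropy_loss(L, oh), 0)
  }
  expect_error(cross_entropy_loss(matrix(0, 1, 2), 3, classes = NULL),
               "1..k")
})

test_that("distillation loss anchors: identity, temperature, hand value", {
  set.seed(4)
  L <- matrix(rnorm(10), 5, 2)
  expect_equal(distillation_loss(L, L), 0)
  # k=2, teacher (1,0), student (0,1), T=1: KL ~ 0.462
  expect_equal(distillation_loss(matrix(c(0, 1), 1, 2),
                                 matrix(c(1, 0), 1, 2), T = 1),
               0.4621, tolerance = 1e-3)
  # tempered distributions flatten as T grows
  expect_lt(distillation_loss(L, L + 1, T = 1000),
            distillation_loss(L, L + 1, T = 1) + 1e-12)
  expect_lt(distillation_loss(L, L + 1, T = 1000), 1e-5)
  expect_error(distillation_loss(L, L, T = 0), "T must be")
})

test_that("self-entropy loss matches hand values in all modes", {
  expect_equal(self_entropy_loss(matrix(0, 3, 4)), 0)
  # k=2, mean logits (1,0): -(1/2) * 1 * ln(0.731) ~ 0.1566
  Y <- matrix(c(1, 0), 1, 2)
  expect_equal(self_entropy_loss(Y), 0.1566, tolerance = 1e-3)
  # invariant to cell order
  set.seed(5)
  L <- matrix(rnorm(12), 4, 3)
  for (m in c("literal", "mean_entropy", "sample_entropy"))
    expect_equal(self_entropy_loss(L, mode = m),
                 self_entropy_loss(L[c(3, 1, 4, 2), ], mode = m))
  # sample entropy is bounded by ln k
  expect_lte(self_entropy_loss(L, mode = "sample_entropy"), log(3))
})

test_that("analytic gradients of all four losses match finite differences", {
  set.seed(6)
  N <- 5; k <- 3
  L <- matrix(rnorm(N * k), N, k)
  emb <- matrix(rnorm(N * 4), N, 4)
  S <- similarity_matrix(emb)
  oh <- diag(k)[sample(k, N, replace = TRUE), ]
  tl <- matrix(rnorm(N * k), N, k)

  cl <- clustering_divergence_loss(L, S, grad = TRUE)
  expect_equal(cl$d_logits,
               fd_grad(function(v) clustering_divergence_loss(v, S), L),
               tolerance = 1e-4)
  demb <- plkd:::similarity_backward(emb, S, cl$d_S)
  expect_equal(demb,
               fd_grad(function(v)
                 clustering_divergence_loss(L, similarity_matrix(v)), emb),
               tolerance = 1e-4)
  ce <- cross_entropy_loss(L, oh, grad = TRUE)
  expect_equal(ce$d_logits,
               fd_grad(function(v) cross_entropy_loss(v, oh), L),
               tolerance = 1e-4)
  kd <- distillation_loss(L, tl, T = 3, grad = TRUE)
  expect_equal(kd$d_logits,
               fd_grad(function(v) distillation_loss(v, tl, T = 3), L),
               tolerance = 1e-4)
  for (m in c("literal", "mean_entropy", "sample_entropy")) {
    se <- self_entropy_loss(L, mode = m, grad = TRUE)
    expect_equal(se$d_logits,
                 fd_grad(function(v) self_entropy_loss(v, mode = m), L),
                 tolerance = 1e-4)
  }
})
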