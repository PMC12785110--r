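test_that("attention weights are row-normalized and symmetry-preserving", {
  set.seed(1)
  p <- teacher_init(5, c("a", "b"), m = 3, h = 4)
  toks <- matrix(rnorm(4 * 4), 4, 4)
  at <- self_attention_layer(toks, p$attn)
  for (W in at$weights)
    expect_equal(rowSums(W), rep(1, 4), tolerance = 1e-6)
  # all tokens identical -> all output rows identical
  same <- matrix(rep(rnorm(4), each = 4), 4, 4)
  o <- self_attention_layer(same, p$attn)$output
  expect_equal(o[1, ], o[2, ], tolerance = 1e-12)
  expect_equal(o[1, ], o[4, ], tolerance = 1e-12)
  # single token: softmax over one element is 1
  one <- matrix(rnorm(4), 1, 4)
  a1 <- self_attention_layer(one, p$attn, d_head = 2)
  expect_equal(drop(a1$weights[[1]]), 1)
  expect_error(self_attention_layer(matrix(NaN, 2, 4), p$attn), "finite")
})

test_that("teacher forward has contracted shapes and is deterministic", {
  set.seed(2)
  p <- teacher_init(8, c("a", "b", "c"), m = 4, h = 6)
  x <- rnorm(8)
  o1 <- teacher_forward(x, p)
  o2 <- teacher_forward(x, p)
  expect_length(o1$logits, 3)
  expect_length(o1$embedding, 6)
  expect_equal(dim(o1$updated_tokens), c(4L, 6L))
  expect_identical(o1$logits, o2$logits)
  # zero input: all pattern tokens zero, embedding driven by cls alone
  oz <- teacher_forward(rep(0, 8), p)
  tk <- plkd:::teacher_forward_batch(p, matrix(0, 1, 8))$tokens
  expect_true(all(tk == 0))
})

test_that("permuting pattern positions permutes tokens and fixes the embedding", {
  set.seed(3)
  p <- teacher_init(8, c("a", "b"), m = 4, h = 6)
  x <- rnorm(8)
  base <- teacher_forward(x, p)
  perm <- c(3, 1, 4, 2)
  p2 <- p
  p2$navigator$W <- p$navigator$W[perm]
  out <- teacher_forward(x, p2)
  expect_equal(out$updated_tokens, base$updated_tokens[perm, ],
               tolerance = 1e-12)
  expect_equal(out$embedding, base$embedding, tolerance = 1e-12)
  expect_equal(out$logits, base$logits, tolerance = 1e-12)
})

test_that("teacher backward matches central finite differences", {
  set.seed(4)
  n <- 6; m <- 3; h <- 4; N <- 5
  p <- teacher_init(n, c("a", "b"), m = m, h = h)
  X <- matrix(rnorm(N * n), N, n)
  oh <- diag(2)[sample(2, N, replace = TRUE), ]
  lossfn <- function(pp) {
    fw <- plkd:::teacher_forward_batch(pp, X)
    S <- similarity_matrix(fw$embedding)
    clustering_divergence_loss(fw$logits, S) +
      cross_entropy_loss(fw$logits, oh)
  }
  fw <- plkd:::teacher_forward_batch(p, X, keep = TRUE)
  S <- similarity_matrix(fw$embedding)
  cl <- clustering_divergence_loss(fw$logits, S, grad = TRUE)
  ce <- cross_entropy_loss(fw$logits, oh, grad = TRUE)
  gr <- plkd:::teacher_backward_batch(
    p, fw$cache, cl$d_logits + ce$d_logits,
    plkd:::similarity_backward(fw$embedding, S, cl$d_S))
  for (spec in list(
    list(\(q) q$navigator$W[[2]], \(q, v) { q$navigator$W[[2]] <- v; q },
         gr$navigator$W[[2]]),
    list(\(q) q$cls, \(q, v) { q$cls <- v; q }, gr$cls),
    list(\(q) q$attn$Wq, \(q, v) { q$attn$Wq <- v; q }, gr$attn$Wq),
    list(\(q) q$attn$Wo, \(q, v) { q$attn$Wo <- v; q }, gr$attn$Wo),
    list(\(q) q$attn$heads[[1]]$Wk,
         \(q, v) { q$attn$heads[[1]]$Wk <- v; q }, gr$attn$heads[[1]]$Wk),
    list(\(q) q$classifier$W, \(q, v) { q$classifier$W <- v; q },
         gr$classifier$W))) {
    num <- fd_grad(function(v) lossfn(spec[[2]](p, v)), spec[[1]](p))
    expect_equal(spec[[3]], num, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("gradients reach every unmasked navigator entry", {
  set.seed(5)
  sets <- gene_set_collection(list(a = paste0("G", 1:4),
                                   b = paste0("G", 3:8)))
  km <- build_knowledge_mask(paste0("G", 1:8), sets)
  p <- teacher_init(8, c("x", "y"), mask = km, h = 4)
  X <- matrix(abs(rnorm(6 * 8)) + 0.5, 6, 8)
  oh <- diag(2)[rep(1:2, 3), ]
  fw <- plkd:::teacher_forward_batch(p, X, keep = TRUE)
  ce <- cross_entropy_loss(fw$logits, oh, grad = TRUE)
  gr <- plkd:::teacher_backward_batch(p, fw$cache, ce$d_logits)
  for (j in 1:2) {
    gW <- gr$navigator$W[[j]]
    expect_true(all(gW[km$mask[, j] == 1, ] != 0))
    expect_true(all(gW[km$mask[, j] == 0, ] == 0))
  }
})

test_that("the default Student is far lighter than a GMT-scale Teacher", {
  # at a realistic pathway collection (300 sets) over 2000 genes the
  # Teacher carries ~29M parameters, the Student well under 5% of that
  set.seed(6)
  te <- teacher_init(2000, paste0("t", 1:22), m = 300, h = 48)
  st <- student_init(2000, paste0("t", 1:22))
  expect_lt(teacher_n_params(st) / teacher_n_params(te), 0.05)
})
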