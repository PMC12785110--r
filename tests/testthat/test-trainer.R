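small_norm <- function(seed = 1, ...) {
  s <- small_sim(seed = seed, ...)
  list(sim = s, norm = normalize_log1p(s$expression))
}

test_that("cosine schedule starts at lr_init and decays below 1%", {
  expect_equal(cosine_lr(0, 48, 0.1), 0.1)
  expect_lte(cosine_lr(47, 48, 0.1), 0.001 * 1.1)
  # monotone decreasing over the run
  lrs <- cosine_lr(0:47, 48, 0.1)
  expect_true(all(diff(lrs) < 0))
})

test_that("training is bitwise deterministic under a fixed seed", {
  d <- small_norm(seed = 11)
  cfg <- train_config(epochs = 2, batch_size = 64, seed = 5, m = 4)
  t1 <- train_teacher(d$norm, cfg)
  t2 <- train_teacher(d$norm, cfg)
  expect_identical(t1$loss_log, t2$loss_log)
  expect_identical(t1$navigator$W, t2$navigator$W)
  s1 <- train_student(d$norm, t1, cfg)
  s2 <- train_student(d$norm, t2, cfg)
  expect_identical(s1$loss_log, s2$loss_log)
})

test_that("teacher loss decreases over epochs (at most one small uptick)", {
  d <- small_norm(seed = 12)
  cfg <- train_config(epochs = 5, batch_size = 64, seed = 2, m = 4)
  te <- train_teacher(d$norm, cfg)
  tot <- te$loss_log$total
  upticks <- sum(diff(tot) > 0.05 * abs(tot[-length(tot)]))
  expect_lte(upticks, 1)
  expect_lt(tot[length(tot)], tot[1])
})

test_that("teacher learns the planted types on a small simulation", {
  d <- small_norm(seed = 13)
  mask <- build_knowledge_mask(d$norm$gene_names, d$sim$planted_sets)
  cfg <- train_config(epochs = 4, batch_size = 64, seed = 3)
  te <- train_teacher(d$norm, cfg, mask = mask)
  expect_gte(accuracy_on(te, d$norm), 0.9)
  # student distilled from it stays close
  st <- train_student(d$norm, te, cfg)
  expect_gte(accuracy_on(st, d$norm), 0.85)
})

test_that("a constant-logit teacher distills into a constant student", {
  d <- small_norm(seed = 14)
  set.seed(1)
  te <- teacher_init(ncol(d$norm$values), c("type1", "type2", "type3"),
                     m = 3, h = 4)
  te$classifier$W[] <- 0
  te$classifier$b <- c(2, -1, 0.5)
  te$gene_names <- d$norm$gene_names
  cfg <- train_config(epochs = 4, batch_size = 64, seed = 3, lambda4 = 0)
  st <- train_student(d$norm, te, cfg)
  expect_lt(st$loss_log$L3[4], 0.01)
  # student tempered probabilities hug the teacher's constant distribution
  sl <- student_forward(d$norm$values, st)
  ps <- plkd:::softmax_rows(sl / 3)
  pt <- drop(plkd:::softmax_rows(matrix(c(2, -1, 0.5) / 3, 1)))
  expect_lt(mean(abs(sweep(ps, 2, pt))), 0.05)
  expect_lt(max(abs(sweep(ps, 2, pt))), 0.15)
})

test_that("prediction obeys the tie-break, softmax and permutation contracts", {
  set.seed(4)
  st <- student_init(5, c("a", "b", "c"), hidden = integer(0))
  st$layers[[1]]$W[] <- 0   # all logits zero
  X <- expression_matrix(matrix(abs(rnorm(15)), 3, 5), normalized = TRUE)
  st$gene_names <- X$gene_names
  pr <- predict_cells(st, X)
  expect_true(all(pr$predicted_type == "a"))  # lowest class index on ties
  probs <- as.matrix(pr[, grepl("^prob_", names(pr))])
  expect_equal(unname(rowSums(probs)), rep(1, 3))
  expect_equal(unname(probs[1, ]), rep(1 / 3, 3))
  # row permutation of X permutes the output identically
  set.seed(5)
  st2 <- student_init(5, c("a", "b"), hidden = integer(0))
  X2 <- expression_matrix(matrix(abs(rnorm(40)), 8, 5), normalized = TRUE)
  st2$gene_names <- X2$gene_names
  p1 <- predict_cells(st2, X2)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  p2 <- predict_cells(st2, subset_cells(X2, perm))
  expect_equal(p2$predicted_type, p1$predicted_type[perm])
  # unaligned gene space is refused with a pointer to align_genes
  X3 <- X2; X3$gene_names <- rev(X3$gene_names)
  expect_error(predict_cells(st2, X3), "align_genes")
})

test_that("embeddings have width h and are identical for identical cells", {
  d <- small_norm(seed = 15)
  set.seed(1)
  te <- teacher_init(ncol(d$norm$values), c("x", "y"), m = 3, h = 12)
  te$gene_names <- d$norm$gene_names
  dup <- subset_cells(d$norm, c(1, 1, 2))
  dup$cell_ids <- c("a", "b", "c")
  emb <- embed_cells(te, dup)
  expect_equal(ncol(emb), 12)
  expect_equal(emb[1, ], emb[2, ])
})

test_that("training refuses degenerate label sets", {
  d <- small_norm(seed = 16)
  d$norm$cell_type <- rep("only", nrow(d$norm$values))
  expect_error(train_teacher(d$norm, train_config(epochs = 1, m = 2)),
               "at least 2 classes")
})
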