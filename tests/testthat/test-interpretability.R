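test_that("pattern gene sets select strictly-above-mean row scores", {
  W <- rbind(c(2, 3), c(1, 0), c(0, 0))  # row sums 5, 1, 0; mean 2
  ps <- extract_pattern_gene_set(W, c("g1", "g2", "g3"), 1)
  expect_equal(ps$genes, "g1")
  expect_equal(ps$threshold, 2)
  # all rows equal: nothing strictly exceeds the mean
  expect_warning(
    ps0 <- extract_pattern_gene_set(matrix(1, 3, 2), c("a", "b", "c")),
    "no gene")
  expect_length(ps0$genes, 0)
  # masked (all-zero) rows can never win over positive unmasked rows
  Wm <- rbind(c(0, 0), c(4, 4), c(3, 1))
  psm <- extract_pattern_gene_set(Wm, c("masked", "g2", "g3"))
  expect_false("masked" %in% psm$genes)
})

test_that("enrichment p-values match the exact hypergeometric tail", {
  universe <- paste0("G", 1:10)
  coll <- gene_set_collection(list(hit = paste0("G", 1:5),
                                   miss = paste0("G", 6:8)))
  e <- enrich_gene_set(paste0("G", 1:5), coll, universe)
  expect_equal(e$p_value[e$pathway == "hit"], 1 / choose(10, 5))
  expect_equal(e$p_value[e$pathway == "miss"], 1)
  expect_true(all(e$p_value >= 0 & e$p_value <= 1))
  expect_true(all(c("q_value") %in% names(e)))
  expect_error(enrich_gene_set(character(0), coll, universe), "empty")
  expect_error(enrich_gene_set("ZZ", coll, universe), "outside")
})

test_that("pattern ranking finds planted location shifts and truncates", {
  set.seed(1)
  n_cells <- 60; m <- 4; h <- 3
  labels <- rep(c("A", "B"), each = n_cells / 2)
  tokens <- array(rnorm(n_cells * m * h), dim = c(n_cells, m, h))
  tokens[labels == "A", 2, ] <- tokens[labels == "A", 2, ] + 3
  r <- rank_patterns_by_type(tokens, labels)
  expect_equal(r$pattern[r$cell_type == "A" & r$rank == 1], "pattern2")
  # m = 4 returns all four per type
  expect_equal(sum(r$cell_type == "A"), 4)
  # deterministic
  expect_identical(r, rank_patterns_by_type(tokens, labels))
  # tiny types are skipped with a warning
  lab2 <- c(rep("A", 2), rep("B", n_cells - 2))
  expect_warning(r2 <- rank_patterns_by_type(tokens, lab2), "fewer than 3")
  expect_false("A" %in% r2$cell_type)
})

test_that("gene graph takes top-2 genes per pattern and thresholds cosine", {
  set.seed(2)
  te <- teacher_init(30, c("a", "b"), m = 10, h = 6)
  te$gene_names <- paste0("G", 1:30)
  gg <- build_gene_graph(te, 1:10)
  expect_lte(length(gg$genes), 20)
  expect_false(any(igraph::which_loop(gg$graph)))
  # tau = 1 leaves no edges (cosine similarity <= 1, ties only for
  # identical directions)
  gg1 <- build_gene_graph(te, 1:10, tau = 1)
  expect_equal(igraph::ecount(gg1$graph), 0)
  expect_error(build_gene_graph(te, integer(0)), "non-empty")
})

test_that("centralities match closed forms on a path and a triangle", {
  path <- igraph::make_graph(~ a - b, b - c)
  cs <- centrality_scores(path)
  expect_equal(cs$betweenness[match(c("a", "b", "c"), cs$gene)],
               c(0, 1, 0))
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("x", "y", "z")
  ct <- centrality_scores(tri)
  expect_equal(ct$degree, rep(2, 3))
  expect_equal(ct$pagerank, rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(sum(ct$pagerank), 1, tolerance = 1e-10)
  # singleton graph: all centralities defined
  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "solo"
  c1 <- centrality_scores(single)
  expect_equal(c1$degree, 0)
  expect_equal(c1$pagerank, 1)
})

test_that("Q statistic is a mean-rank consensus with average-rank ties", {
  sc <- data.frame(gene = c("top", "mid", "twin1", "twin2"),
                   degree = c(5, 3, 2, 2), betweenness = c(1, .5, .1, .1),
                   eigenvector = c(1, .4, .2, .2), pagerank = c(.5, .3, .1, .1),
                   closeness = c(1, .7, .2, .2))
  q <- q_aggregate(sc)
  expect_equal(q$gene[1], "top")
  expect_equal(q$Q[1], 1)
  expect_equal(q$Q[q$gene == "twin1"], q$Q[q$gene == "twin2"])
  expect_true(all(q$Q >= 1 & q$Q <= 4))
})

test_that("shap attribution is exact on linear students", {
  set.seed(3)
  st <- student_init(6, c("a", "b"), hidden = integer(0))
  bg <- matrix(rnorm(20 * 6), 20, 6)
  x <- rnorm(6)
  phi <- shap_attribution(st, bg, x, 2)
  expect_equal(unname(phi), st$layers[[1]]$W[, 2] * (x - colMeans(bg)),
               tolerance = 1e-12)
  # completeness: sum of attributions telescopes to f(x) - f(background)
  f_gap <- unname(student_forward(x, st)[2]) -
    mean(student_forward(bg, st)[, 2])
  expect_equal(sum(phi), f_gap, tolerance = 1e-6)
  # linearity across summed linear heads
  st2 <- st
  st2$layers[[1]]$W <- matrix(rnorm(12), 6, 2)
  st_sum <- st
  st_sum$layers[[1]]$W <- st$layers[[1]]$W + st2$layers[[1]]$W
  expect_equal(shap_attribution(st_sum, bg, x, 1),
               shap_attribution(st, bg, x, 1) +
                 shap_attribution(st2, bg, x, 1), tolerance = 1e-10)
})

test_that("shap attribution tracks exact Shapley on a small ReLU net", {
  set.seed(5)
  st <- student_init(5, c("a", "b"), hidden = 8)
  bg <- matrix(rnorm(40 * 5), 40, 5)
  x <- rnorm(5)
  phi <- shap_attribution(st, bg, x, 1)
  exact <- oracle_shapley(function(z) student_forward(z, st)[1], x, bg)
  # >= 0.9 up to floating-point rounding of the rank correlation
  expect_gte(cor(phi, exact, method = "spearman"), 0.9 - 1e-9)
  # dummy gene: zero first-layer weights give exactly zero attribution
  st$layers[[1]]$W[3, ] <- 0
  expect_equal(unname(shap_attribution(st, bg, x, 1)[3]), 0)
})

test_that("per-type shap ranking and consensus behave as set operations", {
  set.seed(6)
  st <- student_init(6, c("a", "b"), hidden = integer(0))
  st$gene_names <- paste0("G", 1:6)
  X <- matrix(abs(rnorm(8 * 6)) + 0.2, 8, 6,
              dimnames = list(NULL, st$gene_names))
  pred <- rep(c("a", "b"), 4)
  # single predicted cell: ranking equals that cell's own |phi| order
  one <- top_shap_genes(st, X[1, , drop = FALSE], "a", "a",
                        background = X)
  phi1 <- abs(shap_attribution(st, X, X[1, ], 1))
  expect_equal(one$gene, names(sort(phi1, decreasing = TRUE)))
  # fewer than top_n genes: all returned
  expect_equal(nrow(top_shap_genes(st, X, pred, "a", top_n = 10)), 6)
  expect_error(top_shap_genes(st, X, pred, "zz"), "no cells")
  # consensus
  expect_warning(cz <- consensus_genes(c("A", "B"), c("C", "D")), "disjoint")
  expect_length(cz, 0)
  expect_equal(consensus_genes(c("A", "B", "C"), c("C", "A")), c("C", "A"))
  res <- consensus_genes(c("A", "C"), c("C", "B", "A"))
  expect_true(all(res %in% c("A", "C")))
  expect_equal(res, c("C", "A"))
})

test_that("a dominant planted weight surfaces as the top shap gene", {
  set.seed(7)
  st <- student_init(5, c("a", "b"), hidden = integer(0))
  st$layers[[1]]$W[, 1] <- c(10, 0.1, 0.1, 0.1, 0.1)
  st$gene_names <- paste0("G", 1:5)
  X <- matrix(abs(rnorm(6 * 5)) + 0.5, 6, 5)
  out <- top_shap_genes(st, X, rep("a", 6), "a")
  expect_equal(out$gene[1], "G1")
})
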