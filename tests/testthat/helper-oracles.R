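# independent oracles used across test files

# central finite-difference gradient of a scalar function of a matrix/vector
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# brute-force confusion-matrix metrics by direct counting
oracle_metrics <- function(true, pred) {
  classes <- sort(unique(true))
  f1s <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (true[i] == cl && pred[i] == cl) tp <- tp + 1
      if (true[i] != cl && pred[i] == cl) fp <- fp + 1
      if (true[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    P <- if (tp + fp > 0) tp / (tp + fp) else 0
    R <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[ci] <- if (P + R > 0) 2 * P * R / (P + R) else 0
  }
  list(accuracy = sum(true == pred) / length(true), macro_f1 = mean(f1s))
}

# exact Shapley values by enumerating all 2^p coalitions with
# mean-imputation of absent features
oracle_shapley <- function(f, x, background) {
  p <- length(x)
  xbar <- colMeans(background)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    for (bits in 0:(2^p - 1)) {
      S <- which(bitwAnd(bits, 2^(seq_len(p) - 1)) > 0)
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      z0 <- xbar; z0[S] <- x[S]
      z1 <- z0; z1[j] <- x[j]
      phi[j] <- phi[j] + w * (f(z1) - f(z0))
    }
  }
  phi
}

# nearest-centroid classifier on log1p counts (learnability oracle)
nearest_centroid_acc <- function(counts, labels) {
  X <- log1p(counts)
  types <- unique(labels)
  cent <- t(vapply(types, function(t) colMeans(X[labels == t, , drop = FALSE]),
                   numeric(ncol(X))))
  d <- outer(rowSums(X^2), rowSums(cent^2), "+") - 2 * X %*% t(cent)
  mean(types[apply(d, 1, which.min)] == labels)
}

# small fast simulation for unit tests
small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 120, n_cells = 240, n_types = 3, n_batches = 2,
         n_pathways = 6, genes_per_pathway = 15, type_effect = 2,
         batch_shift_sd = 0.2, seed = seed), list(...))
  simulate_cells(do.call(simulation_config, args))
}
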