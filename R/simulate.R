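#' Simulation configuration
#'
#' Parameters of the negative-binomial single-cell count simulator with
#' planted gene modules (pathways), cell-type activity and batch shifts.
#'
#' The generative model for gene g of cell i (type t, batch b) is
#' `count ~ NB(mu, size = nb_dispersion)` with
#' `mu = base_mean * exp(type_activity + batch_offset + marker_effect)`:
#' `type_activity = type_effect` when g belongs to a module assigned to t
#' (0 otherwise), `batch_offset ~ N(0, batch_shift_sd)` drawn once per
#' (batch, gene), and each type additionally owns `markers_per_type`
#' dedicated marker genes inside its first module boosted by
#' `marker_effect` log-units in that type.
#'
#' @param n_genes,n_cells,n_types,n_batches,n_pathways,genes_per_pathway
#'   Counts (all >= 1).
#' @param type_effect Log-fold activity of a type's active modules (>= 0).
#' @param batch_shift_sd SD of per-(batch, gene) log-scale offsets.
#' @param nb_dispersion NB dispersion; variance = mu + mu^2/dispersion.
#' @param base_mean Baseline expression mean.
#' @param markers_per_type Planted high-effect marker genes per type.
#' @param marker_effect Extra log-fold change of a marker in its own type.
#' @param overlap Allow modules to share genes (sampled with replacement
#'   across modules); by default modules are disjoint.
#' @param seed Integer RNG seed.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 1000, n_cells = 2000, n_types = 4,
                              n_batches = 2, n_pathways = 20,
                              genes_per_pathway = 25, type_effect = 2,
                              batch_shift_sd = 0.3, nb_dispersion = 2,
                              base_mean = 1, markers_per_type = 1,
                              marker_effect = 3, overlap = FALSE, seed = 1) {
  cfg <- list(n_genes = n_genes, n_cells = n_cells, n_types = n_types,
              n_batches = n_batches, n_pathways = n_pathways,
              genes_per_pathway = genes_per_pathway,
              type_effect = type_effect, batch_shift_sd = batch_shift_sd,
              nb_dispersion = nb_dispersion, base_mean = base_mean,
              markers_per_type = markers_per_type,
              marker_effect = marker_effect, overlap = isTRUE(overlap),
              seed = as.integer(seed))
  counts <- c("n_genes", "n_cells", "n_types", "n_batches", "n_pathways",
              "genes_per_pathway")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      stop(f, " must be a count >= 1")
  if (cfg$type_effect < 0) stop("type_effect must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$batch_shift_sd < 0) stop("batch_shift_sd must be >= 0")
  if (!cfg$overlap && cfg$n_pathways * cfg$genes_per_pathway > cfg$n_genes)
    stop("n_pathways * genes_per_pathway exceeds n_genes with ",
         "non-overlapping modules; set overlap = TRUE or shrink modules")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a ground-truthed single-cell dataset
#'
#' Draws negative-binomial counts for `n_cells` cells over `n_genes` genes
#' with `n_types` cell types, `n_batches` batches, and `n_pathways` planted
#' gene modules; see [simulation_config()] for the generative model. Cells
#' are assigned types and batches in a balanced round-robin so every
#' (type, batch) combination is populated. Each type activates a contiguous
#' block of `n_pathways / n_types` modules (at least one).
#'
#' @param config A [simulation_config()].
#' @return A `SyntheticDataset` list with elements `expression`
#'   (raw-count [expression_matrix()] carrying `cell_type` and `batch`),
#'   `true_type`, `true_batch`, `planted_sets` (a `GeneSetCollection`),
#'   `type_module_map` (type -> active pathway names) and
#'   `marker_genes` (type -> planted marker symbols).
#' @export
simulate_cells <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_genes; N <- config$n_cells
  K <- config$n_types; B <- config$n_batches; m <- config$n_pathways
  gpp <- config$genes_per_pathway
  genes <- sprintf("G%04d", seq_len(n))
  cells <- sprintf("cell%05d", seq_len(N))
  pw_names <- sprintf("PW%02d", seq_len(m))

  if (config$overlap) {
    modules <- lapply(seq_len(m), function(j) sample(n, gpp))
  } else {
    idx <- sample(n, m * gpp)
    modules <- split(idx, rep(seq_len(m), each = gpp))
  }
  names(modules) <- pw_names

  # contiguous blocks of modules per type; every type gets >= 1 module
  per_type <- max(1L, m %/% K)
  type_mods <- lapply(seq_len(K), function(t) {
    pw_names[(((t - 1L) * per_type) %% m) + seq_len(per_type)]
  })
  type_names <- paste0("type", seq_len(K))
  names(type_mods) <- type_names

  true_type <- type_names[(seq_len(N) - 1L) %% K + 1L]
  true_batch <- paste0("batch", ((seq_len(N) - 1L) %/% K) %% B + 1L)

  # per-type log-activity over genes
  act <- matrix(0, K, n, dimnames = list(type_names, NULL))
  for (t in seq_len(K))
    for (pw in type_mods[[t]])
      act[t, modules[[pw]]] <- config$type_effect

  # planted marker genes: high extra effect, drawn from the type's first module
  markers <- stats::setNames(vector("list", K), type_names)
  if (config$markers_per_type > 0) {
    for (t in seq_len(K)) {
      pool <- modules[[type_mods[[t]][1]]]
      mk <- pool[seq_len(min(config$markers_per_type, length(pool)))]
      markers[[t]] <- genes[mk]
      act[t, mk] <- act[t, mk] + config$marker_effect
    }
  }

  # batch offsets, type-independent, one draw per (batch, gene)
  boff <- matrix(stats::rnorm(B * n, 0, config$batch_shift_sd), B, n)
  batch_idx <- as.integer(sub("batch", "", true_batch))
  type_idx <- match(true_type, type_names)

  log_mu <- log(config$base_mean) + act[type_idx, , drop = FALSE] +
    boff[batch_idx, , drop = FALSE]
  counts <- matrix(stats::rnbinom(N * n, mu = exp(log_mu),
                                  size = config$nb_dispersion),
                   N, n, dimnames = list(cells, genes))

  planted <- gene_set_collection(lapply(modules, function(ix) genes[ix]))
  expr <- expression_matrix(counts, gene_names = genes, cell_ids = cells,
                            cell_type = true_type, batch = true_batch)
  structure(list(expression = expr, true_type = true_type,
                 true_batch = true_batch, planted_sets = planted,
                 type_module_map = type_mods, marker_genes = markers,
                 config = config),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat("SyntheticDataset:", x$config$n_cells, "cells,", x$config$n_genes,
      "genes,", x$config$n_types, "types,", x$config$n_batches, "batches,",
      x$config$n_pathways, "planted modules\n")
  invisible(x)
}

#' Randomly corrupt a fraction of labels
#'
#' Exactly `round(noise_ratio * N)` cells (chosen without replacement) are
#' reassigned to a uniformly chosen *different* label, emulating annotation
#' noise in the reference atlas.
#'
#' @param labels Character/factor vector of per-cell labels.
#' @param noise_ratio Fraction in `[0, 1]` of cells to corrupt.
#' @param seed Integer seed.
#' @return Corrupted label vector (character).
#' @export
corrupt_labels <- function(labels, noise_ratio, seed = 1) {
  labels <- as.character(labels)
  if (!is.numeric(noise_ratio) || noise_ratio < 0 || noise_ratio > 1)
    stop("noise_ratio must be in [0, 1]")
  lev <- unique(labels)
  if (length(lev) < 2) stop("need at least 2 distinct labels")
  n_flip <- round(noise_ratio * length(labels))
  if (n_flip == 0) return(labels)
  set.seed(as.integer(seed))
  pos <- sample(length(labels), n_flip)
  for (i in pos) {
    others <- lev[lev != labels[i]]
    labels[i] <- others[sample.int(length(others), 1L)]
  }
  labels
}

#' Subsample to an extreme class imbalance
#'
#' Keeps all cells of the `major` label and `floor(n_major / ratio)` cells
#' of the `minor` label (at most the available count); all other labels are
#' dropped. Used to stress-test rare-population detection at ratios such as
#' 100:1 to 500:1.
#'
#' @param X An [expression_matrix()] or `SyntheticDataset`.
#' @param labels Per-cell labels; defaults to `X$cell_type` /
#'   `X$true_type`.
#' @param major,minor Label values for the majority and minority class.
#' @param ratio Positive target ratio majority:minority.
#' @param seed Integer seed for choosing which minor cells to keep.
#' @return A list with `expression` (subsampled `ExpressionMatrix`) and
#'   `labels`.
#' @export
subsample_imbalance <- function(X, major, minor, ratio, labels = NULL,
                                seed = 1) {
  if (inherits(X, "SyntheticDataset")) {
    if (is.null(labels)) labels <- X$true_type
    X <- X$expression
  }
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (is.null(labels)) labels <- X$cell_type
  if (is.null(labels)) stop("labels required")
  labels <- as.character(labels)
  if (!is.numeric(ratio) || ratio <= 0) stop("ratio must be positive")
  maj_idx <- which(labels == major)
  min_idx <- which(labels == minor)
  if (!length(maj_idx)) stop("major label '", major, "' not present")
  if (!length(min_idx)) stop("minor label '", minor, "' not present")
  n_keep <- min(length(min_idx), floor(length(maj_idx) / ratio))
  if (n_keep < 1)
    stop("ratio ", ratio, " leaves no minority cells (",
         length(maj_idx), " major cells)")
  set.seed(as.integer(seed))
  keep_min <- sort(sample(min_idx, n_keep))
  keep <- sort(c(maj_idx, keep_min))
  sub <- X
  sub$values <- X$values[keep, , drop = FALSE]
  sub$cell_ids <- X$cell_ids[keep]
  if (!is.null(X$cell_type)) sub$cell_type <- X$cell_type[keep]
  if (!is.null(X$batch)) sub$batch <- X$batch[keep]
  list(expression = sub, labels = labels[keep])
}
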