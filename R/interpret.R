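#' Extract the gene set represented by a pattern
#'
#' Row-sums the pattern's projection matrix W_j into a per-gene score
#' P_j and selects the genes whose score strictly exceeds the mean of
#' P_j. When the Teacher was trained with a persistent knowledge mask,
#' masked rows are exactly zero and can never be selected while any
#' unmasked score is positive.
#'
#' @param W_j n x h projection matrix of pattern j (e.g.
#'   `teacher$navigator$W[[j]]`).
#' @param gene_names Gene symbols of the model's gene space.
#' @param pattern_index Index j recorded on the result.
#' @return A `PatternGeneSet` list: `pattern_index`, `genes`,
#'   `row_scores` (named P_j), `threshold` (mean of P_j).
#' @export
extract_pattern_gene_set <- function(W_j, gene_names,
                                     pattern_index = NA_integer_) {
  P <- rowSums(W_j)
  names(P) <- gene_names
  thr <- mean(P)
  genes <- gene_names[P > thr]
  if (!length(genes))
    warning("no gene strictly exceeds the mean row score of pattern ",
            pattern_index)
  structure(list(pattern_index = pattern_index, genes = genes,
                 row_scores = P, threshold = thr),
            class = "PatternGeneSet")
}

#' Hypergeometric over-representation test of a gene set
#'
#' For every pathway in `collection`, the probability of observing at
#' least the attained overlap between `genes` and the pathway under
#' hypergeometric sampling from `universe`. Benjamini-Hochberg q-values
#' are attached; rows are sorted by ascending p-value.
#'
#' @param genes Query gene set (must be a subset of `universe`).
#' @param collection A `GeneSetCollection`.
#' @param universe All genes of the model space.
#' @return Data frame: `pathway`, `overlap`, `set_size`, `p_value`,
#'   `q_value`.
#' @export
enrich_gene_set <- function(genes, collection, universe) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("empty query gene set")
  universe <- unique(as.character(universe))
  if (!all(genes %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(genes, universe), 5), collapse = ", "))
  n_u <- length(universe)
  n_q <- length(genes)
  res <- lapply(names(collection), function(pw) {
    set <- intersect(collection[[pw]], universe)
    ov <- length(intersect(genes, set))
    p <- if (ov == 0) 1 else
      stats::phyper(ov - 1, length(set), n_u - length(set), n_q,
                    lower.tail = FALSE)
    data.frame(pathway = pw, overlap = ov, set_size = length(set),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Rank patterns by cell-type specificity
#'
#' Each pattern token is summarized per cell by a scalar (the mean of its
#' h entries by default, or the L2 norm), then a one-vs-rest Wilcoxon
#' rank-sum test (alternative: greater) is run per cell type; the top 10
#' patterns per type by ascending p-value are returned (all patterns when
#' m < 10).
#'
#' @param tokens Cells x m x h array ([pattern_tokens()]).
#' @param labels Per-cell type labels.
#' @param pattern_names Optional names for the m patterns.
#' @param top_n Patterns to keep per type (default 10).
#' @param scalarize `"mean"` (default) or `"l2"`.
#' @return Data frame: `cell_type`, `rank`, `pattern`, `statistic`,
#'   `p_value`.
#' @export
rank_patterns_by_type <- function(tokens, labels, pattern_names = NULL,
                                  top_n = 10, scalarize = c("mean", "l2")) {
  scalarize <- match.arg(scalarize)
  labels <- as.character(labels)
  stopifnot(length(dim(tokens)) == 3, dim(tokens)[1] == length(labels))
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types")
  m <- dim(tokens)[2]
  if (is.null(pattern_names)) pattern_names <- paste0("pattern", seq_len(m))
  # scalar summary per cell x pattern
  scal <- if (scalarize == "mean") apply(tokens, c(1, 2), mean)
          else sqrt(apply(tokens^2, c(1, 2), sum))
  out <- list()
  for (ty in types) {
    in_ty <- labels == ty
    if (sum(in_ty) < 3) {
      warning("type '", ty, "' has fewer than 3 cells; skipped")
      next
    }
    stats_p <- vapply(seq_len(m), function(j) {
      w <- stats::wilcox.test(scal[in_ty, j], scal[!in_ty, j],
                              alternative = "greater", exact = FALSE)
      c(w$statistic, w$p.value)
    }, numeric(2))
    ord <- order(stats_p[2, ], -stats_p[1, ])[seq_len(min(top_n, m))]
    out[[ty]] <- data.frame(cell_type = ty, rank = seq_along(ord),
                            pattern = pattern_names[ord],
                            statistic = stats_p[1, ord],
                            p_value = stats_p[2, ord],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Build a gene co-expression graph from top patterns
#'
#' For each of a type's top patterns, the top `genes_per_pattern` genes by
#' the pattern's row-score P_j are taken and their rows of W_j kept as
#' gene embeddings; genes are connected when the cosine similarity of
#' their embeddings exceeds `tau`. A gene picked by several patterns is
#' kept once with its embeddings averaged (with a warning).
#'
#' @param teacher A trained `TeacherParams` with `gene_names`.
#' @param top_patterns Character or integer vector of pattern indices
#'   (e.g. one type's rows of [rank_patterns_by_type()]); names of the
#'   form `"pattern<j>"` are accepted.
#' @param genes_per_pattern Genes per pattern (default 2).
#' @param tau Cosine-similarity edge threshold (default 0.5).
#' @return A `GeneGraph` list: `graph` (igraph, undirected, no
#'   self-loops), `embeddings` (genes x h), `genes`.
#' @export
build_gene_graph <- function(teacher, top_patterns, genes_per_pattern = 2,
                             tau = 0.5) {
  stopifnot(inherits(teacher, "TeacherParams"))
  if (!length(top_patterns)) stop("top_patterns must be non-empty")
  if (is.character(top_patterns))
    top_patterns <- as.integer(sub("^pattern", "", top_patterns))
  genes <- character(0)
  embs <- list()
  for (j in top_patterns) {
    Wj <- navigator_weight(teacher$navigator, j)
    P <- rowSums(Wj)
    top <- order(P, decreasing = TRUE)[seq_len(min(genes_per_pattern,
                                                   length(P)))]
    for (gi in top) {
      g <- teacher$gene_names[gi]
      if (g %in% genes) {
        warning("gene ", g, " selected by multiple patterns; embeddings ",
                "averaged")
        embs[[g]] <- rbind(embs[[g]], Wj[gi, ])
      } else {
        genes <- c(genes, g)
        embs[[g]] <- matrix(Wj[gi, ], nrow = 1)
      }
    }
  }
  E <- t(vapply(genes, function(g) colMeans(embs[[g]]),
                numeric(teacher$h)))
  nrm <- sqrt(rowSums(E^2))
  nrm[nrm == 0] <- 1
  C <- tcrossprod(E / nrm)
  adj <- (C > tau)
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  igraph::V(gr)$name <- genes
  structure(list(graph = gr, embeddings = E, genes = genes, tau = tau),
            class = "GeneGraph")
}

#' Five centrality indicators per gene
#'
#' Degree, normalized betweenness, eigenvector centrality, PageRank
#' (damping 0.85) and closeness (harmonic for disconnected graphs are
#' handled per-component by igraph).
#'
#' @param graph A [build_gene_graph()] `GeneGraph` or an igraph object.
#' @return Data frame with one row per gene and columns `degree`,
#'   `betweenness`, `eigenvector`, `pagerank`, `closeness`.
#' @export
centrality_scores <- function(graph) {
  g <- if (inherits(graph, "GeneGraph")) graph$graph else graph
  n <- igraph::vcount(g)
  if (n < 1) stop("empty graph")
  deg <- igraph::degree(g)
  btw <- if (n > 2) igraph::betweenness(g, normalized = TRUE)
         else stats::setNames(rep(0, n), igraph::V(g)$name)
  eig <- if (igraph::ecount(g) > 0)
    igraph::eigen_centrality(g)$vector
  else stats::setNames(rep(0, n), igraph::V(g)$name)
  pr <- igraph::page_rank(g, damping = 0.85)$vector
  cls <- suppressWarnings(igraph::closeness(g))
  cls[!is.finite(cls)] <- 0
  data.frame(gene = igraph::V(g)$name, degree = as.numeric(deg),
             betweenness = as.numeric(btw), eigenvector = as.numeric(eig),
             pagerank = as.numeric(pr), closeness = as.numeric(cls),
             stringsAsFactors = FALSE)
}

#' Aggregate centrality indicators into a Q statistic
#'
#' Per indicator, genes are ranked descending (ties get average ranks);
#' Q(gene) is the mean rank across the five indicators, so smaller Q means
#' more central. Q lies in `[1, n_genes]`.
#'
#' @param scores A [centrality_scores()] data frame.
#' @return The same rows ordered by ascending `Q`, with a `Q` column.
#' @export
q_aggregate <- function(scores) {
  stopifnot(nrow(scores) >= 1)
  ind <- c("degree", "betweenness", "eigenvector", "pagerank", "closeness")
  R <- vapply(ind, function(cn) rank(-scores[[cn]], ties.method = "average"),
              numeric(nrow(scores)))
  if (is.null(dim(R))) R <- matrix(R, nrow = 1)
  out <- scores
  out$Q <- rowMeans(R)
  out[order(out$Q, out$gene), , drop = FALSE]
}

# per-layer background means (inputs and pre-activations) of the Student
student_background <- function(student, background) {
  fw <- student_forward_batch(student, background, keep = TRUE)
  list(inputs = lapply(fw$cache$inputs, colMeans),
       pre = lapply(fw$cache$pre, colMeans),
       logits = colMeans(fw$logits))
}

#' Layer-wise Shapley attribution for the Student
#'
#' DeepLIFT-style chained multipliers through the Student's dense layers.
#' The reference activation of every layer is the mean activation of the
#' background set, so attributions telescope: their sum over genes equals
#' the logit of `x` minus the mean background logit. For ReLU units the
#' multiplier is the rescale rule `(a - a_ref)/(z - z_ref)`; near-zero
#' denominators fall back to the unit's derivative at the reference. For a
#' single linear layer this reduces to the exact Shapley value
#' `phi_q = W[q, c] * (x_q - mean(x_q))`.
#'
#' @param student A `StudentParams`.
#' @param background Cells x n matrix of background expression (reference
#'   sample).
#' @param x Length-n expression vector of the cell to explain.
#' @param target_class Class index (1-based) or class label.
#' @param eps Denominator threshold for the linear-rule fallback.
#' @return Length-n named attribution vector.
#' @export
shap_attribution <- function(student, background, x, target_class,
                             eps = 1e-7) {
  stopifnot(inherits(student, "StudentParams"))
  if (is.null(dim(background))) background <- matrix(background, nrow = 1)
  if (!nrow(background)) stop("background must be non-empty")
  if (is.character(target_class)) {
    target_class <- match(target_class, student$classes)
    if (is.na(target_class)) stop("unknown class label")
  }
  bg <- student_background(student, background)
  shap_multiplier_chain(student, bg, x, target_class, eps)
}

# multiplier chain for one cell given precomputed background means
shap_multiplier_chain <- function(student, bg, x, target_class, eps = 1e-7) {
  fw <- student_forward_batch(student, matrix(x, nrow = 1), keep = TRUE)
  L <- length(student$layers)
  # multiplier vector from the target logit backwards
  mult <- numeric(student$k)
  mult[target_class] <- 1
  for (l in rev(seq_len(L))) {
    # through the nonlinearity of layer l (none on the output layer)
    if (l < L) {
      z <- drop(fw$cache$pre[[l]])
      zr <- bg$pre[[l]]          # mean background pre-activation
      ar <- bg$inputs[[l + 1]]   # mean background activation
      dz <- z - zr
      mr <- ifelse(abs(dz) > eps, (pmax(z, 0) - ar) / dz,
                   as.numeric(zr > 0))
      mult <- mult * mr
    }
    mult <- drop(student$layers[[l]]$W %*% mult)
  }
  phi <- mult * (drop(x) - bg$inputs[[1]])
  names(phi) <- student$gene_names %||% names(x)
  phi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean absolute Shapley attribution per gene for one cell type
#'
#' Computes [shap_attribution()] for every cell predicted as `type`
#' (against that type's class index), averages the absolute values over
#' cells, and returns the top genes.
#'
#' @param student A `StudentParams`.
#' @param X Cells x n matrix (or [expression_matrix()]) of cells to
#'   explain.
#' @param predicted Per-cell predicted labels.
#' @param type The cell type to explain.
#' @param background Background matrix (defaults to `X`).
#' @param top_n Genes to return (default 10).
#' @return Data frame `gene`, `mean_abs_shap`, ordered descending.
#' @export
top_shap_genes <- function(student, X, predicted, type, background = NULL,
                           top_n = 10) {
  if (inherits(X, "ExpressionMatrix")) X <- X$values
  if (is.null(background)) background <- X
  if (inherits(background, "ExpressionMatrix")) background <- background$values
  sel <- which(as.character(predicted) == type)
  if (!length(sel)) stop("no cells predicted as '", type, "'")
  cls <- match(type, student$classes)
  if (is.na(cls)) stop("'", type, "' is not one of the model's classes")
  bg <- student_background(student, background)
  acc <- numeric(ncol(X))
  for (i in sel)
    acc <- acc + abs(shap_multiplier_chain(student, bg, X[i, ], cls))
  acc <- acc / length(sel)
  genes <- student$gene_names %||% colnames(X) %||%
    paste0("g", seq_along(acc))
  ord <- order(acc, decreasing = TRUE)[seq_len(min(top_n, length(acc)))]
  data.frame(gene = genes[ord], mean_abs_shap = acc[ord],
             stringsAsFactors = FALSE)
}

#' Teacher-Student consensus gene ranking
#'
#' Intersects the Teacher-derived gene pool (pattern learning) with the
#' Student's Shapley-ranked genes, keeping the Student's order. Genes
#' supported by both global pattern structure and local decision
#' boundaries.
#'
#' @param teacher_genes Character vector (or `PatternGeneSet` list) of
#'   Teacher-derived genes.
#' @param student_top Ranked character vector or [top_shap_genes()] data
#'   frame.
#' @return Character vector: the intersection in Student rank order
#'   (empty with a warning when disjoint).
#' @export
consensus_genes <- function(teacher_genes, student_top) {
  if (is.list(teacher_genes) && !is.data.frame(teacher_genes))
    teacher_genes <- unique(unlist(lapply(teacher_genes, function(x)
      if (inherits(x, "PatternGeneSet")) x$genes else x)))
  if (is.data.frame(student_top)) student_top <- student_top$gene
  out <- student_top[student_top %in% teacher_genes]
  if (!length(out)) warning("Teacher and Student gene sets are disjoint")
  out
}

#' Teacher gene pool for one cell type
#'
#' Union of the pattern gene sets ([extract_pattern_gene_set()]) of a
#' type's top patterns. When the Teacher was trained with a knowledge
#' mask, the pattern-to-pathway mapping is already given by the GMT and
#' the per-pattern gene sets coincide with (a data-driven subset of) the
#' pathway members.
#'
#' @param teacher A trained `TeacherParams`.
#' @param top_patterns Pattern indices or `"pattern<j>"` names.
#' @return Character vector of genes.
#' @export
teacher_gene_pool <- function(teacher, top_patterns) {
  if (is.character(top_patterns))
    top_patterns <- as.integer(sub("^pattern", "", top_patterns))
  unique(unlist(lapply(top_patterns, function(j)
    extract_pattern_gene_set(navigator_weight(teacher$navigator, j),
                             teacher$gene_names, j)$genes)))
}
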