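#' Classification metrics
#'
#' Accuracy, per-class precision/recall/F1 from one-vs-rest confusion
#' counts, and macro-F1 (unweighted mean of per-class F1 over the classes
#' present in the true labels). A class with `tp + fp = 0` gets precision
#' 0; with `tp + fn = 0`, recall 0; F1 is 0 when precision + recall = 0.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @return List: `accuracy`, `per_class` (data frame with tp/fp/fn/tn,
#'   precision, recall, f1), `macro_f1`.
#' @export
classification_metrics <- function(true_labels, pred_labels) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (!length(true_labels)) stop("empty input")
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  N <- length(true_labels)
  classes <- sort(unique(true_labels))
  per <- lapply(classes, function(cl) {
    tp <- sum(true_labels == cl & pred_labels == cl)
    fp <- sum(true_labels != cl & pred_labels == cl)
    fn <- sum(true_labels == cl & pred_labels != cl)
    tn <- N - tp - fp - fn
    P <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R <- if (tp + fn == 0) 0 else tp / (tp + fn)
    F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = P, recall = R, f1 = F1, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(accuracy = mean(true_labels == pred_labels), per_class = per,
       macro_f1 = mean(per$f1))
}

#' Adjusted Rand index
#'
#' Permutation-model-adjusted agreement between two partitions; 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return The ARI.
#' @export
ari <- function(labels_a, labels_b) {
  if (!length(labels_a)) stop("empty input")
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Scaled average silhouette width
#'
#' `(mean silhouette + 1) / 2` of `labels` on the embedding, in [0, 1];
#' higher means tighter, better-separated label clusters.
#'
#' @param embeddings Cells x d numeric matrix.
#' @param labels Per-cell labels (>= 2 distinct).
#' @return Scalar in [0, 1].
#' @export
asw_scaled <- function(embeddings, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("need at least 2 distinct labels for a silhouette")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(embeddings))
  (mean(sil[, "sil_width"]) + 1) / 2
}

# k-nearest-neighbour index matrix (self excluded) from an embedding
knn_index <- function(embeddings, k) {
  D <- as.matrix(stats::dist(embeddings))
  diag(D) <- Inf
  t(apply(D, 1, function(r) order(r)[seq_len(k)]))
}

#' kBET-style batch-mixing acceptance rate
#'
#' For each cell, a chi-square goodness-of-fit test compares the batch
#' composition of its k nearest neighbours with the global batch
#' frequencies; the acceptance rate is the fraction of cells with
#' p > 0.05. 1 means perfectly mixed batches, 0 means fully separated.
#'
#' @param embeddings Cells x d matrix.
#' @param batch_labels Per-cell batch labels (>= 2 batches).
#' @param k Neighbourhood size (default `min(50, floor(N/10))`).
#' @return Acceptance rate in [0, 1].
#' @export
kbet_acceptance <- function(embeddings, batch_labels,
                            k = min(50L, nrow(embeddings) %/% 10L)) {
  batch_labels <- as.character(batch_labels)
  N <- nrow(embeddings)
  if (length(unique(batch_labels)) < 2) stop("need at least 2 batches")
  if (k >= N) stop("k must be smaller than the number of cells")
  if (k < 2) stop("k must be >= 2")
  freq <- table(batch_labels) / N
  batches <- names(freq)
  nn <- knn_index(embeddings, k)
  expd <- k * as.numeric(freq)
  pvals <- vapply(seq_len(N), function(i) {
    obs <- tabulate(match(batch_labels[nn[i, ]], batches),
                    nbins = length(batches))
    stat <- sum((obs - expd)^2 / expd)
    stats::pchisq(stat, df = length(batches) - 1, lower.tail = FALSE)
  }, numeric(1))
  mean(pvals > 0.05)
}

# mean average precision of same-type retrieval within k-NN ranking
map_score <- function(nn, labels) {
  N <- nrow(nn)
  mean(vapply(seq_len(N), function(i) {
    same <- labels[nn[i, ]] == labels[i]
    if (!any(same)) return(0)
    hits <- cumsum(same)
    sum((hits / seq_along(same))[same]) / sum(same)
  }, numeric(1)))
}

# Seurat alignment score: 1 - (xbar - k/B) / (k - k/B), clipped to [0,1]
sas_score <- function(nn, batch_labels) {
  k <- ncol(nn)
  B <- length(unique(batch_labels))
  own <- vapply(seq_len(nrow(nn)), function(i)
    sum(batch_labels[nn[i, ]] == batch_labels[i]), numeric(1))
  xbar <- mean(own)
  val <- 1 - (xbar - k / B) / (k - k / B)
  min(max(val, 0), 1)
}

# graph connectivity: per type, largest connected component fraction of
# the k-NN graph restricted to that type
gc_score <- function(nn, labels) {
  types <- unique(labels)
  mean(vapply(types, function(ty) {
    idx <- which(labels == ty)
    if (length(idx) == 1) return(1)
    sub <- matrix(match(nn[idx, ], idx), nrow = length(idx))
    el <- cbind(rep(seq_along(idx), ncol(sub)), as.vector(sub))
    el <- el[!is.na(el[, 2]), , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    max(igraph::components(g)$csize) / length(idx)
  }, numeric(1)))
}

#' Composite integration score
#'
#' Biology conservation = (MAP + cell-type ASW + NC) / 3; batch removal =
#' (SAS + omics ASW + GC) / 3; overall = 0.4 * batch + 0.6 * biology.
#' MAP is the mean average precision of same-type retrieval in the k-NN
#' ranking, NC the mean fraction of k-NN sharing the cell's type, omics
#' ASW is `1 - asw_scaled(layer labels)` (higher = layers better mixed),
#' SAS the Seurat alignment score over own-layer neighbour counts, and GC
#' the mean largest-connected-component fraction of each type's k-NN
#' subgraph. All components are clipped to [0, 1].
#'
#' @param joint_embeddings Cells x d matrix of the joint embedding.
#' @param type_labels Per-cell biological type labels.
#' @param layer_labels Per-cell batch / omics-layer labels.
#' @param k Neighbourhood size (default `min(50, floor(N/10))`).
#' @return A `CompositeScore` list with the six components,
#'   `biology_conservation`, `batch_removal` and `overall`.
#' @export
composite_score <- function(joint_embeddings, type_labels, layer_labels,
                            k = min(50L, nrow(joint_embeddings) %/% 10L)) {
  if (is.null(type_labels) || is.null(layer_labels))
    stop("type and layer labels are both required")
  type_labels <- as.character(type_labels)
  layer_labels <- as.character(layer_labels)
  nn <- knn_index(joint_embeddings, k)
  clip01 <- function(x) min(max(x, 0), 1)
  map <- clip01(map_score(nn, type_labels))
  ct_asw <- clip01(asw_scaled(joint_embeddings, type_labels))
  nc <- clip01(mean(vapply(seq_len(nrow(nn)), function(i)
    mean(type_labels[nn[i, ]] == type_labels[i]), numeric(1))))
  sas <- clip01(sas_score(nn, layer_labels))
  om_asw <- if (length(unique(layer_labels)) < 2) 1 else
    clip01(1 - asw_scaled(joint_embeddings, layer_labels))
  gc <- clip01(gc_score(nn, type_labels))
  bio <- (map + ct_asw + nc) / 3
  bat <- (sas + om_asw + gc) / 3
  structure(list(map = map, celltype_asw = ct_asw, nc = nc, sas = sas,
                 omics_asw = om_asw, gc = gc, biology_conservation = bio,
                 batch_removal = bat, overall = 0.4 * bat + 0.6 * bio),
            class = "CompositeScore")
}

#' @export
print.CompositeScore <- function(x, ...) {
  cat(sprintf("CompositeScore: overall %.3f (biology %.3f, batch %.3f)\n",
              x$overall, x$biology_conservation, x$batch_removal))
  invisible(x)
}
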