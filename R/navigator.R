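#' Build a knowledge-based mask from gene sets
#'
#' Binary genes x pathways membership matrix: entry (g, j) is 1 iff gene g
#' belongs to pathway j. The mask zeroes the rows of the j-th Navigator
#' projection matrix for genes outside pathway j, so each pattern token can
#' only read the expression of its pathway's member genes.
#'
#' @param gene_names Ordered gene symbols of the model's gene space.
#' @param sets A `GeneSetCollection` ([read_gmt()]).
#' @return A `KnowledgeMask`: list with `mask` (n x m 0/1 matrix),
#'   `gene_names`, `pathway_names`.
#' @export
build_knowledge_mask <- function(gene_names, sets) {
  gene_names <- as.character(gene_names)
  if (!length(gene_names)) stop("gene_names must be non-empty")
  stopifnot(inherits(sets, "GeneSetCollection") || is.list(sets))
  m <- length(sets)
  mask <- matrix(0, length(gene_names), m,
                 dimnames = list(gene_names, names(sets)))
  empty <- character(0)
  for (j in seq_len(m)) {
    hit <- gene_names %in% sets[[j]]
    if (!any(hit)) empty <- c(empty, names(sets)[j])
    mask[hit, j] <- 1
  }
  if (length(empty))
    warning("pathways with no genes in the model gene space (kept as ",
            "all-zero columns): ", paste(empty, collapse = ", "))
  structure(list(mask = mask, gene_names = gene_names,
                 pathway_names = names(sets)),
            class = "KnowledgeMask")
}

#' Read/write a knowledge mask as a genes x pathways TSV of 0/1
#' @param mask A `KnowledgeMask`.
#' @param path Output path.
#' @return `path` invisibly (write) or a `KnowledgeMask` (read).
#' @export
write_mask_tsv <- function(mask, path) {
  stopifnot(inherits(mask, "KnowledgeMask"))
  utils::write.table(mask$mask, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_mask_tsv
#' @export
read_mask_tsv <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (!all(m %in% c(0, 1))) stop("mask entries must be 0/1")
  structure(list(mask = m, gene_names = rownames(m),
                 pathway_names = colnames(m)),
            class = "KnowledgeMask")
}

#' Initialize Navigator parameters
#'
#' One n x h projection matrix per pattern. Initialization is
#' Kaiming-uniform with fan-in counted over *unmasked* entries of each
#' column's pathway, so sparse pathway projections are not under-scaled;
#' masked rows are exactly zero from the start.
#'
#' @param n_genes Number of genes n.
#' @param m Number of patterns (defaults to `ncol(mask$mask)` when a mask
#'   is given).
#' @param h Token width.
#' @param mask Optional `KnowledgeMask`.
#' @param mask_mode `"persistent"` re-applies the mask at every forward
#'   and gradient step (masked weights stay exactly 0); `"init_only"`
#'   masks only the initialization.
#' @return A `NavigatorParams` list: `W` (list of m n x h matrices), `m`,
#'   `h`, `mask` (n x m matrix or NULL), `mask_mode`.
#' @export
navigator_init <- function(n_genes, m = NULL, h = 48, mask = NULL,
                           mask_mode = c("persistent", "init_only")) {
  mask_mode <- match.arg(mask_mode)
  mask_mat <- NULL
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "KnowledgeMask"))
    if (nrow(mask$mask) != n_genes)
      stop("mask has ", nrow(mask$mask), " genes, expected ", n_genes)
    mask_mat <- mask$mask
    if (is.null(m)) m <- ncol(mask_mat)
    if (m != ncol(mask_mat)) stop("m must equal the number of mask columns")
  }
  if (is.null(m)) m <- 64L
  W <- vector("list", m)
  for (j in seq_len(m)) {
    fan_in <- if (is.null(mask_mat)) n_genes else max(1, sum(mask_mat[, j]))
    bound <- sqrt(6 / fan_in)
    Wj <- matrix(stats::runif(n_genes * h, -bound, bound), n_genes, h)
    if (!is.null(mask_mat)) Wj <- Wj * mask_mat[, j]
    W[[j]] <- Wj
  }
  structure(list(W = W, m = as.integer(m), h = as.integer(h),
                 n_genes = as.integer(n_genes), mask = mask_mat,
                 mask_mode = mask_mode),
            class = "NavigatorParams")
}

#' Navigator forward pass
#'
#' Projects expression vectors into m pattern tokens: token j of cell i is
#' `t(W_j) %*% x_i` with W_j masked to pathway j's genes.
#'
#' @param X Numeric matrix (cells x genes) or a single length-n vector.
#' @param params A `NavigatorParams`.
#' @return A 3-d array cells x m x h of pattern tokens.
#' @export
navigator_forward <- function(X, params) {
  stopifnot(inherits(params, "NavigatorParams"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != params$n_genes)
    stop("input has ", ncol(X), " genes, navigator expects ", params$n_genes)
  if (any(!is.finite(X))) stop("non-finite expression input")
  N <- nrow(X)
  out <- array(0, dim = c(N, params$m, params$h))
  for (j in seq_len(params$m)) {
    Wj <- navigator_weight(params, j)
    out[, j, ] <- X %*% Wj
  }
  out
}

# effective (masked) weight of pattern j
navigator_weight <- function(params, j) {
  Wj <- params$W[[j]]
  if (!is.null(params$mask) && params$mask_mode == "persistent")
    Wj <- Wj * params$mask[, j]
  Wj
}

# gradient of the token array w.r.t. each W_j; dT is cells x m x h
navigator_backward <- function(X, params, dT) {
  gW <- vector("list", params$m)
  N <- nrow(X)
  for (j in seq_len(params$m)) {
    dTj <- matrix(dT[, j, ], nrow = N)
    g <- crossprod(X, dTj)
    if (!is.null(params$mask) && params$mask_mode == "persistent")
      g <- g * params$mask[, j]
    gW[[j]] <- g
  }
  gW
}
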