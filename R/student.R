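#' Initialize Student parameters
#'
#' The Student is a plain fully connected network mapping gene expression
#' directly to class logits; default layout n -> 256 -> 64 -> k with ReLU.
#' No dropout or batch normalization: the layer-wise Shapley attribution
#' assumes plain dense layers.
#'
#' @param n_genes Input dimension n.
#' @param classes Character vector of class labels.
#' @param hidden Integer vector of hidden widths (default `c(256, 64)`;
#'   use `integer(0)` for a single linear layer).
#' @return A `StudentParams` list: `layers` (list of `list(W, b)` with W
#'   of shape in x out), `classes`, `k`, `activation`.
#' @export
student_init <- function(n_genes, classes, hidden = c(256, 64)) {
  classes <- as.character(classes)
  k <- length(classes)
  dims <- c(n_genes, hidden, k)
  layers <- lapply(seq_len(length(dims) - 1), function(l)
    list(W = xavier_mat(dims[l], dims[l + 1]), b = numeric(dims[l + 1])))
  structure(list(layers = layers, classes = classes, k = k,
                 n_genes = as.integer(n_genes), activation = "relu"),
            class = "StudentParams")
}

#' @export
print.StudentParams <- function(x, ...) {
  dims <- c(x$n_genes, vapply(x$layers, function(l) ncol(l$W), integer(1)))
  cat("StudentParams: MLP", paste(dims, collapse = " -> "), ";",
      format(teacher_n_params(x), big.mark = ","), "parameters\n")
  invisible(x)
}

# batched forward; keep = TRUE caches per-layer inputs/pre-activations
student_forward_batch <- function(params, X, keep = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != params$n_genes)
    stop("input has ", ncol(X), " genes, student expects ", params$n_genes)
  L <- length(params$layers)
  a <- X
  inputs <- vector("list", L)
  pre <- vector("list", L)
  for (l in seq_len(L)) {
    inputs[[l]] <- a
    z <- sweep(a %*% params$layers[[l]]$W, 2, params$layers[[l]]$b, "+")
    pre[[l]] <- z
    a <- if (l < L) pmax(z, 0) else z
  }
  out <- list(logits = a)
  if (keep) out$cache <- list(inputs = inputs, pre = pre)
  out
}

# backward; d_logits N x k -> gradients shaped like params$layers
student_backward_batch <- function(params, cache, d_logits) {
  L <- length(params$layers)
  g <- vector("list", L)
  delta <- d_logits
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (cache$pre[[l]] > 0)
    g[[l]] <- list(W = crossprod(cache$inputs[[l]], delta),
                   b = colSums(delta))
    if (l > 1) delta <- delta %*% t(params$layers[[l]]$W)
  }
  list(layers = g)
}

#' Student forward pass
#'
#' @param x Length-n expression vector or cells x genes matrix.
#' @param params A [student_init()] `StudentParams`.
#' @return Logits: length-k vector (single cell) or N x k matrix.
#' @export
student_forward <- function(x, params) {
  single <- is.null(dim(x))
  out <- student_forward_batch(params, x)$logits
  colnames(out) <- params$classes
  if (single) drop(out) else out
}
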