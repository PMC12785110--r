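#' Construct an ExpressionMatrix
#'
#' Lightweight container for a cells x genes expression matrix with optional
#' per-cell `cell_type` and `batch` labels. Rows are cells, columns are genes.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param gene_names Character vector of unique gene symbols (defaults to
#'   `colnames(values)`).
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   `rownames(values)`).
#' @param cell_type Optional per-cell type labels (length = number of cells).
#' @param batch Optional per-cell batch labels.
#' @param normalized Logical; `TRUE` once values are size-factor scaled and
#'   log1p transformed.
#'
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_names = colnames(values),
                              cell_ids = rownames(values),
                              cell_type = NULL, batch = NULL,
                              normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(values)))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != ncol(values))
    stop("gene_names length (", length(gene_names), ") != number of genes (",
         ncol(values), ")")
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != number of cells (",
         nrow(values), ")")
  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup))
    stop("duplicate gene names: ", paste(dup, collapse = ", "))
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup))
    stop("duplicate cell ids: ", paste(dup, collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (!normalized && any(values < 0))
    stop("raw counts must be non-negative")
  check_lab <- function(lab, what) {
    if (is.null(lab)) return(NULL)
    if (length(lab) != nrow(values))
      stop(what, " labels must have length = number of cells")
    as.character(lab)
  }
  dimnames(values) <- list(cell_ids, gene_names)
  structure(list(values = values, gene_names = gene_names,
                 cell_ids = cell_ids,
                 cell_type = check_lab(cell_type, "cell_type"),
                 batch = check_lab(batch, "batch"),
                 normalized = isTRUE(normalized)),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "cells x", ncol(x$values),
      "genes;", if (x$normalized) "normalized" else "raw counts", "\n")
  if (!is.null(x$cell_type))
    cat("  cell types:", paste(utils::head(sort(unique(x$cell_type)), 8),
                               collapse = ", "), "\n")
  if (!is.null(x$batch))
    cat("  batches:", paste(sort(unique(x$batch)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix from disk
#'
#' Supported formats: dense `csv` (first column = cell id, header = gene
#' names) and MatrixMarket `mtx` with `genes.tsv` / `barcodes.tsv` sidecar
#' files in the same directory (genes x cells orientation, as emitted by
#' CellRanger-style pipelines; transposed on read so that cells are rows).
#'
#' @param path File path (`.csv` or `.mtx`).
#' @param format One of `"csv"`, `"mtx"`; inferred from the extension when
#'   omitted.
#' @param normalized Logical flag stored on the returned object.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, format = c("auto", "csv", "mtx"),
                            normalized = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx",
                     stop("cannot infer format from extension of ", path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("csv must have a cell-id column plus gene columns")
    cell_ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
      row <- which(is.na(suppressWarnings(as.numeric(tab[[bad + 1]]))))[1]
      stop("non-numeric entry at row ", row, ", column '",
           colnames(tab)[bad + 1], "'")
    }
    expression_matrix(vals, gene_names = colnames(tab)[-1],
                      cell_ids = cell_ids, normalized = normalized)
  } else {
    dirn <- dirname(path)
    gf <- file.path(dirn, "genes.tsv")
    bf <- file.path(dirn, "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("mtx sidecars genes.tsv/barcodes.tsv not found next to ", path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.delim(gf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("mtx dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecars")
    expression_matrix(t(m), gene_names = genes, cell_ids = cells,
                      normalized = normalized)
  }
}

#' Write an expression matrix to disk
#'
#' @param X An [expression_matrix()] object.
#' @param path Output path; `.csv` writes a dense table, `.mtx` writes
#'   MatrixMarket plus `genes.tsv`/`barcodes.tsv` sidecars.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- data.frame(cell_id = X$cell_ids, X$values, check.names = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(X$values), sparse = TRUE), path)
    dirn <- dirname(path)
    writeLines(X$gene_names, file.path(dirn, "genes.tsv"))
    writeLines(X$cell_ids, file.path(dirn, "barcodes.tsv"))
  } else stop("unsupported extension: ", ext)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description (discarded), then member gene symbols,
#' tab-separated. Symbols are deduplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return A `GeneSetCollection`: named list of character vectors with a
#'   class attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    nm <- fields[1]
    if (nm %in% names(sets))
      stop("duplicate pathway name in GMT: ", nm)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " (", nm, ") has no genes")
    sets[[nm]] <- genes
  }
  gene_set_collection(sets)
}

#' Construct a GeneSetCollection from a named list
#'
#' @param sets Named list of character vectors (pathway -> gene symbols).
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway names")
  if (any(vapply(sets, length, integer(1)) == 0L))
    stop("every gene set must be non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(sets, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x), "sets;",
      length(unique(unlist(x))), "distinct genes\n")
  invisible(x)
}

#' Write gene sets to a GMT file
#'
#' @param sets A `GeneSetCollection` or named list of gene vectors.
#' @param path Output path.
#' @param description Description column value (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Size-factor normalization followed by log1p
#'
#' Each cell's counts are scaled so its total equals `target_sum` (default:
#' the median of per-cell totals), then `log(1 + x)` is applied, matching the
#' standard scRNA-seq preprocessing convention.
#'
#' @param X A raw-count [expression_matrix()].
#' @param target_sum Positive number, or `"median"` for the median of
#'   per-cell totals.
#' @return A normalized `ExpressionMatrix` (`normalized = TRUE`).
#' @export
normalize_log1p <- function(X, target_sum = "median") {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (X$normalized)
    stop("matrix is already normalized; normalize_log1p() is one-shot")
  totals <- rowSums(X$values)
  if (any(totals <= 0)) {
    bad <- X$cell_ids[totals <= 0]
    stop("cells with zero total counts: ", paste(bad, collapse = ", "))
  }
  if (identical(target_sum, "median")) target_sum <- stats::median(totals)
  if (!is.numeric(target_sum) || target_sum <= 0)
    stop("target_sum must be positive or \"median\"")
  scaled <- X$values * (target_sum / totals)
  out <- X
  out$values <- log1p(scaled)
  dimnames(out$values) <- list(X$cell_ids, X$gene_names)
  out$normalized <- TRUE
  out
}

#' Subset an expression matrix by cell
#'
#' @param X An [expression_matrix()].
#' @param idx Integer or logical cell index.
#' @return The subsetted `ExpressionMatrix` (labels carried along).
#' @export
subset_cells <- function(X, idx) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  X$values <- X$values[idx, , drop = FALSE]
  X$cell_ids <- X$cell_ids[idx]
  if (!is.null(X$cell_type)) X$cell_type <- X$cell_type[idx]
  if (!is.null(X$batch)) X$batch <- X$batch[idx]
  X
}

#' Align an expression matrix to a reference gene space
#'
#' Columns are reordered to `reference_genes`; genes absent from `X` are
#' zero-filled (with a warning), genes not in the reference are dropped
#' (with a warning). Query data must be aligned to the Teacher's gene space
#' before prediction.
#'
#' @param X An [expression_matrix()].
#' @param reference_genes Ordered character vector of gene symbols.
#' @return An `ExpressionMatrix` over exactly `reference_genes`.
#' @export
align_genes <- function(X, reference_genes) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  reference_genes <- as.character(reference_genes)
  shared <- intersect(reference_genes, X$gene_names)
  if (!length(shared))
    stop("no genes shared with the reference gene space")
  missing <- setdiff(reference_genes, X$gene_names)
  extra <- setdiff(X$gene_names, reference_genes)
  if (length(missing))
    warning("zero-filling ", length(missing), " reference genes absent from input: ",
            paste(utils::head(missing, 10), collapse = ", "),
            if (length(missing) > 10) ", ...")
  if (length(extra))
    warning("dropping ", length(extra), " genes not in the reference: ",
            paste(utils::head(extra, 10), collapse = ", "),
            if (length(extra) > 10) ", ...")
  vals <- matrix(0, nrow(X$values), length(reference_genes),
                 dimnames = list(X$cell_ids, reference_genes))
  vals[, shared] <- X$values[, shared, drop = FALSE]
  out <- X
  out$values <- vals
  out$gene_names <- reference_genes
  out
}
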