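#' Labelled single-cell expression matrix
#'
#' The universal input container of the package: a non-negative cells x genes
#' count matrix (dense or sparse) together with unique gene and cell
#' identifiers and, optionally, one class label per cell.
#'
#' @param counts Numeric matrix or `Matrix::sparseMatrix`, cells in rows and
#'   genes in columns, all entries >= 0.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Defaults to `colnames(counts)`.
#' @param cell_ids Character vector of unique cell barcodes, one per row.
#'   Defaults to `rownames(counts)`.
#' @param labels Optional per-cell class labels (character or factor), either
#'   unnamed and in cell order, or named by cell barcode.
#'
#' @return An object of class `sc_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `gene_ids`, `cell_ids`, `labels` (character or `NULL`)
#'   and `class_names` (sorted unique labels, or `NULL`).
#' @export
sc_matrix <- function(counts, gene_ids = colnames(counts),
                      cell_ids = rownames(counts), labels = NULL) {
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(counts), ")")
  if (length(cell_ids) != nrow(counts))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(counts), ")")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(cell_ids, gene_ids)
  m <- structure(list(counts = counts, gene_ids = gene_ids,
                      cell_ids = cell_ids, labels = NULL,
                      class_names = NULL),
                 class = "sc_matrix")
  if (!is.null(labels)) m <- set_labels(m, labels)
  m
}

#' Attach per-cell class labels
#'
#' @param m An [sc_matrix].
#' @param labels Character/factor vector, unnamed (cell order) or named by
#'   barcode; every cell must receive exactly one label.
#' @return `m` with `labels` and `class_names` set.
#' @export
set_labels <- function(m, labels) {
  stopifnot(inherits(m, "sc_matrix"))
  if (!is.null(names(labels)) && !all(names(labels) == "")) {
    missing <- setdiff(m$cell_ids, names(labels))
    if (length(missing))
      stop("labels missing for ", length(missing), " cells, e.g. ",
           missing[1])
    labels <- labels[m$cell_ids]
  } else if (length(labels) != length(m$cell_ids)) {
    stop("need one label per cell: got ", length(labels), ", expected ",
         length(m$cell_ids))
  }
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels contain NA")
  m$labels <- labels
  m$class_names <- sort(unique(labels))
  m
}

#' @export
dim.sc_matrix <- function(x) dim(x$counts)

#' @export
print.sc_matrix <- function(x, ...) {
  cat("sc_matrix: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("classes: ",
        paste(names(tab), " (", as.integer(tab), ")",
              sep = "", collapse = ", "), "\n", sep = "")
  } else cat("labels: unset\n")
  invisible(x)
}

#' Subset an sc_matrix by cells and/or genes
#'
#' @param m An [sc_matrix].
#' @param cells,genes Index vectors (integer, logical, or id character).
#' @return The subset `sc_matrix`.
#' @export
subset_cells <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "sc_matrix"))
  ci <- if (is.null(cells)) seq_along(m$cell_ids) else
    resolve_index(cells, m$cell_ids, "cell")
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else
    resolve_index(genes, m$gene_ids, "gene")
  sc_matrix(m$counts[ci, gi, drop = FALSE],
            gene_ids = m$gene_ids[gi], cell_ids = m$cell_ids[ci],
            labels = if (!is.null(m$labels)) m$labels[ci])
}

resolve_index <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos))
      stop("unknown ", what, " id(s): ",
           paste(utils::head(idx[is.na(pos)], 5), collapse = ", "))
    pos
  } else if (is.logical(idx)) {
    which(idx)
  } else as.integer(idx)
}

#' Dense numeric matrix of counts (cells x genes)
#' @param m An [sc_matrix].
#' @return A base dense matrix.
#' @export
as_dense <- function(m) as.matrix(m$counts)
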