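#' Read an expression matrix from disk
#'
#' Supports the 10x-style Matrix Market triplet (`matrix.mtx` +
#' `genes.tsv`/`features.tsv` + `barcodes.tsv`, tab-separated, no header)
#' and a dense CSV/TSV with a header row of gene ids and barcodes in the
#' first column. Orientation on disk is auto-detected: the axis whose
#' length matches the barcodes file is taken as cells; the returned matrix
#' is always cells x genes. If a labels file is found alongside (or given),
#' labels are attached.
#'
#' @param path Directory of the triplet, or the dense CSV/TSV file.
#' @param format One of `"auto"`, `"mtx_triplet"`, `"dense_csv"`.
#' @param labels Optional path to a two-column TSV (barcode, label; header
#'   optional). For triplet directories, `labels.tsv` is picked up
#'   automatically when present.
#' @param orientation For square matrices, where auto-detection is
#'   ambiguous: `"cells_by_genes"` or `"genes_by_cells"`.
#' @return An [sc_matrix] (labels unset unless a labels file was read).
#' @export
read_matrix <- function(path, format = c("auto", "mtx_triplet", "dense_csv"),
                        labels = NULL,
                        orientation = c("auto", "cells_by_genes",
                                        "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx_triplet" else "dense_csv"
  m <- if (format == "mtx_triplet")
    read_mtx_triplet(path, orientation)
  else read_dense_csv(path)
  if (is.null(labels) && format == "mtx_triplet" &&
      file.exists(file.path(path, "labels.tsv")))
    labels <- file.path(path, "labels.tsv")
  if (!is.null(labels)) m <- set_labels(m, read_labels(labels))
  m
}

read_mtx_triplet <- function(dir, orientation = "auto") {
  mtx <- file.path(dir, "matrix.mtx")
  genes_f <- file.path(dir, "genes.tsv")
  if (!file.exists(genes_f)) genes_f <- file.path(dir, "features.tsv")
  bc_f <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, genes_f, bc_f))
    if (!file.exists(f)) stop("missing file: ", f)
  counts <- Matrix::readMM(mtx)
  genes <- utils::read.delim(genes_f, header = FALSE,
                             colClasses = "character")[[1]]
  barcodes <- utils::read.delim(bc_f, header = FALSE,
                                colClasses = "character")[[1]]
  nr <- nrow(counts); nc <- ncol(counts)
  cells_rows <- if (nr == nc) {
    if (orientation == "auto")
      stop("square matrix in ", mtx,
           ": pass orientation = 'cells_by_genes' or 'genes_by_cells'")
    orientation == "cells_by_genes"
  } else if (length(barcodes) == nr && length(genes) == nc) {
    TRUE
  } else if (length(barcodes) == nc && length(genes) == nr) {
    FALSE
  } else {
    stop("dimension mismatch: matrix.mtx is ", nr, " x ", nc, " but ",
         basename(genes_f), " has ", length(genes), " entries and ",
         basename(bc_f), " has ", length(barcodes), " entries")
  }
  if (!cells_rows) counts <- Matrix::t(counts)
  if (length(genes) != ncol(counts))
    stop("dimension mismatch: ", basename(genes_f), " has ", length(genes),
         " entries, matrix has ", ncol(counts), " genes")
  if (length(barcodes) != nrow(counts))
    stop("dimension mismatch: ", basename(bc_f), " has ", length(barcodes),
         " entries, matrix has ", nrow(counts), " cells")
  sc_matrix(counts, gene_ids = genes, cell_ids = barcodes)
}

read_dense_csv <- function(file) {
  sep <- if (grepl("\\.tsv$|\\.txt$", file)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = "character")
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
           dimnames = list(rownames(df), colnames(df))))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("non-numeric entry in ", file, " at data line ", bad["row"],
         ", column '", colnames(mat)[bad["col"]], "'")
  }
  sc_matrix(mat)
}

#' Read a per-cell label file
#'
#' @param file Two-column TSV/CSV (barcode, label); a header line is
#'   detected and skipped if its first field is one of the common header
#'   words.
#' @return Named character vector of labels (names = barcodes).
#' @export
read_labels <- function(file) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  df <- utils::read.table(file, header = FALSE, sep = sep,
                          colClasses = "character")
  if (ncol(df) < 2) stop("labels file needs two columns: ", file)
  if (tolower(df[1, 1]) %in% c("barcode", "cell", "cell_id", "barcodes"))
    df <- df[-1, , drop = FALSE]
  stats::setNames(df[[2]], df[[1]])
}

#' Write an expression matrix to disk
#'
#' @param m An [sc_matrix].
#' @param path Output directory (triplet) or file (dense CSV/TSV).
#' @param format `"mtx_triplet"` or `"dense_csv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("mtx_triplet", "dense_csv")) {
  stopifnot(inherits(m, "sc_matrix"))
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
    writeLines(m$gene_ids, file.path(path, "genes.tsv"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    if (!is.null(m$labels))
      utils::write.table(data.frame(m$cell_ids, m$labels),
                         file.path(path, "labels.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    df <- as.data.frame(as.matrix(m$counts))
    utils::write.table(cbind(barcode = m$cell_ids, df), path,
                       sep = if (grepl("\\.tsv$", path)) "\t" else ",",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
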