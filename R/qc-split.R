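#' Cell quality-control parameters
#'
#' Default thresholds follow common droplet scRNA-seq practice: a cell is
#' kept when it has strictly more than 200 detected genes, strictly more
#' than 250 total UMIs, and a mitochondrial read fraction strictly below
#' 20%. Mitochondrial genes are recognised by a case-insensitive gene-id
#' prefix.
#'
#' @param min_genes_per_cell Detected-gene threshold (strict `>`).
#' @param min_umis_per_cell Total-UMI threshold (strict `>`).
#' @param max_mito_fraction Mitochondrial fraction threshold (strict `<`),
#'   in `[0, 1]`.
#' @param mito_gene_prefix Gene-id prefix marking mitochondrial genes.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_cell = 200, min_umis_per_cell = 250,
                      max_mito_fraction = 0.20, mito_gene_prefix = "MT-") {
  stopifnot(min_genes_per_cell > 0, min_umis_per_cell > 0,
            max_mito_fraction > 0, max_mito_fraction <= 1)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_umis_per_cell = min_umis_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 mito_gene_prefix = mito_gene_prefix),
            class = "qc_params")
}

#' Filter cells by quality-control thresholds
#'
#' Keeps exactly the cells passing all three criteria of [qc_params]; the
#' gene set is unchanged. The number of cells failing each criterion is
#' attached as attribute `"qc_removed"` (a cell can count against several
#' criteria).
#'
#' @param m An [sc_matrix].
#' @param q A [qc_params] object.
#' @return The filtered [sc_matrix].
#' @export
apply_qc <- function(m, q = qc_params()) {
  stopifnot(inherits(m, "sc_matrix"), inherits(q, "qc_params"))
  counts <- m$counts
  n_genes <- Matrix::rowSums(counts > 0)
  n_umis <- Matrix::rowSums(counts)
  mito <- startsWith(toupper(m$gene_ids), toupper(q$mito_gene_prefix))
  mito_frac <- if (any(mito)) {
    mf <- Matrix::rowSums(counts[, mito, drop = FALSE]) / n_umis
    mf[n_umis == 0] <- 0
    mf
  } else rep(0, nrow(counts))
  pass_genes <- n_genes > q$min_genes_per_cell
  pass_umis <- n_umis > q$min_umis_per_cell
  pass_mito <- mito_frac < q$max_mito_fraction
  keep <- pass_genes & pass_umis & pass_mito
  if (!any(keep)) warning("QC removed all cells")
  out <- subset_cells(m, cells = keep)
  attr(out, "qc_removed") <- c(low_genes = sum(!pass_genes),
                               low_umis = sum(!pass_umis),
                               high_mito = sum(!pass_mito))
  out
}

#' Stratified train/test split
#'
#' Partitions cells into disjoint train and test sets. Under
#' stratification the per-class test count is `round(class_size *
#' test_fraction)`; the draw is deterministic for a fixed seed.
#'
#' @param m A labelled [sc_matrix]; every class needs at least 2 cells
#'   when stratifying.
#' @param test_fraction Fraction of cells assigned to the test set,
#'   in (0, 1).
#' @param stratified Draw per class (default) or from the pooled cells.
#' @param seed Integer seed controlling the draw.
#' @return A list with elements `train` and `test`, both [sc_matrix].
#' @export
split_cells <- function(m, test_fraction = 0.2, stratified = TRUE,
                        seed = 1L) {
  stopifnot(inherits(m, "sc_matrix"),
            test_fraction > 0, test_fraction < 1)
  if (is.null(m$labels)) stop("split requires labels; call set_labels()")
  n <- length(m$cell_ids)
  test_idx <- local_seed(seed, {
    if (stratified) {
      tab <- table(m$labels)
      if (any(tab < 2))
        stop("class(es) with a single cell cannot be stratified: ",
             paste(names(tab)[tab < 2], collapse = ", "))
      unlist(lapply(names(tab), function(cl) {
        idx <- which(m$labels == cl)
        sample(idx, round(length(idx) * test_fraction))
      }), use.names = FALSE)
    } else sample(n, round(n * test_fraction))
  })
  list(train = subset_cells(m, cells = setdiff(seq_len(n), test_idx)),
       test = subset_cells(m, cells = sort(test_idx)))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

#' Library-size normalisation (counts per million, log1p)
#'
#' Optional preprocessing: scales each cell to one million total counts
#' and applies `log1p`. Raw counts are the package default throughout;
#' this transform is opt-in.
#'
#' @param m An [sc_matrix].
#' @return An [sc_matrix] with transformed values.
#' @export
normalize_cpm <- function(m) {
  stopifnot(inherits(m, "sc_matrix"))
  tot <- Matrix::rowSums(m$counts)
  tot[tot == 0] <- 1
  out <- m
  scaled <- Matrix::Diagonal(x = 1e6 / tot) %*% m$counts
  out$counts <- methods::as(log1p(scaled), "CsparseMatrix")
  dimnames(out$counts) <- dimnames(m$counts)
  out
}
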