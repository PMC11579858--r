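#' Synthetic scRNA-seq configuration
#'
#' Parameterizes the ground-truth generator: labelled negative-binomial
#' count matrices with a small set of class-discriminative (informative)
#' genes planted among many uninformative ones. Defaults mirror a
#' five-subpopulation breast-tumour dissociation: five classes with
#' 773/1184/897/1020/1000 cells, 2,000 genes of which 50 carry a
#' class-specific four-fold (log2FC 2) mean shift, moderate
#' overdispersion (negative-binomial size 5), and no extra dropout beyond
#' what the count model itself produces.
#'
#' @param n_classes Number of cell classes (>= 2).
#' @param cells_per_class Integer vector, one count per class.
#' @param n_genes Total genes.
#' @param n_informative Genes given a class-specific mean shift
#'   (`<= n_genes`).
#' @param effect_log2fc Log2 fold-change applied to an informative gene's
#'   mean in its assigned class (> 0 to plant signal; 0 gives a null
#'   dataset).
#' @param baseline_mean_range Positive interval; baseline gene means are
#'   drawn log-uniformly from it.
#' @param dispersion Negative-binomial size parameter (> 0); variance is
#'   `mu + mu^2 / dispersion`.
#' @param dropout_extra Extra zero-inflation probability in `[0, 1)`.
#' @param seed Integer seed; generation is deterministic per seed.
#' @param class_names Optional class label strings.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 5,
                             cells_per_class = c(773, 1184, 897, 1020, 1000),
                             n_genes = 2000, n_informative = 50,
                             effect_log2fc = 2,
                             baseline_mean_range = c(0.1, 3),
                             dispersion = 5, dropout_extra = 0,
                             seed = 1L, class_names = NULL) {
  if (n_classes < 2) stop("invalid n_classes: must be >= 2")
  if (length(cells_per_class) == 1)
    cells_per_class <- rep(cells_per_class, n_classes)
  if (length(cells_per_class) != n_classes)
    stop("invalid cells_per_class: length must equal n_classes")
  if (any(cells_per_class < 1)) stop("invalid cells_per_class: must be >= 1")
  if (n_genes < 1) stop("invalid n_genes")
  if (n_informative < 0 || n_informative > n_genes)
    stop("invalid n_informative: must be in [0, n_genes]")
  if (effect_log2fc < 0) stop("invalid effect_log2fc: must be >= 0")
  if (length(baseline_mean_range) != 2 || any(baseline_mean_range <= 0) ||
      diff(baseline_mean_range) < 0)
    stop("invalid baseline_mean_range: need a positive interval")
  if (dispersion <= 0) stop("invalid dispersion: must be > 0")
  if (dropout_extra < 0 || dropout_extra >= 1)
    stop("invalid dropout_extra: must be in [0, 1)")
  if (is.null(class_names))
    class_names <- paste0("class", seq_len(n_classes))
  if (length(class_names) != n_classes)
    stop("invalid class_names: length must equal n_classes")
  structure(list(n_classes = as.integer(n_classes),
                 cells_per_class = as.integer(cells_per_class),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_log2fc = effect_log2fc,
                 baseline_mean_range = baseline_mean_range,
                 dispersion = dispersion, dropout_extra = dropout_extra,
                 seed = as.integer(seed), class_names = class_names),
            class = "synthetic_config")
}

#' Generate a labelled synthetic count matrix
#'
#' Draws counts from a negative binomial with gene-wise baseline means
#' (log-uniform over `baseline_mean_range`) and common dispersion. Each
#' informative gene is assigned one class round-robin (so every class has
#' markers) and its mean is multiplied by `2^effect_log2fc` in that
#' class. Optional extra zero-inflation masks entries independently at
#' rate `dropout_extra`. Bitwise deterministic for a fixed seed.
#'
#' @param cfg A [synthetic_config].
#' @return List with `matrix` (a labelled [sc_matrix]) and `truth`: list
#'   of `informative_gene_ids`, `class_of_gene` (named character map for
#'   the informative genes), `true_labels`, and `baseline_means`.
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_cells <- sum(cfg$cells_per_class)
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  labels <- rep(cfg$class_names, cfg$cells_per_class)
  local_seed(cfg$seed, {
    baseline <- exp(stats::runif(cfg$n_genes,
                                 log(cfg$baseline_mean_range[1]),
                                 log(cfg$baseline_mean_range[2])))
    informative <- sort(sample.int(cfg$n_genes, cfg$n_informative))
    gene_class <- rep_len(cfg$class_names, length(informative))
    mu_class <- matrix(baseline, nrow = cfg$n_classes,
                       ncol = cfg$n_genes, byrow = TRUE,
                       dimnames = list(cfg$class_names, gene_ids))
    fc <- 2^cfg$effect_log2fc
    for (i in seq_along(informative))
      mu_class[gene_class[i], informative[i]] <-
        mu_class[gene_class[i], informative[i]] * fc
    counts <- matrix(0, n_cells, cfg$n_genes)
    for (k in seq_len(cfg$n_classes)) {
      rows <- which(labels == cfg$class_names[k])
      counts[rows, ] <- matrix(
        stats::rnbinom(length(rows) * cfg$n_genes,
                       mu = rep(mu_class[k, ], each = length(rows)),
                       size = cfg$dispersion),
        nrow = length(rows))
    }
    if (cfg$dropout_extra > 0)
      counts[matrix(stats::runif(length(counts)) < cfg$dropout_extra,
                    nrow = n_cells)] <- 0
  })
  m <- sc_matrix(counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 labels = labels)
  truth <- list(informative_gene_ids = gene_ids[informative],
                class_of_gene = stats::setNames(gene_class,
                                                gene_ids[informative]),
                true_labels = stats::setNames(labels, cell_ids),
                baseline_means = stats::setNames(baseline, gene_ids))
  list(matrix = m, truth = truth)
}

#' Write a ready-to-read synthetic fixture
#'
#' Writes a Matrix Market triplet (plus `labels.tsv`) for one of three
#' canned shapes: `tiny` (5 classes x 20 cells x 200 genes, for fast
#' tests), `default` (the five-subpopulation inventory
#' 773/1184/897/1020/1000 x 2,000 genes), `stress` (same cells, 29,733
#' genes, for scaling tests).
#'
#' @param name Fixture name.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return List with `dir`, `config` and `truth`, invisibly.
#' @export
make_fixture <- function(name = c("tiny", "default", "stress"),
                         dir = tempfile(paste0("fixture_", name)),
                         seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = synthetic_config(n_classes = 5, cells_per_class = rep(20L, 5),
                            n_genes = 200, n_informative = 25,
                            effect_log2fc = 2, dispersion = 5,
                            seed = seed),
    default = synthetic_config(seed = seed),
    stress = synthetic_config(n_genes = 29733, n_informative = 50,
                              seed = seed))
  sim <- generate_synthetic(cfg)
  write_matrix(sim$matrix, dir, format = "mtx_triplet")
  invisible(list(dir = dir, config = cfg, truth = sim$truth))
}
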