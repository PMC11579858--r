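#' @title Per-gene importance rankings
#' @description Three complementary scorers rank genes of a labelled
#'   expression matrix: a multiclass F-score (between-class separation over
#'   within-class variance), excess squared coefficient of variation above a
#'   fitted technical baseline, and PCA-loading importance. All three obey
#'   the same exclusion rule: genes whose score is zero, negative or
#'   undefined are dropped from the ranking.
#' @name feature_scoring
NULL

# Small denominator guard so perfectly separating genes (zero within-class
# variance, nonzero between-class separation) get finite, maximal scores.
.FSCORE_EPS <- 1e-12

feature_ranking <- function(method, scores, gene_ids) {
  stopifnot(length(scores) == length(gene_ids))
  keep <- is.finite(scores) & scores > 0
  ord <- order(-scores[keep])          # stable: ties keep input gene order
  structure(list(method = method,
                 scores = stats::setNames(as.numeric(scores), gene_ids),
                 ranked_gene_ids = gene_ids[keep][ord],
                 n_excluded = sum(!keep)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("feature_ranking [", x$method, "]: ", length(x$ranked_gene_ids),
      " ranked genes, ", x$n_excluded, " excluded (score <= 0)\n", sep = "")
  invisible(x)
}

#' @export
length.feature_ranking <- function(x) length(x$ranked_gene_ids)

# Per-class column sums and sums of squares in one sparse pass.
class_moments <- function(counts, labels) {
  classes <- sort(unique(labels))
  sums <- do.call(rbind, lapply(classes, function(cl)
    Matrix::colSums(counts[labels == cl, , drop = FALSE])))
  sumsq <- do.call(rbind, lapply(classes, function(cl)
    Matrix::colSums(counts[labels == cl, , drop = FALSE]^2)))
  list(classes = classes, n = as.integer(table(labels)[classes]),
       sums = sums, sumsq = sumsq)
}

binary_fscore <- function(pos_sum, pos_sumsq, n_pos,
                          neg_sum, neg_sumsq, n_neg) {
  mu_pos <- pos_sum / n_pos
  mu_neg <- neg_sum / n_neg
  mu_all <- (pos_sum + neg_sum) / (n_pos + n_neg)
  var_pos <- pmax(0, (pos_sumsq - n_pos * mu_pos^2) / (n_pos - 1))
  var_neg <- pmax(0, (neg_sumsq - n_neg * mu_neg^2) / (n_neg - 1))
  num <- (mu_pos - mu_all)^2 + (mu_neg - mu_all)^2
  f <- num / (var_pos + var_neg + .FSCORE_EPS)
  f[num == 0] <- 0
  f
}

#' F-score gene ranking
#'
#' For two classes each gene's score is the classical feature-selection
#' F-score: the squared deviations of the two class means from the global
#' mean, divided by the sum of the within-class sample variances. With more
#' than two classes the score is aggregated over one-vs-rest binary
#' F-scores (mean by default). Genes with zero within-class variance but
#' nonzero separation receive finite, very large scores through a tiny
#' denominator guard; genes constant everywhere score 0 and are excluded.
#'
#' @param m A labelled [sc_matrix] with at least 2 classes, each of at
#'   least 2 cells.
#' @param aggregate How one-vs-rest scores are combined for > 2 classes:
#'   `"mean"` (default) or `"max"`.
#' @return A `feature_ranking` (method `"fscore"`).
#' @export
fscore_rank <- function(m, aggregate = c("mean", "max")) {
  stopifnot(inherits(m, "sc_matrix"))
  aggregate <- match.arg(aggregate)
  if (is.null(m$labels)) stop("fscore_rank requires labels")
  tab <- table(m$labels)
  if (length(tab) < 2) stop("need >= 2 classes, got ", length(tab))
  if (any(tab < 2))
    stop("every class needs >= 2 cells; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  cm <- class_moments(m$counts, m$labels)
  tot_sum <- colSums(cm$sums)
  tot_sumsq <- colSums(cm$sumsq)
  n_tot <- sum(cm$n)
  per_class <- vapply(seq_along(cm$classes), function(i)
    as.numeric(binary_fscore(cm$sums[i, ], cm$sumsq[i, ], cm$n[i],
                             tot_sum - cm$sums[i, ],
                             tot_sumsq - cm$sumsq[i, ],
                             n_tot - cm$n[i])),
    numeric(ncol(m$counts)))
  per_class <- matrix(per_class, nrow = ncol(m$counts))
  scores <- if (length(cm$classes) == 2) {
    # both one-vs-rest views are the same binary problem; use it directly
    per_class[, 1]
  } else if (aggregate == "mean") {
    rowMeans(per_class)
  } else apply(per_class, 1, max)
  feature_ranking("fscore", scores, m$gene_ids)
}

#' CV-squared gene ranking with technical-baseline fit
#'
#' Computes each gene's observed squared coefficient of variation
#' (variance over squared mean) and fits the technical-noise relationship
#' `CV2(mu) = a1/mu + a0` across genes by a gamma-family, identity-link
#' generalized linear model of observed CV2 against `1/mu`. The importance
#' score is `log2(observed / fitted)`, so genes at or below the fitted
#' technical baseline (score <= 0) drop out of the ranking under the
#' global exclusion rule.
#'
#' @param m An [sc_matrix]; labels are not used. Needs >= 2 genes with
#'   positive mean and distinct means.
#' @return A `feature_ranking` (method `"cv2"`) with an extra element
#'   `fit`: list of `a1`, `a0`, per-gene `mu` and observed `cv2`.
#' @export
cv2_rank <- function(m) {
  stopifnot(inherits(m, "sc_matrix"))
  mu <- Matrix::colMeans(m$counts)
  n <- nrow(m$counts)
  v <- (Matrix::colSums(m$counts^2) - n * mu^2) / (n - 1)
  v <- pmax(v, 0)
  cv2 <- rep(NA_real_, length(mu))
  pos <- mu > 0
  if (any(!pos)) warning(sum(!pos), " zero-mean gene(s) skipped")
  cv2[pos] <- v[pos] / mu[pos]^2
  use <- pos & cv2 > 0
  if (sum(use) < 2 || length(unique(mu[use])) < 2)
    stop("degenerate CV2 fit: need >= 2 genes with positive, ",
         "distinct means and positive CV2")
  fit <- fit_cv2_glm(mu[use], cv2[use])
  fitted_all <- rep(NA_real_, length(mu))
  fitted_all[pos] <- fit$a1 / mu[pos] + fit$a0
  scores <- rep(NA_real_, length(mu))
  ok <- pos & is.finite(cv2) & cv2 > 0 & fitted_all > 0
  scores[ok] <- log2(cv2[ok] / fitted_all[ok])
  rk <- feature_ranking("cv2", scores, m$gene_ids)
  rk$fit <- list(a1 = fit$a1, a0 = fit$a0,
                 mu = stats::setNames(mu, m$gene_ids),
                 cv2 = stats::setNames(cv2, m$gene_ids))
  rk
}

# Gamma-family identity-link GLM of cv2 on 1/mu, started from the
# ordinary least-squares line; falls back to the OLS coefficients if the
# gamma fit cannot be completed on degenerate inputs.
fit_cv2_glm <- function(mu, cv2) {
  x <- 1 / mu
  ls <- stats::lm.fit(cbind(1, x), cv2)$coefficients
  co <- tryCatch({
    start <- ls
    if (any(start[1] + start[2] * x <= 0))
      start <- c(mean(cv2), 0)
    g <- suppressWarnings(stats::glm(cv2 ~ x,
                                     family = stats::Gamma(link = "identity"),
                                     start = start))
    stats::coef(g)
  }, error = function(e) {
    warning("gamma GLM failed (", conditionMessage(e),
            "); using least-squares line")
    ls
  })
  list(a0 = unname(co[1]), a1 = unname(co[2]))
}

#' PCA-loading gene ranking
#'
#' Standardizes the matrix gene-wise, takes the leading principal
#' components, and scores gene `i` as `sum_j |loading_ij| * EVR_j`, the
#' absolute loadings weighted by each component's explained-variance
#' ratio. By default components are retained up to 90% cumulative
#' explained variance. Genes constant across cells have no defined
#' standardization and are assigned score 0 (hence excluded).
#'
#' @param m An [sc_matrix]; labels are not used.
#' @param n_components Number of leading components, or `NULL` to choose
#'   by `var_explained`.
#' @param var_explained Cumulative explained-variance cutoff used when
#'   `n_components` is `NULL`.
#' @return A `feature_ranking` (method `"pca"`).
#' @export
pca_rank <- function(m, n_components = NULL, var_explained = 0.9) {
  stopifnot(inherits(m, "sc_matrix"))
  x <- as.matrix(m$counts)
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  xs <- scale(x, center = TRUE, scale = ifelse(const, 1, sds))
  xs[, const] <- 0
  max_pc <- min(nrow(xs) - 1L, ncol(xs))
  if (!is.null(n_components)) {
    if (n_components < 1) stop("n_components must be >= 1")
    if (n_components > max_pc)
      stop("n_components (", n_components, ") exceeds min(cells - 1, genes) = ",
           max_pc)
  }
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_components)) {
    max(1L, which(cumsum(evr) >= var_explained)[1])
  } else as.integer(n_components)
  k <- min(k, ncol(pc$rotation))
  scores <- abs(pc$rotation[, seq_len(k), drop = FALSE]) %*%
    evr[seq_len(k)]
  scores <- as.numeric(scores)
  scores[const] <- 0
  feature_ranking("pca", scores, m$gene_ids)
}

#' Top-k overlap between rankings
#'
#' Counts how many genes the top-`k` prefixes of two or more rankings
#' share, pairwise and jointly — the numeric counterpart of a Venn
#' diagram over scorers.
#'
#' @param rankings List of >= 2 `feature_ranking` objects.
#' @param k Prefix length; must not exceed the shortest ranking.
#' @return List with `k`, a symmetric `pairwise` count matrix (methods as
#'   dimnames), and `common_genes`, the genes in every top-k prefix.
#' @export
topk_overlap <- function(rankings, k = 100) {
  if (length(rankings) < 2) stop("need >= 2 rankings")
  stopifnot(all(vapply(rankings, inherits, logical(1), "feature_ranking")))
  shortest <- min(vapply(rankings, length, integer(1)))
  if (k > shortest)
    stop("k (", k, ") exceeds shortest ranking (", shortest, ")")
  tops <- lapply(rankings, function(r) r$ranked_gene_ids[seq_len(k)])
  methods_ <- vapply(rankings, `[[`, character(1), "method")
  nm <- make.unique(methods_)
  p <- outer(seq_along(tops), seq_along(tops),
             Vectorize(function(i, j) length(intersect(tops[[i]], tops[[j]]))))
  dimnames(p) <- list(nm, nm)
  list(k = k, pairwise = p, common_genes = Reduce(intersect, tops))
}

#' Write a ranking as TSV
#'
#' Columns: `gene_id`, `score`, `rank`, `method`; excluded genes are not
#' written.
#'
#' @param ranking A `feature_ranking`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ranking <- function(ranking, file) {
  ids <- ranking$ranked_gene_ids
  utils::write.table(
    data.frame(gene_id = ids, score = ranking$scores[ids],
               rank = seq_along(ids), method = ranking$method),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
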