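#' Rank genes by a named scoring method
#'
#' Dispatcher over the three scorers: `"fscore"` ([fscore_rank]),
#' `"cv2"` ([cv2_rank]) and `"pca"` ([pca_rank]).
#'
#' @param m A labelled [sc_matrix].
#' @param method Scorer name.
#' @param ... Passed to the scorer.
#' @return A `feature_ranking`.
#' @export
rank_genes <- function(m, method = c("fscore", "cv2", "pca"), ...) {
  method <- match.arg(method)
  switch(method,
         fscore = fscore_rank(m, ...),
         cv2 = cv2_rank(m, ...),
         pca = pca_rank(m, ...))
}

#' Geometric subset-size schedule
#'
#' Default grid of nested prefix sizes for incremental feature selection:
#' `n_points` sizes spaced geometrically from `from` to `n`, rounded and
#' de-duplicated.
#'
#' @param n Largest size (typically the ranking length).
#' @param n_points Number of grid points.
#' @param from Smallest size.
#' @return Strictly increasing integer vector.
#' @export
ifs_schedule <- function(n, n_points = 10, from = 10) {
  from <- min(from, n)
  sizes <- unique(round(exp(seq(log(from), log(n), length.out = n_points))))
  as.integer(sizes)
}

#' Incremental feature selection over one ranking and one classifier
#'
#' Walks the schedule of nested ranking prefixes in increasing order; at
#' each size trains the classifier (grid search + stratified CV, see
#' [train_classifier]) on the top-`s` genes and records the mean CV
#' accuracy. Stops early once `patience` consecutive sizes fail to improve
#' on the running maximum. The optimal size is the smallest evaluated size
#' achieving the maximum accuracy (first maximum under the plateau rule).
#' CV folds depend only on the labels and the seed, so they are identical
#' across subset sizes and the curve is comparable size-to-size.
#'
#' @param ranking A `feature_ranking`.
#' @param spec A [classifier_spec].
#' @param m The labelled [sc_matrix] the ranking refers to.
#' @param schedule Strictly increasing sizes, all `<= length(ranking)`;
#'   `NULL` for the default [ifs_schedule].
#' @param folds CV folds.
#' @param patience Consecutive non-improving sizes tolerated before
#'   stopping.
#' @return An `ifs_result`: `method_pair`, `subset_sizes` (evaluated),
#'   `cv_accuracy`, `optimal_size`, `optimal_gene_ids`, `stopped_early`.
#' @export
run_ifs <- function(ranking, spec, m, schedule = NULL, folds = 5,
                    patience = 3) {
  stopifnot(inherits(ranking, "feature_ranking"),
            inherits(spec, "classifier_spec"), inherits(m, "sc_matrix"))
  if (is.null(m$labels)) stop("run_ifs requires labels")
  if (is.null(schedule)) schedule <- ifs_schedule(length(ranking))
  schedule <- as.integer(schedule)
  if (!length(schedule)) stop("schedule must be non-empty")
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  if (max(schedule) > length(ranking))
    stop("schedule exceeds ranking length (", length(ranking), ")")
  acc <- numeric(0)
  sizes <- integer(0)
  best_acc <- -Inf
  stall <- 0L
  stopped <- FALSE
  for (s in schedule) {
    X <- feature_matrix(m, ranking$ranked_gene_ids[seq_len(s)])
    model <- train_classifier(spec, X, m$labels, folds = folds)
    sizes <- c(sizes, s)
    acc <- c(acc, model$cv_accuracy)
    if (model$cv_accuracy > best_acc) {
      best_acc <- model$cv_accuracy
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience && s < max(schedule)) {
        stopped <- TRUE
        break
      }
    }
  }
  opt <- which(acc == max(acc))[1]
  structure(list(method_pair = c(scorer = ranking$method,
                                 algorithm = spec$algorithm),
                 subset_sizes = sizes, cv_accuracy = acc,
                 optimal_size = sizes[opt],
                 optimal_accuracy = acc[opt],
                 optimal_gene_ids =
                   ranking$ranked_gene_ids[seq_len(sizes[opt])],
                 stopped_early = stopped),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("ifs_result [", x$method_pair[["scorer"]], " + ",
      x$method_pair[["algorithm"]], "]: optimal size ", x$optimal_size,
      ", CV accuracy ", sprintf("%.4f", x$optimal_accuracy),
      if (x$stopped_early) " (stopped early)", "\n", sep = "")
  invisible(x)
}

#' Sweep all scorer x classifier combinations
#'
#' Computes one ranking per scorer, runs [run_ifs] for every
#' (scorer, classifier) pair, and selects the winning combination: the
#' highest optimal CV accuracy, ties broken by smaller optimal size (a
#' simpler model at equal accuracy), then by declaration order. A shared
#' schedule is truncated per ranking to sizes within that ranking's
#' length.
#'
#' @param m A labelled [sc_matrix].
#' @param scorers Character vector of scorer names.
#' @param specs List of [classifier_spec]s.
#' @param schedule,folds,patience Passed to [run_ifs].
#' @return An `ifs_sweep`: `results` (list of `ifs_result`, scorer-major
#'   order), `summary` (data frame), `best` (index into `results`),
#'   `rankings` (named list of `feature_ranking`).
#' @export
sweep_ifs <- function(m, scorers = c("fscore", "cv2", "pca"),
                      specs = lapply(c("knn", "svm", "rfc", "xgboost"),
                                     classifier_spec),
                      schedule = NULL, folds = 5, patience = 3) {
  if (!length(scorers)) stop("need >= 1 scorer")
  if (!length(specs)) stop("need >= 1 classifier spec")
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  rankings <- stats::setNames(lapply(scorers, function(sc)
    rank_genes(m, sc)), scorers)
  results <- list()
  for (sc in scorers) {
    rk <- rankings[[sc]]
    sched <- if (is.null(schedule)) ifs_schedule(length(rk)) else {
      s <- schedule[schedule <= length(rk)]
      if (!length(s)) s <- length(rk)
      s
    }
    for (spec in specs)
      results[[length(results) + 1L]] <-
        run_ifs(rk, spec, m, schedule = sched, folds = folds,
                patience = patience)
  }
  summary_df <- do.call(rbind, lapply(results, function(r)
    data.frame(scorer = r$method_pair[["scorer"]],
               algorithm = r$method_pair[["algorithm"]],
               optimal_size = r$optimal_size,
               optimal_accuracy = r$optimal_accuracy)))
  best <- select_best_combination(summary_df)
  structure(list(results = results, summary = summary_df, best = best,
                 rankings = rankings),
            class = "ifs_sweep")
}

# Highest accuracy; ties -> smaller optimal size; ties -> earlier entry.
select_best_combination <- function(summary_df) {
  order(-summary_df$optimal_accuracy, summary_df$optimal_size,
        seq_len(nrow(summary_df)))[1]
}

#' @export
print.ifs_sweep <- function(x, ...) {
  cat("ifs_sweep: ", nrow(x$summary), " combinations\n", sep = "")
  print(x$summary)
  b <- x$summary[x$best, ]
  cat("best: ", b$scorer, " + ", b$algorithm, " (", b$optimal_size,
      " genes, CV accuracy ", sprintf("%.4f", b$optimal_accuracy), ")\n",
      sep = "")
  invisible(x)
}

#' Write an IFS curve as TSV (columns: size, cv_accuracy)
#' @param result An `ifs_result`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ifs_curve <- function(result, file) {
  utils::write.table(
    data.frame(size = result$subset_sizes,
               cv_accuracy = result$cv_accuracy),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
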