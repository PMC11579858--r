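#' Classifier specification
#'
#' Describes one of the four supported classifier families together with
#' its hyperparameter grid and the seed used for every stochastic
#' component (fold shuffling, tree subsampling, probability calibration).
#' Grid search over the grid with stratified k-fold cross-validated
#' accuracy is the selection criterion; on ties the first grid point in
#' declaration order wins (grid points are enumerated with the first
#' hyperparameter varying fastest).
#'
#' Default grids: knn `k in {1, 5, 15, 31}`; svm (RBF kernel)
#' `cost in {0.1, 1, 10}`, `gamma = "scale"` (1 / (p * var(X)));
#' rfc `num_trees in {100, 500}`, `max_depth in {0, 10}` (0 = unbounded);
#' xgboost `nrounds in {100, 300}`, `max_depth in {3, 6}`,
#' `eta in {0.1, 0.3}`.
#'
#' @param algorithm One of `"knn"`, `"svm"`, `"rfc"`, `"xgboost"`.
#' @param grid Named list of candidate value vectors; `NULL` for the
#'   documented default grid.
#' @param seed Integer seed.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("knn", "svm", "rfc", "xgboost"),
                            grid = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!length(grid)) stop("grid must be non-empty")
  structure(list(algorithm = algorithm, grid = grid,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

default_grid <- function(algorithm) {
  switch(algorithm,
         knn = list(k = c(1, 5, 15, 31)),
         svm = list(cost = c(0.1, 1, 10), gamma = "scale"),
         rfc = list(num_trees = c(100, 500), max_depth = c(0, 10)),
         xgboost = list(nrounds = c(100, 300), max_depth = c(3, 6),
                        eta = c(0.1, 0.3)))
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles each class independently and deals its members over the folds
#' round-robin, so every fold carries near-proportional class counts.
#' Deterministic for a fixed seed.
#'
#' @param y Label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_stratified_folds <- function(y, k = 5, seed = 1L) {
  y <- as.character(y)
  fold <- integer(length(y))
  local_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

#' Train a classifier with grid search
#'
#' Evaluates every grid point by stratified k-fold cross-validated
#' accuracy, picks the best (ties: first in declaration order), and
#' refits it on all of `X`. Fully deterministic given `spec$seed`.
#'
#' @param spec A [classifier_spec].
#' @param X Dense numeric matrix, cells x selected genes, with gene ids as
#'   column names.
#' @param y Label vector, one per row of `X`.
#' @param folds Number of CV folds; every class needs at least `folds`
#'   members.
#' @return A `trained_model`: list with `spec`, `chosen_params`,
#'   `cv_accuracy` (mean CV accuracy of the chosen point),
#'   `grid_results` (data frame of all points), `feature_gene_ids`,
#'   `classes`, and the opaque `fit`.
#' @export
train_classifier <- function(spec, X, y, folds = 5) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(X),
            nrow(X) == length(y))
  if (is.null(colnames(X))) stop("X needs gene ids as column names")
  y <- as.character(y)
  tab <- table(y)
  if (any(tab < folds))
    stop("class(es) with fewer than ", folds, " cells: ",
         paste(names(tab)[tab < folds], collapse = ", "),
         "; reduce the fold count")
  grid_df <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  fold_id <- make_stratified_folds(y, folds, spec$seed)
  cv_acc <- vapply(seq_len(nrow(grid_df)), function(g) {
    params <- as.list(grid_df[g, , drop = FALSE])
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_one(spec$algorithm, params, X[tr, , drop = FALSE],
                     y[tr], spec$seed)
      pred <- hard_predict(fit, X[!tr, , drop = FALSE])
      mean(pred == y[!tr])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(cv_acc)              # first maximum wins ties
  chosen <- as.list(grid_df[best, , drop = FALSE])
  fit <- fit_one(spec$algorithm, chosen, X, y, spec$seed)
  structure(list(spec = spec, chosen_params = chosen,
                 cv_accuracy = cv_acc[best],
                 grid_results = cbind(grid_df, cv_accuracy = cv_acc),
                 feature_gene_ids = colnames(X),
                 classes = sort(unique(y)), fit = fit),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model [", x$spec$algorithm, "]: ",
      length(x$feature_gene_ids), " genes, ", length(x$classes),
      " classes, CV accuracy ", sprintf("%.4f", x$cv_accuracy), "\n",
      "params: ", paste(names(x$chosen_params), unlist(x$chosen_params),
                        sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# --- per-family fitting ----------------------------------------------------

fit_one <- function(algorithm, params, X, y, seed) {
  classes <- sort(unique(y))
  fit <- switch(
    algorithm,
    knn = list(X = X, y = y, k = min(params$k, nrow(X))),
    svm = {
      gamma <- params$gamma
      if (identical(gamma, "scale")) {
        v <- stats::var(as.numeric(X))
        gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
      }
      local_seed(seed,
        e1071::svm(x = X, y = factor(y, levels = classes),
                   kernel = "radial", cost = params$cost,
                   gamma = as.numeric(gamma), probability = TRUE))
    },
    rfc = ranger::ranger(
      x = X, y = factor(y, levels = classes),
      num.trees = params$num_trees, max.depth = params$max_depth,
      probability = TRUE, seed = seed, num.threads = 1),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(
        X, label = as.integer(factor(y, levels = classes)) - 1L,
        nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes),
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed,
                      verbosity = 0),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    stop("unknown algorithm: ", algorithm))
  list(algorithm = algorithm, fit = fit, classes = classes,
       feature_gene_ids = colnames(X))
}

proba_one <- function(fitobj, X) {
  classes <- fitobj$classes
  p <- switch(
    fitobj$algorithm,
    knn = knn_proba(fitobj$fit, X, classes),
    svm = {
      pr <- stats::predict(fitobj$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, classes, drop = FALSE]
    },
    rfc = {
      pr <- stats::predict(fitobj$fit, data = X, num.threads = 1)$predictions
      pr[, classes, drop = FALSE]
    },
    xgboost = {
      pr <- stats::predict(fitobj$fit, xgboost::xgb.DMatrix(X, nthread = 1))
      if (is.null(dim(pr)))
        pr <- matrix(pr, nrow = nrow(X), ncol = length(classes),
                     byrow = TRUE)
      colnames(pr) <- classes
      pr
    })
  p <- pmax(p, 0)
  p <- p / rowSums(p)
  rownames(p) <- rownames(X)
  p
}

hard_predict <- function(fitobj, X) {
  p <- proba_one(fitobj, X)
  colnames(p)[max.col(p, ties.method = "first")]
}

# k-nearest-neighbour class-vote probabilities (Euclidean distance;
# neighbour ties broken by training order for determinism).
knn_proba <- function(fit, X, classes) {
  tr <- fit$X
  cross <- X %*% t(tr)
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * cross
  k <- fit$k
  p <- matrix(0, nrow(X), length(classes),
              dimnames = list(rownames(X), classes))
  for (i in seq_len(nrow(X))) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(factor(fit$y[nn], levels = classes))
    p[i, ] <- as.numeric(votes) / k
  }
  p
}

#' Class-probability predictions
#'
#' @param model A `trained_model`.
#' @param X Dense matrix whose columns are exactly the model's
#'   `feature_gene_ids`, in order (a mismatch is an error naming the
#'   missing/extra genes).
#' @return Matrix of per-cell class probabilities (columns = classes,
#'   rows sum to 1).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  check_feature_columns(colnames(X), model$feature_gene_ids)
  proba_one(model$fit, X)
}

#' Hard label predictions (argmax of [predict_proba])
#' @inheritParams predict_proba
#' @return Character vector of predicted class labels.
#' @export
predict_labels <- function(model, X) {
  p <- predict_proba(model, X)
  colnames(p)[max.col(p, ties.method = "first")]
}

check_feature_columns <- function(have, want) {
  if (is.null(have)) stop("prediction matrix needs gene ids as column names")
  if (identical(have, want)) return(invisible(TRUE))
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  msg <- "prediction matrix columns do not match model features"
  if (length(missing))
    msg <- paste0(msg, "; missing: ",
                  paste(utils::head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ...")
  if (length(extra))
    msg <- paste0(msg, "; extra: ",
                  paste(utils::head(extra, 5), collapse = ", "),
                  if (length(extra) > 5) ", ...")
  if (!length(missing) && !length(extra))
    msg <- paste0(msg, "; same genes but wrong order")
  stop(msg)
}

#' Dense feature submatrix for a gene subset, in the given order
#'
#' @param m An [sc_matrix].
#' @param gene_ids Ordered gene ids (e.g. a ranking prefix).
#' @return Dense cells x genes matrix with gene ids as column names.
#' @export
feature_matrix <- function(m, gene_ids) {
  as.matrix(m$counts[, gene_ids, drop = FALSE])
}
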