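#' Confusion matrix
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Ordered class labels; defaults to the sorted union of
#'   both vectors.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  tab <- table(factor(y_true, levels = classes),
               factor(y_pred, levels = classes))
  mat <- matrix(as.integer(tab), nrow = length(classes),
                dimnames = list(true = classes, predicted = classes))
  mat
}

#' One-vs-rest ROC curve points
#'
#' Sweeps the decision threshold over the score values (tied scores move
#' together) and returns the (FPR, TPR) staircase from (0, 0) to (1, 1).
#' The trapezoidal area under these points equals the probability that a
#' random positive outranks a random negative, with ties counting one
#' half.
#'
#' @param y_true_binary Logical vector (TRUE = positive); both classes
#'   must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(y_true_binary, scores) {
  stopifnot(length(y_true_binary) == length(scores))
  y <- as.logical(y_true_binary)
  if (all(y) || !any(y))
    stop("ROC needs both positive and negative examples")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  # indices after which the threshold can sit (end of each tie group)
  last_of_group <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  data.frame(fpr = c(0, fp / sum(!y)), tpr = c(0, tp / sum(y)))
}

#' Trapezoidal area under a ROC curve
#' @param roc Data frame from [roc_points].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Multiclass evaluation report
#'
#' Computes accuracy (correct over total), and per-class one-vs-rest
#' precision, recall and F1 from the confusion matrix, macro-averaged
#' (unweighted mean over classes) with micro averages alongside. Macro F1
#' is the mean of per-class F1 values, not the F1 of the macro precision
#' and recall. One-vs-rest ROC curves and trapezoidal AUCs are derived
#' from the probability columns. Empty ratios (0/0) are reported as 0
#' with a warning so reports never contain NaN; classes absent from
#' `y_true` get recall 0 and no ROC curve.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param y_proba Optional matrix of class probabilities (columns named
#'   by class, rows summing to 1); required for ROC/AUC.
#' @param classes Ordered class set; defaults to `colnames(y_proba)` or
#'   the sorted label union.
#' @return An `evaluation_report`: `accuracy`, `precision`, `recall`,
#'   `f1` (macro), `micro` (list), `per_class` (data frame), `confusion`,
#'   `roc` (per-class data frames), `auc` (per-class), `macro_auc`.
#' @export
evaluate_predictions <- function(y_true, y_pred, y_proba = NULL,
                                 classes = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(classes))
    classes <- if (!is.null(y_proba)) colnames(y_proba) else
      sort(unique(c(y_true, y_pred)))
  if (!is.null(y_proba)) {
    stopifnot(nrow(y_proba) == length(y_true))
    if (any(abs(rowSums(y_proba) - 1) > 1e-6))
      stop("probability rows must sum to 1")
    bad <- setdiff(unique(y_true), colnames(y_proba))
    if (length(bad))
      stop("true label(s) outside the model's classes: ",
           paste(bad, collapse = ", "))
  }
  cm <- confusion_matrix(y_true, y_pred, classes)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  if (any(rowSums(cm) == 0))
    warning("class(es) absent from y_true: ",
            paste(classes[rowSums(cm) == 0], collapse = ", "),
            "; their recall is reported as 0")
  roc <- auc <- NULL
  if (!is.null(y_proba)) {
    roc <- stats::setNames(vector("list", length(classes)), classes)
    auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
    for (cl in classes) {
      pos <- y_true == cl
      if (any(pos) && !all(pos)) {
        roc[[cl]] <- roc_points(pos, y_proba[, cl])
        auc[cl] <- auc_trapezoid(roc[[cl]])
      }
    }
  }
  structure(list(
    accuracy = sum(tp) / total,
    precision = mean(precision), recall = mean(recall), f1 = mean(f1),
    micro = list(precision = sum(tp) / (sum(tp) + sum(fp)),
                 recall = sum(tp) / (sum(tp) + sum(fn))),
    per_class = data.frame(class = classes, n = rowSums(cm), tp = tp,
                           fp = fp, fn = fn,
                           tn = total - tp - fp - fn,
                           precision = precision, recall = recall,
                           f1 = f1,
                           auc = if (is.null(auc)) NA_real_ else auc,
                           row.names = NULL),
    confusion = cm, roc = roc, auc = auc,
    macro_auc = if (is.null(auc)) NA_real_ else
      mean(auc, na.rm = TRUE)),
    class = "evaluation_report")
}

safe_ratio <- function(num, den, what) {
  out <- num / den
  if (any(den == 0)) {
    warning("0/0 in ", what, " reported as 0")
    out[den == 0] <- 0
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: accuracy %.4f | macro P %.4f R %.4f F1 %.4f",
    x$accuracy, x$precision, x$recall, x$f1))
  if (!is.null(x$auc)) cat(sprintf(" | macro AUC %.4f", x$macro_auc))
  cat("\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report (JSON scalars + TSV tables)
#'
#' Writes `<prefix>.json` (all scalar metrics and the per-class table),
#' `<prefix>_confusion.tsv`, and one `<prefix>_roc_<class>.tsv` per class
#' with a ROC curve.
#'
#' @param report An `evaluation_report`.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, prefix) {
  files <- character(0)
  json <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, f1 = report$f1,
         micro = report$micro, macro_auc = report$macro_auc,
         per_class = report$per_class),
    json, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  files <- c(files, json)
  conf <- paste0(prefix, "_confusion.tsv")
  utils::write.table(report$confusion, conf, sep = "\t", quote = FALSE,
                     col.names = NA)
  files <- c(files, conf)
  for (cl in names(report$roc)) {
    if (is.null(report$roc[[cl]])) next
    f <- paste0(prefix, "_roc_", gsub("[^A-Za-z0-9._-]", "_", cl), ".tsv")
    utils::write.table(report$roc[[cl]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
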