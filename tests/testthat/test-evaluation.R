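test_that("perfect predictions score 1.0 on every metric", {
  y <- rep(c("A", "B", "C"), each = 4)
  proba <- matrix(0, 12, 3, dimnames = list(NULL, c("A", "B", "C")))
  proba[cbind(seq_len(12), match(y, colnames(proba)))] <- 1
  rep_ <- evaluate_predictions(y, y, proba)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$recall, 1)
  expect_equal(rep_$f1, 1)
  expect_equal(unname(rep_$auc), rep(1, 3))
  expect_equal(rep_$macro_auc, 1)
})

test_that("the 2x2 worked example reproduces hand-computed macro metrics", {
  # confusion [[2,1],[1,2]]: accuracy 4/6, macro P = R = F1 = 2/3
  y_true <- c("A", "A", "A", "B", "B", "B")
  y_pred <- c("A", "A", "B", "A", "B", "B")
  rep_ <- evaluate_predictions(y_true, y_pred)
  expect_equal(rep_$confusion,
               matrix(c(2L, 1L, 1L, 2L), 2,
                      dimnames = list(true = c("A", "B"),
                                      predicted = c("A", "B"))))
  expect_equal(rep_$accuracy, 4 / 6)
  expect_equal(rep_$precision, 2 / 3)
  expect_equal(rep_$recall, 2 / 3)
  expect_equal(rep_$f1, 2 / 3)
})

test_that("confusion-matrix marginals reconcile with per-class TP/FP/FN/TN", {
  set.seed(71)
  classes <- c("A", "B", "C", "D")
  y_true <- sample(classes, 200, replace = TRUE)
  y_pred <- sample(classes, 200, replace = TRUE)
  rep_ <- evaluate_predictions(y_true, y_pred)
  cm <- rep_$confusion
  pc <- rep_$per_class
  expect_equal(pc$tp + pc$fn, unname(rowSums(cm)))
  expect_equal(pc$tp + pc$fp, unname(colSums(cm)))
  expect_equal(pc$tp + pc$fp + pc$fn + pc$tn, rep(200L, 4))
  expect_equal(rep_$accuracy, sum(diag(cm)) / sum(cm))
})

test_that("evaluation is invariant to permuting the cells", {
  set.seed(72)
  y_true <- sample(c("A", "B", "C"), 60, replace = TRUE)
  proba <- matrix(stats::runif(180), 60, 3,
                  dimnames = list(NULL, c("A", "B", "C")))
  proba <- proba / rowSums(proba)
  y_pred <- colnames(proba)[max.col(proba)]
  r1 <- evaluate_predictions(y_true, y_pred, proba)
  perm <- sample(60)
  r2 <- evaluate_predictions(y_true[perm], y_pred[perm],
                             proba[perm, , drop = FALSE])
  expect_equal(r1$confusion, r2$confusion)
  expect_equal(r1$f1, r2$f1)
  expect_equal(r1$auc, r2$auc)
})

test_that("macro F1 averages per-class F1, not the F1 of macro P/R", {
  # crafted so mean(per-class F1) != F1(macro P, macro R)
  y_true <- c(rep("A", 8), rep("B", 2))
  y_pred <- c(rep("A", 6), "B", "B", "A", "B")
  rep_ <- evaluate_predictions(y_true, y_pred)
  f1_per_class <- rep_$per_class$f1
  macro_from_pr <- 2 * rep_$precision * rep_$recall /
    (rep_$precision + rep_$recall)
  expect_equal(rep_$f1, mean(f1_per_class))
  expect_false(isTRUE(all.equal(rep_$f1, macro_from_pr)))
})

test_that("degenerate ratios warn and report 0, never NaN", {
  # class C never predicted -> precision 0/0; class D absent from truth
  y_true <- c("A", "A", "B", "B", "C")
  y_pred <- c("A", "A", "B", "B", "B")
  expect_warning(r1 <- evaluate_predictions(y_true, y_pred,
                                            classes = c("A", "B", "C")),
                 "precision")
  expect_false(anyNA(r1$per_class$precision))
  expect_equal(r1$per_class$precision[r1$per_class$class == "C"], 0)

  w <- capture_warnings(
    r2 <- evaluate_predictions(c("A", "A", "B"), c("A", "A", "B"),
                               classes = c("A", "B", "D")))
  expect_true(any(grepl("absent", w)))
  expect_equal(r2$per_class$recall[r2$per_class$class == "D"], 0)

  proba <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(evaluate_predictions(c("A", "Z"), c("A", "B"), proba),
               "outside")
})

test_that("ROC staircases are monotone from (0,0) to (1,1) with boundary AUCs", {
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  perfect <- roc_points(y, c(9, 8, 7, 3, 2, 1))
  expect_equal(auc_trapezoid(perfect), 1)
  reversed <- roc_points(y, c(1, 2, 3, 7, 8, 9))
  expect_equal(auc_trapezoid(reversed), 0)
  ties <- roc_points(y, rep(5, 6))
  expect_equal(auc_trapezoid(ties), 0.5)
  for (r in list(perfect, reversed, ties)) {
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[nrow(r)], r$tpr[nrow(r)]), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
  expect_error(roc_points(c(TRUE, TRUE), c(1, 2)), "both")
})

test_that("trapezoidal AUC equals brute-force pair counting with ties", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (all(y) || !any(y)) y[1:2] <- c(TRUE, FALSE)
    s <- sample(round(stats::runif(n, 0, 5), 1))  # deliberate ties
    expect_equal(auc_trapezoid(roc_points(y, s)), oracle_auc(y, s),
                 tolerance = 1e-12)
  }
})

test_that("reports serialize to JSON and TSV", {
  set.seed(75)
  y_true <- sample(c("A", "B"), 30, replace = TRUE)
  proba <- matrix(stats::runif(60), 30, 2, dimnames = list(NULL, c("A", "B")))
  proba <- proba / rowSums(proba)
  y_pred <- colnames(proba)[max.col(proba)]
  rep_ <- evaluate_predictions(y_true, y_pred, proba)
  prefix <- tempfile("report")
  files <- write_report(rep_, prefix)
  expect_true(all(file.exists(files)))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$accuracy, rep_$accuracy)
  conf <- as.matrix(read.delim(paste0(prefix, "_confusion.tsv"),
                               row.names = 1))
  expect_equal(unname(conf), unname(rep_$confusion), ignore_attr = TRUE)
})
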