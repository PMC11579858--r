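#' Pipeline configuration
#'
#' Bundles every stage's parameters for an end-to-end run:
#' QC -> stratified split -> gene ranking per scorer -> IFS sweep ->
#' refit of the winning combination on the training split -> evaluation
#' on the held-out split -> reports. All randomness funnels through the
#' single `seed`; stages draw deterministic derived seeds (`seed + 1` for
#' the split, `seed + 2` for classifier fitting and CV folds).
#'
#' @param input Path to the input matrix (triplet directory or dense
#'   CSV/TSV) or an [sc_matrix] built in code.
#' @param labels Optional labels file path (ignored when `input` already
#'   carries labels).
#' @param format Input format, see [read_matrix].
#' @param qc A [qc_params], or `NULL` to skip QC.
#' @param test_fraction,stratified Split parameters, see [split_cells].
#' @param scorers Scorer names for the sweep.
#' @param classifiers Classifier algorithm names or [classifier_spec]s.
#' @param schedule,folds,patience IFS parameters, see [run_ifs].
#' @param normalize Apply [normalize_cpm] before scoring/classification.
#' @param seed Integer master seed (mandatory).
#' @param output_dir Directory for all artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, labels = NULL, format = "auto",
                            qc = qc_params(), test_fraction = 0.2,
                            stratified = TRUE,
                            scorers = c("fscore", "cv2", "pca"),
                            classifiers = c("knn", "svm", "rfc", "xgboost"),
                            schedule = NULL, folds = 5, patience = 3,
                            normalize = FALSE, seed, output_dir) {
  if (missing(seed)) stop("seed is mandatory")
  if (missing(output_dir)) stop("output_dir is mandatory")
  structure(list(input = input, labels = labels, format = format, qc = qc,
                 test_fraction = test_fraction, stratified = stratified,
                 scorers = scorers, classifiers = classifiers,
                 schedule = schedule, folds = folds, patience = patience,
                 normalize = normalize, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes every stage of [pipeline_config] and writes rankings
#' (`ranking_<method>.tsv`), IFS curves (`ifs_<scorer>_<algorithm>.tsv`),
#' a sweep summary (`ifs_summary.tsv`), the winning model archive
#' (`model.rds`), the held-out evaluation report (`evaluation.json` +
#' TSVs), and a JSON run manifest. Re-running with the same configuration
#' and seed reproduces all numeric outputs.
#'
#' @param cfg A [pipeline_config].
#' @param quiet Suppress stage log lines.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(stage, ...) if (!quiet)
    message("[", stage, "] ", ...)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  files <- character(0)

  m <- if (inherits(cfg$input, "sc_matrix")) cfg$input else
    read_matrix(cfg$input, format = cfg$format, labels = cfg$labels)
  if (is.null(m$labels)) stop("pipeline input needs labels")
  say("load", nrow(m$counts), " cells x ", ncol(m$counts), " genes, ",
      length(m$class_names), " classes")

  if (!is.null(cfg$qc)) {
    m <- apply_qc(m, cfg$qc)
    rem <- attr(m, "qc_removed")
    say("qc", nrow(m$counts), " cells kept (removed: ",
        paste(names(rem), rem, sep = "=", collapse = ", "), ")")
    if (nrow(m$counts) == 0)
      stop("stage qc: all cells removed; relax the thresholds or ",
           "disable QC")
  }
  if (cfg$normalize) m <- normalize_cpm(m)

  sp <- split_cells(m, test_fraction = cfg$test_fraction,
                    stratified = cfg$stratified, seed = cfg$seed + 1L)
  say("split", nrow(sp$train$counts), " train / ",
      nrow(sp$test$counts), " test cells")

  specs <- lapply(cfg$classifiers, function(cl)
    if (inherits(cl, "classifier_spec")) cl else
      classifier_spec(cl, seed = cfg$seed + 2L))
  sweep <- sweep_ifs(sp$train, scorers = cfg$scorers, specs = specs,
                     schedule = cfg$schedule, folds = cfg$folds,
                     patience = cfg$patience)
  for (method in names(sweep$rankings)) {
    f <- out(paste0("ranking_", method, ".tsv"))
    write_ranking(sweep$rankings[[method]], f)
    files <- c(files, f)
  }
  for (r in sweep$results) {
    f <- out(paste0("ifs_", r$method_pair[["scorer"]], "_",
                    r$method_pair[["algorithm"]], ".tsv"))
    write_ifs_curve(r, f)
    files <- c(files, f)
  }
  utils::write.table(sweep$summary, out("ifs_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, out("ifs_summary.tsv"))
  best <- sweep$results[[sweep$best]]
  say("sweep", nrow(sweep$summary), " combinations; best = ",
      best$method_pair[["scorer"]], " + ", best$method_pair[["algorithm"]],
      " (", best$optimal_size, " genes)")

  spec <- specs[[match(best$method_pair[["algorithm"]],
                       vapply(specs, `[[`, character(1), "algorithm"))]]
  X_train <- feature_matrix(sp$train, best$optimal_gene_ids)
  model <- train_classifier(spec, X_train, sp$train$labels,
                            folds = cfg$folds)
  save_model(model, out("model.rds"))
  files <- c(files, out("model.rds"))
  say("train", "refit on ", nrow(X_train), " cells x ", ncol(X_train),
      " genes; CV accuracy ", sprintf("%.4f", model$cv_accuracy))

  X_test <- feature_matrix(sp$test, best$optimal_gene_ids)
  proba <- predict_proba(model, X_test)
  pred <- colnames(proba)[max.col(proba, ties.method = "first")]
  report <- evaluate_predictions(sp$test$labels, pred, proba)
  files <- c(files, write_report(report, out("evaluation")))
  say("evaluate", "held-out accuracy ", sprintf("%.4f", report$accuracy),
      ", macro F1 ", sprintf("%.4f", report$f1))

  manifest <- list(
    package_version = as.character(utils::packageVersion("scIFS")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = serializable_config(cfg),
    input = if (is.character(cfg$input)) cfg$input else "<in-memory>",
    n_cells_after_qc = nrow(m$counts),
    winner = list(scorer = unname(best$method_pair[["scorer"]]),
                  algorithm = unname(best$method_pair[["algorithm"]]),
                  optimal_size = best$optimal_size,
                  cv_accuracy = best$optimal_accuracy),
    test_metrics = list(accuracy = report$accuracy,
                        precision = report$precision,
                        recall = report$recall, f1 = report$f1,
                        macro_auc = report$macro_auc),
    outputs = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(manifest)
}

# Plain-list view of a pipeline_config for the JSON manifest.
serializable_config <- function(cfg) {
  out <- unclass(cfg)
  out$input <- NULL
  if (!is.null(out$qc)) out$qc <- unclass(out$qc)
  out$classifiers <- lapply(out$classifiers, function(cl)
    if (inherits(cl, "classifier_spec")) unclass(cl) else cl)
  out
}

#' Save a trained model archive
#'
#' The archive carries the fitted state, the ordered feature gene list,
#' the chosen hyperparameters and a package-version stamp.
#'
#' @param model A `trained_model`.
#' @param file Output path (`.rds`).
#' @return `file`, invisibly.
#' @export
save_model <- function(model, file) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(list(model = model,
               version = as.character(utils::packageVersion("scIFS"))),
          file)
  invisible(file)
}

#' Load a trained model archive
#' @param file Path written by [save_model].
#' @return The `trained_model`.
#' @export
load_model <- function(file) {
  arc <- readRDS(file)
  if (!is.list(arc) || !inherits(arc$model, "trained_model"))
    stop("not a model archive: ", file)
  arc$model
}

#' Predict cell states for a new matrix
#'
#' Subsets and reorders the matrix's genes to the model's feature list
#' (column order never matters), then emits per-cell labels and class
#' probabilities. Feature genes missing from the matrix are an error
#' naming them, unless `impute_missing_as_zero` is set, in which case
#' they are filled with zeros.
#'
#' @param model A `trained_model` or archive path.
#' @param m An [sc_matrix] or path readable by [read_matrix].
#' @param impute_missing_as_zero Fill absent feature genes with zeros.
#' @param out Optional TSV path (barcode, predicted_label, one
#'   probability column per class).
#' @return Data frame of predictions, invisibly when `out` is given.
#' @export
predict_cells <- function(model, m, impute_missing_as_zero = FALSE,
                          out = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(m)) m <- read_matrix(m)
  stopifnot(inherits(model, "trained_model"), inherits(m, "sc_matrix"))
  want <- model$feature_gene_ids
  missing <- setdiff(want, m$gene_ids)
  if (length(missing) && !impute_missing_as_zero)
    stop("matrix is missing ", length(missing), " feature gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...",
         "; pass impute_missing_as_zero = TRUE to zero-fill")
  X <- matrix(0, nrow(m$counts), length(want),
              dimnames = list(m$cell_ids, want))
  present <- intersect(want, m$gene_ids)
  X[, present] <- as.matrix(m$counts[, present, drop = FALSE])
  proba <- predict_proba(model, X)
  res <- data.frame(barcode = m$cell_ids,
                    predicted_label =
                      colnames(proba)[max.col(proba, ties.method = "first")],
                    proba, check.names = FALSE)
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(res))
  }
  res
}
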