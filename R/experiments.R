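#' Run one classification experiment end to end
#'
#' Orchestrates the two study tasks on a corpus: call-type classification
#' (LF vs HF) or individual-cow identification on the full corpus or on one
#' call-type subset. The explainable model runs on the 23 extracted vocal
#' parameters through the stratified k-fold harness (optionally with the
#' leave-one-feature-out importance profile); the deep model runs on pooled
#' spectrograms through the same protocol.
#'
#' @param recordings List of [call_recording()]s (from [load_manifest()] or
#'   [synthesize_corpus()]).
#' @param task `"callclass"` or `"identification"`.
#' @param subset For identification: `"ALL"`, `"LF"` or `"HF"` (ignored for
#'   call-type classification).
#' @param model `"explainable"` or `"deep"`.
#' @param k Folds for the evaluation.
#' @param r Bagged instances per ensemble (explainable model).
#' @param control [ensemble_control()] for the explainable model.
#' @param dl_config [grunet_config()] for the deep model (its `input_grid`
#'   sets the spectrogram pooling).
#' @param importance Also compute the leave-one-feature-out profile
#'   (explainable model only).
#' @param features Optional precomputed feature table (skips extraction).
#' @param seed Integer seed.
#' @param out_dir Optional directory to write results (JSON + CSV).
#' @return List of class `bovine_experiment`: `result` (an
#'   [experiment_result()]), `importance` (or NULL), `n_calls`, `dropped`
#'   (cows excluded for having fewer than `k` calls in the subset), `spec`.
#' @export
run_experiment <- function(recordings, task = c("callclass", "identification"),
                           subset = c("ALL", "LF", "HF"),
                           model = c("explainable", "deep"),
                           k = 5, r = 50, control = ensemble_control(),
                           dl_config = grunet_config(), importance = FALSE,
                           features = NULL, seed = 1, out_dir = NULL) {
  task <- match.arg(task)
  subset <- match.arg(subset)
  model <- match.arg(model)
  meta <- data.frame(
    call_id = vapply(recordings, `[[`, "", "call_id"),
    cow_id = vapply(recordings, `[[`, "", "cow_id"),
    call_type = vapply(recordings, `[[`, "", "call_type"),
    stringsAsFactors = FALSE
  )
  keep <- rep(TRUE, nrow(meta))
  if (task == "identification" && subset != "ALL") {
    keep <- meta$call_type == subset
  }
  target <- if (task == "callclass") "call_type" else "cow_id"
  # drop classes that cannot be stratified into k folds
  dropped <- character(0)
  counts <- table(meta[[target]][keep])
  small <- names(counts)[counts < k]
  if (length(small) > 0) {
    if (task == "callclass") {
      stop("call type(s) with fewer than k calls: ",
           paste(small, collapse = ", "))
    }
    dropped <- small
    keep <- keep & !(meta[[target]] %in% small)
  }
  recs <- recordings[keep]
  message(sprintf("experiment %s/%s/%s: %d of %d calls%s", task, subset, model,
                  length(recs), length(recordings),
                  if (length(dropped)) paste0("; dropped cows: ",
                                              paste(dropped, collapse = ", "))
                  else ""))

  imp <- NULL
  if (model == "explainable") {
    ft <- if (is.null(features)) extract_feature_table(recs) else
      features[features$call_id %in% meta$call_id[keep], , drop = FALSE]
    tbl <- feature_table(ft, target)
    result <- evaluate_stratified_kfold(tbl, k = k, r = r, control = control,
                                        seed = seed)
    result$task <- paste0(task, if (task == "identification")
      paste0("/", subset) else "")
    if (importance) {
      imp <- leave_one_feature_out_importance(tbl, k = k, r = r,
                                              control = control, seed = seed)
    }
  } else {
    xs <- prepare_spectrogram_batch(recs, grid = dl_config$input_grid)
    y <- factor(vapply(recs, `[[`, "", target))
    result <- evaluate_grunet(xs, y, k = k, config = dl_config, seed = seed)
    result$task <- paste0(task, if (task == "identification")
      paste0("/", subset) else "")
  }

  out <- structure(list(result = result, importance = imp,
                        n_calls = length(recs), dropped = dropped,
                        spec = list(task = task, subset = subset,
                                    model = model, k = k, r = r, seed = seed)),
                   class = "bovine_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.bovine_experiment <- function(x, ...) {
  print(x$result)
  if (!is.null(x$importance)) {
    cat("top features:\n")
    print(utils::head(x$importance$profile[, c("feature", "importance_pct")], 5))
  }
  invisible(x)
}

#' Tabulate experiment results in the standard layout
#'
#' One row per experiment: dataset, model, train and test accuracy as
#' `mean +/- sd` percentages.
#'
#' @param ... [run_experiment()] results (or `experiment_result`s).
#' @return data.frame with columns `dataset`, `model`, `train_acc_mean`,
#'   `train_acc_sd`, `test_acc_mean`, `test_acc_sd` (percent).
#' @export
report_results <- function(...) {
  results <- lapply(list(...), function(x) {
    if (inherits(x, "bovine_experiment")) x$result else x
  })
  do.call(rbind, lapply(results, function(r) {
    data.frame(dataset = r$task, model = r$model,
               train_acc_mean = round(100 * r$train_mean, 1),
               train_acc_sd = round(100 * r$train_sd, 1),
               test_acc_mean = round(100 * r$test_mean, 1),
               test_acc_sd = round(100 * r$test_sd, 1),
               stringsAsFactors = FALSE)
  }))
}

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- with(exp$spec, paste(task, subset, model, sep = "_"))
  utils::write.csv(report_results(exp), file.path(out_dir, paste0(stem, "_result.csv")),
                   row.names = FALSE)
  payload <- list(spec = exp$spec, n_calls = exp$n_calls,
                  dropped = exp$dropped,
                  folds = exp$result$folds,
                  train_mean = exp$result$train_mean,
                  train_sd = exp$result$train_sd,
                  test_mean = exp$result$test_mean,
                  test_sd = exp$result$test_sd)
  jsonlite::write_json(payload, file.path(out_dir, paste0(stem, "_result.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(exp$importance)) {
    utils::write.csv(exp$importance$profile[, c("feature", "importance_pct")],
                     file.path(out_dir, paste0(stem, "_importance.csv")),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
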