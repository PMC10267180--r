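# Plant-wise data splitting, accuracy computation, leave-one-out
# cross-validation and the inference-timing report. Splitting is always by
# plant: windows of one plant never appear on both sides of a split.

#' Split a cohort by plant
#'
#' @param cohort named list of [recording()]s (or a character vector of ids).
#' @param test_ids plant ids forming the test side.
#' @return An object of class `split_plan` with disjoint `train_plants` and
#'   `test_plants` covering the cohort.
#' @export
split_by_plant <- function(cohort, test_ids) {
  ids <- if (is.character(cohort)) cohort else names(cohort)
  if (is.null(ids) || !length(ids)) split_error("cohort has no plant ids")
  test_ids <- as.character(test_ids)
  unknown <- setdiff(test_ids, ids)
  if (length(unknown))
    split_error(paste("unknown plant id(s):", paste(unknown, collapse = ", ")))
  if (!length(test_ids)) split_error("test set must be non-empty")
  train_ids <- setdiff(ids, test_ids)
  if (!length(train_ids)) split_error("train set must be non-empty")
  structure(list(train_plants = train_ids, test_plants = test_ids),
            class = "split_plan")
}

#' Window-level accuracy of a confidence trace
#'
#' Fraction of windows where `confidence >= threshold` matches the label
#' (ties go to the stressed class). Windows labelled `-1` are excluded.
#'
#' @param trace a [prediction_trace()].
#' @param labels integer labels in `{-1, 0, 1}` aligned with the trace.
#' @param threshold decision threshold in (0, 1).
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(trace, labels, threshold = 0.5) {
  conf <- if (inherits(trace, "prediction_trace")) trace$confidences
          else as.numeric(trace)
  if (length(labels) != length(conf))
    shape_error("labels must align with the trace")
  if (threshold <= 0 || threshold >= 1)
    config_error("`threshold` must lie in (0, 1)")
  keep <- labels %in% c(0L, 1L)
  if (!any(keep)) label_error("all labels are -1; accuracy undefined")
  mean(as.integer(conf[keep] >= threshold) == labels[keep])
}

#' Assemble an evaluation report
#'
#' @param per_plant_accuracy named numeric vector of per-plant accuracies.
#' @param training_accuracy accuracy on the training windows (dropout off).
#' @return An object of class `evaluation_report` with the average and
#'   standard deviation across plants.
#' @export
evaluation_report <- function(per_plant_accuracy, training_accuracy = NA_real_) {
  acc <- unlist(per_plant_accuracy)
  if (any(acc < 0 | acc > 1, na.rm = TRUE))
    shape_error("accuracies must lie in [0, 1]")
  structure(list(per_plant_accuracy = acc,
                 average_accuracy = mean(acc),
                 std_dev = stats::sd(acc),
                 training_accuracy = training_accuracy),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (p in names(x$per_plant_accuracy))
    cat(sprintf("  %-4s %6.2f%%\n", p, 100 * x$per_plant_accuracy[[p]]))
  cat(sprintf("  average %.2f%% (sd %.2f%%), training %.2f%%\n",
              100 * x$average_accuracy,
              100 * (x$std_dev %||% NA_real_),
              100 * x$training_accuracy))
  invisible(x)
}

# Preprocess one recording according to an experiment_config: optional notch,
# simplification (or raw windowing), labelling. Normalization happens later,
# split-aware.
preprocess_recording <- function(rec, config) {
  samples <- rec$samples
  if (length(config$notch_freqs))
    samples <- notch_filter(samples, rec$fs, config$notch_freqs)
  frec <- recording(rec$plant_id, rec$fs, samples, rec$stimulus_time,
                    rec$symptom_time, rec$t0)
  ws <- if (isTRUE(config$use_simplification))
    simplify(frec, S = config$simplify$S, N = config$simplify$N,
             F = config$simplify$F)
  else
    make_windows(frec, config$window_length_s,
                 config$extra_downsample %||% 1)
  label_windows(ws, frec, config$protocol)
}

# Train on the labelled windows of the training plants and evaluate on each
# test plant's labelled windows. Returns the report and (optionally) raw
# full-trace predictions per test plant.
fit_and_evaluate <- function(cohort, plan, config, seed,
                             return_traces = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  if (length(intersect(plan$train_plants, plan$test_plants)))
    split_error("train/test plant sets overlap")
  wsets <- lapply(cohort[c(plan$train_plants, plan$test_plants)],
                  preprocess_recording, config = config)
  all_ws <- bind_windows(wsets)
  norm_method <- config$normalization
  extrema <- if (norm_method == "per_plant_minmax")
    plant_extrema(all_ws) else NULL
  all_ws <- normalize(all_ws, norm_method, per_plant_extrema = extrema)

  train_idx <- all_ws$plant_ids %in% plan$train_plants &
    all_ws$labels %in% c(0L, 1L)
  train_ws <- subset_windows(all_ws, train_idx)
  spec_args <- list(kind = config$architecture,
                    input_length = ncol(all_ws$windows))
  for (nm in c("encoder", "mlp", "fcn", "resnet"))
    if (!is.null(config$arch_params[[nm]]))
      spec_args[[nm]] <- config$arch_params[[nm]]
  spec <- do.call(architecture_spec, spec_args)
  model <- build_model(spec, seed = seed)
  model <- train(model, train_ws, budget = config$train_budget, seed = seed)

  train_trace <- predict_confidences(model, train_ws)
  training_accuracy <- accuracy(train_trace, train_ws$labels,
                                config$decision_threshold)

  per_plant <- list(); traces <- list()
  for (p in plan$test_plants) {
    idx <- all_ws$plant_ids == p
    pws <- subset_windows(all_ws, idx)
    trace <- predict_confidences(model, pws)
    per_plant[[p]] <- accuracy(trace, pws$labels, config$decision_threshold)
    if (return_traces)
      traces[[p]] <- list(trace = trace, labels = pws$labels)
  }
  out <- list(report = evaluation_report(per_plant, training_accuracy),
              model = model)
  if (return_traces) out$traces <- traces
  out
}

#' Plant-wise leave-one-out cross-validation
#'
#' One fold per plant: the model trains on all other plants and is evaluated
#' on the held-out one. Per-fold seeds derive deterministically from the
#' master seed and the plant id, so adding a plant does not reshuffle other
#' folds.
#'
#' @param cohort named list of [recording()]s (>= 2 plants).
#' @param config an [experiment_config()].
#' @param return_traces keep per-fold test traces (for fusion analyses).
#' @return List with `folds` (per-plant `evaluation_report`s, and traces if
#'   requested) and `summary` (mean and sd of the held-out accuracies).
#' @export
loocv <- function(cohort, config, return_traces = FALSE) {
  ids <- names(cohort)
  if (length(ids) < 2) split_error("LOOCV needs at least 2 plants")
  folds <- list()
  for (p in ids) {
    plan <- split_by_plant(cohort, p)
    fit <- fit_and_evaluate(cohort, plan, config,
                            seed = derive_seed(config$seed, p),
                            return_traces = return_traces)
    folds[[p]] <- list(report = fit$report,
                       test_plant = p,
                       seed = derive_seed(config$seed, p))
    if (return_traces) folds[[p]]$traces <- fit$traces
  }
  test_acc <- vapply(folds, function(f) f$report$average_accuracy, numeric(1))
  train_acc <- vapply(folds, function(f) f$report$training_accuracy,
                      numeric(1))
  list(folds = folds,
       summary = list(mean_test_accuracy = mean(test_acc),
                      sd_test_accuracy = stats::sd(test_acc),
                      mean_training_accuracy = mean(train_acc),
                      per_plant = test_acc))
}

#' Inference-timing report
#'
#' Median wall-clock time per window at each batch size, over `reps`
#' repetitions after a warm-up pass. Report-only: wall-clock numbers are
#' hardware-dependent and never asserted in tests.
#'
#' @param classifier a trained `stress_classifier`.
#' @param windows a [window_set()].
#' @param batch_sizes batch sizes to measure (study protocol: 1 and 64).
#' @param reps repetitions per batch size (>= 30 for the report).
#' @return Data frame with one row per batch size: median seconds per window
#'   and the repetition count.
#' @export
inference_timing <- function(classifier, windows, batch_sizes = c(1, 64),
                             reps = 30) {
  rows <- lapply(batch_sizes, function(bs) {
    n_win <- min(nrow(windows$windows), bs)
    wsub <- subset_windows(windows, seq_len(n_win))
    predict_confidences(classifier, wsub, batch_size = bs)  # warm-up
    times <- vapply(seq_len(reps), function(i) {
      t0 <- proc.time()[["elapsed"]]
      predict_confidences(classifier, wsub, batch_size = bs)
      (proc.time()[["elapsed"]] - t0) / n_win
    }, numeric(1))
    data.frame(batch_size = bs, median_s_per_window = stats::median(times),
               reps = reps)
  })
  do.call(rbind, rows)
}
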