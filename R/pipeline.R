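# End-to-end orchestration: simulate -> preprocess -> train -> predict ->
# fuse -> evaluate -> detect-onset, with a manifest that makes the run
# reproducible. Any stage error aborts with the stage name; the manifest of
# completed stages is still written.

#' Run the full stress-detection pipeline
#'
#' @param config an [experiment_config()] or a path to a YAML config.
#' @param input_path optional HDF5 cohort to analyse; when `NULL` a cohort is
#'   simulated from `config$cohort`.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed` (mirrors `--seed`).
#' @param write_cohort_h5 also write the simulated cohort to HDF5 (skipped by
#'   default to keep scaled runs light).
#' @return Invisibly, a list with the evaluation report, fused traces, onset
#'   results and the manifest.
#' @export
run_pipeline <- function(config, input_path = NULL, out_dir = tempfile("run"),
                         seed = NULL, write_cohort_h5 = FALSE) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "experiment_config"))
    config_error("`config` must be an experiment_config or a YAML path")
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(config = unclass(config), seed = config$seed,
                   input_path = input_path, out_dir = out_dir,
                   stages = list())
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, file.path(out_dir, "manifest.json"))
      ps_abort(sprintf("pipeline stage `%s` failed: %s", name,
                       conditionMessage(e)), "phytostress_stage_error")
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  cohort <- stage("simulate", function() {
    if (!is.null(input_path)) {
      if (!file.exists(input_path))
        config_error(paste("input cohort not found:", input_path))
      read_cohort(input_path)
    } else {
      cc <- do.call(cohort_config,
                    merge_config_lists(list(seed = config$seed),
                                       config$cohort))
      cohort <- generate_cohort(cc)
      if (write_cohort_h5)
        write_cohort(cohort, file.path(out_dir, "cohort.h5"))
      cohort
    }
  })

  plan <- stage("split", function() {
    test_ids <- intersect(config$protocol$test_plants, names(cohort))
    if (!length(test_ids))
      config_error("none of protocol.test_plants are present in the cohort")
    split_by_plant(cohort, test_ids)
  })

  # preprocess + train + predict (full traces on test plants)
  fit <- stage("train_predict", function()
    fit_and_evaluate(cohort, plan, config, seed = config$seed,
                     return_traces = TRUE))

  fused <- stage("fuse", function()
    lapply(fit$traces, function(tr)
      combine_predictions(tr$trace, config$fusion$L, config$fusion$method)))

  evaluation <- stage("evaluate", function() {
    fused_acc <- vapply(names(fused), function(p)
      accuracy(fused[[p]], fit$traces[[p]]$labels,
               config$decision_threshold), numeric(1))
    list(report = fit$report, fused_accuracy = fused_acc)
  })

  onsets <- stage("detect_onset", function()
    lapply(names(fused), function(p)
      detect_stress_onset(fused[[p]], config$onset_threshold,
                          search_from = cohort[[p]]$stimulus_time)) |>
      stats::setNames(names(fused)))

  # artifacts
  rep <- evaluation$report
  utils::write.csv(data.frame(
    plant_id = names(rep$per_plant_accuracy),
    raw_accuracy = as.numeric(rep$per_plant_accuracy),
    fused_accuracy = as.numeric(evaluation$fused_accuracy[
      names(rep$per_plant_accuracy)])),
    file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  for (p in names(fused))
    write_trace(fused[[p]], file.path(out_dir, paste0("trace_", p, ".csv")))
  jsonlite::write_json(
    lapply(onsets, function(o)
      list(onset_time_s = if (is.na(o$onset_time)) NULL else o$onset_time,
           threshold = o$threshold)),
    file.path(out_dir, "onsets.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  write_manifest(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(report = rep, fused_accuracy = evaluation$fused_accuracy,
                 traces = fit$traces, fused = fused, onsets = onsets,
                 manifest = manifest, out_dir = out_dir))
}
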