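# Experiment configuration: the full parameter ledger of a run. Defaults are
# the published operating point: notch at 50/100 Hz, 16-s windows, rolling
# median of 50 samples, decimation by 10, per-window min-max normalization,
# the encoder architecture, mean fusion, decision threshold 0.5, onset
# threshold 0.65, 48 h of training data per state, test plants B0/B5/C5.

#' Construct an experiment configuration
#'
#' @param notch_freqs powerline frequencies to notch out, Hz (empty vector
#'   disables filtering, e.g. for low-rate synthetic runs).
#' @param window_length_s raw-window length in seconds (used when
#'   `use_simplification = FALSE`).
#' @param extra_downsample decimation for raw windows (the 30 s / factor-3
#'   variant).
#' @param use_simplification use the simplification transform (S, N, F)
#'   instead of raw windows.
#' @param simplify list with `S` (seconds), `N` (samples), `F` (factor).
#' @param normalization one of `"none"`, `"per_plant_minmax"`,
#'   `"per_window_minmax"`, `"per_window_demean"`.
#' @param architecture one of `"mlp"`, `"fcn"`, `"resnet"`, `"encoder"`.
#' @param arch_params optional per-architecture overrides passed to
#'   [architecture_spec()] (e.g. smaller filter counts for scaled runs).
#' @param train_budget list with `epochs` and optionally `lr`, `batch_size`.
#' @param fusion list with `L` (>= 1) and `method` (`"mean"`/`"median"`).
#' @param decision_threshold window-classification threshold in (0, 1).
#' @param onset_threshold onset-detection threshold in (0.5, 1).
#' @param protocol list with `train_hours_per_state` (48 or 108 in the
#'   study; any positive value for scaled runs), `scheme` (`"symptom"` or
#'   `"extended"`) and `test_plants`.
#' @param cohort optional list of [cohort_config()] arguments for the
#'   simulate stage of the pipeline.
#' @param seed master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(notch_freqs = c(50, 100),
                              window_length_s = 16,
                              extra_downsample = 1,
                              use_simplification = TRUE,
                              simplify = list(S = 16, N = 50, F = 10),
                              normalization = "per_window_minmax",
                              architecture = "encoder",
                              arch_params = NULL,
                              train_budget = list(epochs = 3, lr = 1e-3,
                                                  batch_size = 64),
                              fusion = list(L = 10, method = "mean"),
                              decision_threshold = 0.5,
                              onset_threshold = 0.65,
                              protocol = list(train_hours_per_state = 48,
                                              scheme = "symptom",
                                              test_plants = c("B0", "B5", "C5")),
                              cohort = list(),
                              seed = 42) {
  cfg <- structure(as.list(environment()), class = "experiment_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) config_error(sprintf("config field `%s`: %s", field, why))
  chk(all(cfg$notch_freqs > 0), "notch_freqs", "must be positive")
  chk(cfg$window_length_s > 0, "window_length_s", "must be > 0")
  chk(cfg$simplify$S > 0, "simplify.S", "must be > 0")
  chk(cfg$simplify$N >= 1, "simplify.N", "must be >= 1")
  chk(cfg$simplify$F >= 1, "simplify.F", "must be >= 1")
  chk(cfg$normalization %in% c("none", "per_plant_minmax",
                               "per_window_minmax", "per_window_demean"),
      "normalization", "unknown method")
  chk(cfg$architecture %in% c("mlp", "fcn", "resnet", "encoder"),
      "architecture", "unknown architecture")
  chk(cfg$fusion$L >= 1, "fusion.L", "must be >= 1")
  chk(cfg$fusion$method %in% c("mean", "median"), "fusion.method",
      "must be mean or median")
  chk(cfg$decision_threshold > 0 && cfg$decision_threshold < 1,
      "decision_threshold", "must lie in (0, 1)")
  chk(cfg$onset_threshold > 0.5 && cfg$onset_threshold < 1,
      "onset_threshold", "must lie in (0.5, 1)")
  chk(cfg$protocol$train_hours_per_state > 0, "protocol.train_hours_per_state",
      "must be > 0")
  invisible(cfg)
}

# Recursive default-merge (nested lists): values in `user` override `base`.
merge_config_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config_lists(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load an experiment configuration from YAML
#'
#' Unspecified fields take the package defaults; invariants are validated
#' with errors naming the offending field. An empty file yields the full
#' default configuration.
#'
#' @param path path to a YAML file.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) config_error(paste("config file not found:", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- experiment_config()
  cfg <- merge_config_lists(unclass(defaults), user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    config_error(paste("unknown config field(s):",
                       paste(extra, collapse = ", ")))
  cfg <- structure(cfg, class = "experiment_config")
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#' @param cfg an [experiment_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
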