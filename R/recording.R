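# The Recording container: one plant's univariate voltage trace plus the
# experiment metadata every downstream stage needs. All timestamps are seconds
# since recording start (t0 = 0); calendar dates are not modelled.

#' Construct a recording
#'
#' A `recording` holds one plant's univariate electrophysiological time
#' series together with its sampling rate and the two experiment timestamps:
#' when the stressor (nitrogen cut) was applied and when visual symptoms
#' appeared.
#'
#' @param plant_id character scalar, unique within a cohort (e.g. `"B0"`).
#' @param fs sampling rate in Hz.
#' @param samples numeric vector of voltage samples (arbitrary units).
#' @param stimulus_time seconds since start when the stressor was applied.
#' @param symptom_time seconds since start when visual symptoms appeared.
#' @param t0 start time in seconds (always 0 in this package; kept explicit
#'   so the invariant `t0 <= stimulus_time <= symptom_time <= end` is checked
#'   where it is stated).
#' @return An object of class `recording`.
#' @export
recording <- function(plant_id, fs, samples, stimulus_time, symptom_time,
                      t0 = 0) {
  if (!is.character(plant_id) || length(plant_id) != 1L || !nzchar(plant_id))
    config_error("`plant_id` must be a non-empty character scalar")
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (!is.numeric(samples)) config_error("`samples` must be numeric")
  stopifnot_scalar_num(stimulus_time, "stimulus_time")
  stopifnot_scalar_num(symptom_time, "symptom_time")
  end_time <- t0 + length(samples) / fs
  if (!(t0 <= stimulus_time && stimulus_time <= symptom_time &&
        symptom_time <= end_time))
    config_error("need t0 <= stimulus_time <= symptom_time <= end of recording")
  structure(
    list(plant_id = plant_id, fs = fs, t0 = t0,
         samples = as.numeric(samples),
         stimulus_time = stimulus_time, symptom_time = symptom_time),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> plant %s: %d samples @ %g Hz (%s), stimulus at %s, symptoms at %s\n",
    x$plant_id, length(x$samples), x$fs,
    format_duration(length(x$samples) / x$fs),
    format_duration(x$stimulus_time), format_duration(x$symptom_time)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording`.
#' @return Numeric scalar, seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs
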