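# Plant profiles and cohort configuration for the synthetic generator.
#
# The real recordings are proprietary; the generator emulates their documented
# statistical structure: per-plant value ranges that differ by orders of
# magnitude, a slow baseline drift, a state-dependent oscillation/burst
# "texture" visible at a few-seconds scale, optional 50 Hz powerline
# contamination, white measurement noise, and a gradual normal->stressed
# transition between the stimulus and the visual-symptom time.

#' Describe one state's signal texture
#'
#' The texture is the seconds-scale component that discriminates the normal
#' and stressed states: a narrow-band oscillation plus sporadic oscillatory
#' bursts.
#'
#' @param freq_hz centre frequency of the oscillation band, Hz.
#' @param amp oscillation amplitude (arbitrary units, pre `amplitude_scale`).
#' @param burst_rate_per_min expected burst events per minute (Poisson).
#' @param burst_amp amplitude of each burst envelope; default `2 * amp`.
#' @param burst_width_s Gaussian envelope width (sd) of a burst, seconds.
#' @return A list of class `texture_spec`.
#' @export
texture_spec <- function(freq_hz, amp, burst_rate_per_min = 0,
                         burst_amp = 2 * amp, burst_width_s = 1) {
  stopifnot_scalar_num(freq_hz, "freq_hz", positive = TRUE)
  stopifnot_scalar_num(amp, "amp", nonneg = TRUE)
  stopifnot_scalar_num(burst_rate_per_min, "burst_rate_per_min", nonneg = TRUE)
  structure(list(freq_hz = freq_hz, amp = amp,
                 burst_rate_per_min = burst_rate_per_min,
                 burst_amp = burst_amp, burst_width_s = burst_width_s),
            class = "texture_spec")
}

#' Construct a plant profile
#'
#' @param plant_id character id, unique within a cohort.
#' @param amplitude_scale global per-plant range factor (> 0). Real cohorts
#'   show per-plant value ranges differing by orders of magnitude, which is
#'   what makes normalization matter.
#' @param drift_spec list with `corner_hz` (corner frequency of the slow
#'   baseline process) and `amp` (its stationary standard deviation).
#' @param texture_normal,texture_stressed [texture_spec()] for each state.
#' @param powerline_amp amplitude of the additive 50 Hz contaminant (>= 0).
#' @param noise_sd white-noise standard deviation (>= 0).
#' @param responsiveness in `[0, 1]`: how strongly this plant expresses the
#'   stressed texture once symptoms are developed. Low values model the
#'   resilient plants that defeat classification in real cohorts.
#' @return An object of class `plant_profile`.
#' @export
plant_profile <- function(plant_id,
                          amplitude_scale = 1,
                          drift_spec = list(corner_hz = 5e-4, amp = 1),
                          texture_normal = texture_spec(0.035, 0.3,
                                                        burst_rate_per_min = 0.2),
                          texture_stressed = texture_spec(0.35, 1,
                                                          burst_rate_per_min = 2),
                          powerline_amp = 0,
                          noise_sd = 0.1,
                          responsiveness = 1) {
  if (!is.character(plant_id) || length(plant_id) != 1L)
    config_error("`plant_id` must be a character scalar")
  stopifnot_scalar_num(amplitude_scale, "amplitude_scale", positive = TRUE)
  stopifnot_scalar_num(powerline_amp, "powerline_amp", nonneg = TRUE)
  stopifnot_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar_num(responsiveness, "responsiveness")
  if (responsiveness < 0 || responsiveness > 1)
    config_error("`responsiveness` must lie in [0, 1]")
  stopifnot_scalar_num(drift_spec$corner_hz, "drift_spec$corner_hz",
                       positive = TRUE)
  stopifnot_scalar_num(drift_spec$amp, "drift_spec$amp", nonneg = TRUE)
  if (!inherits(texture_normal, "texture_spec") ||
      !inherits(texture_stressed, "texture_spec"))
    config_error("textures must be built with texture_spec()")
  structure(list(plant_id = plant_id, amplitude_scale = amplitude_scale,
                 drift_spec = drift_spec, texture_normal = texture_normal,
                 texture_stressed = texture_stressed,
                 powerline_amp = powerline_amp, noise_sd = noise_sd,
                 responsiveness = responsiveness),
            class = "plant_profile")
}

#' Hyper-distributions from which per-plant profiles are drawn
#'
#' Ranges are uniform unless noted. `amp_scale_range` is sampled log-uniformly
#' so that plant ranges differ by orders of magnitude. A fraction
#' `responsive_fraction` of plants (rounded up) draw their responsiveness from
#' `responsiveness_range` (above the `detectability_floor`); the rest are
#' "resilient" and draw from `resilient_range`.
#'
#' @param amp_scale_range log-uniform range of per-plant amplitude scales.
#' @param drift_corner_range,drift_amp_range drift process parameter ranges.
#' @param normal_freq_range,normal_amp_range normal-state texture ranges (Hz,
#'   amplitude).
#' @param stressed_freq_range,stressed_amp_range stressed-state texture ranges.
#' @param normal_burst_rate,stressed_burst_rate burst rates, events/min.
#' @param powerline_fraction fraction of plants with 50 Hz contamination.
#' @param powerline_amp_range amplitude range for contaminated plants.
#' @param noise_sd_range white-noise sd range.
#' @param responsive_fraction minimum fraction of detectably responsive plants.
#' @param detectability_floor responsiveness above which a plant is considered
#'   detectable.
#' @param responsiveness_range,resilient_range responsiveness ranges for the
#'   two groups.
#' @return A list of class `cohort_hyper`.
#' @export
cohort_hyper <- function(amp_scale_range = c(0.1, 10),
                         drift_corner_range = c(2e-4, 1e-3),
                         drift_amp_range = c(0.5, 1.5),
                         normal_freq_range = c(0.02, 0.05),
                         normal_amp_range = c(0.2, 0.4),
                         stressed_freq_range = c(0.2, 0.5),
                         stressed_amp_range = c(0.8, 1.2),
                         normal_burst_rate = 0.2,
                         stressed_burst_rate = 2,
                         powerline_fraction = 0.5,
                         powerline_amp_range = c(0.02, 0.1),
                         noise_sd_range = c(0.05, 0.15),
                         responsive_fraction = 0.8,
                         detectability_floor = 0.5,
                         responsiveness_range = c(0.7, 1),
                         resilient_range = c(0.05, 0.4)) {
  structure(as.list(environment()), class = "cohort_hyper")
}

#' Construct a cohort configuration
#'
#' Defaults are the experiment this package emulates: 16 plants recorded at
#' 500 Hz for 15 days, nitrogen cut after 6 days, visual symptoms 5 days
#' later.
#'
#' @param n_plants number of plants (>= 1; cohort generation needs >= 2).
#' @param fs sampling rate, Hz.
#' @param duration_days recording length per plant, days.
#' @param stimulus_day day (from start) on which the stressor is applied.
#' @param symptom_lag_days days between stimulus and visual symptoms.
#' @param seed master seed for profile sampling and per-plant signal seeds.
#' @param hyper profile hyper-distributions, see [cohort_hyper()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_plants = 16, fs = 500, duration_days = 15,
                          stimulus_day = 6, symptom_lag_days = 5,
                          seed = 1, hyper = cohort_hyper()) {
  stopifnot_scalar_num(n_plants, "n_plants", positive = TRUE)
  if (n_plants != round(n_plants)) config_error("`n_plants` must be integer")
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  stopifnot_scalar_num(duration_days, "duration_days", positive = TRUE)
  stopifnot_scalar_num(stimulus_day, "stimulus_day")
  stopifnot_scalar_num(symptom_lag_days, "symptom_lag_days")
  if (!(0 < stimulus_day && stimulus_day + symptom_lag_days < duration_days &&
        symptom_lag_days > 0))
    config_error(
      "need 0 < stimulus_day < stimulus_day + symptom_lag_days < duration_days")
  stopifnot_scalar_num(seed, "seed")
  if (!inherits(hyper, "cohort_hyper"))
    hyper <- do.call(cohort_hyper, hyper)   # partial lists take defaults
  structure(list(n_plants = as.integer(n_plants), fs = fs,
                 duration_days = duration_days, stimulus_day = stimulus_day,
                 symptom_lag_days = symptom_lag_days, seed = seed,
                 hyper = hyper),
            class = "cohort_config")
}

# Plant ids follow the device/channel convention: 8 channels per device,
# devices lettered from B ("B0".."B7", "C0".."C7", ...).
make_plant_ids <- function(n) {
  idx <- seq_len(n) - 1L
  paste0(LETTERS[2L + idx %/% 8L], idx %% 8L)
}
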