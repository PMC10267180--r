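# Synthetic signal generation.
#
# Each recording is amplitude_scale * (drift + texture + powerline + noise):
#   * drift    — AR(1) process with corner frequency `corner_hz`, i.e.
#                low-pass-filtered Gaussian noise, stationary sd = amp;
#   * texture  — per-state narrow-band oscillation (random-walk phase, so it
#                decorrelates slowly) plus Poisson-timed oscillatory bursts;
#                the stressed texture is blended in with a weight that ramps
#                linearly from 0 at stimulus_time to `responsiveness` at
#                symptom_time and stays constant afterwards;
#   * powerline — 50 Hz sinusoid (amplitude may be 0);
#   * noise    — white Gaussian noise.
# This is an emulation of the qualitative multi-scale appearance of real
# greenhouse recordings, not a biophysical model.

ar1_drift <- function(n, fs, corner_hz, amp) {
  if (amp == 0 || n == 0L) return(numeric(n))
  a <- exp(-2 * pi * corner_hz / fs)
  innov_sd <- amp * sqrt(1 - a^2)
  x0 <- stats::rnorm(1, 0, amp)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), a,
                           method = "recursive", init = x0))
}

# Narrow-band oscillation with a slowly diffusing phase + Poisson bursts.
texture_process <- function(n, fs, spec) {
  out <- numeric(n)
  if (n == 0L) return(out)
  t <- (seq_len(n) - 1) / fs
  if (spec$amp > 0) {
    # phase random walk: ~10% relative frequency jitter
    jitter <- cumsum(stats::rnorm(n, 0, 2 * pi * spec$freq_hz * 0.1 / sqrt(fs)))
    out <- out + spec$amp * sin(2 * pi * spec$freq_hz * t +
                                  stats::runif(1, 0, 2 * pi) + jitter)
  }
  if (spec$burst_rate_per_min > 0 && spec$burst_amp > 0) {
    dur_min <- n / fs / 60
    n_events <- stats::rpois(1, spec$burst_rate_per_min * dur_min)
    if (n_events > 0) {
      centers <- stats::runif(n_events, 0, n / fs)
      f_burst <- spec$freq_hz * 4
      half <- 3 * spec$burst_width_s
      for (c0 in centers) {
        i0 <- max(1L, floor((c0 - half) * fs) + 1L)
        i1 <- min(n, ceiling((c0 + half) * fs))
        if (i0 > i1) next
        tt <- ((i0:i1) - 1) / fs - c0
        out[i0:i1] <- out[i0:i1] + spec$burst_amp *
          exp(-tt^2 / (2 * spec$burst_width_s^2)) *
          sin(2 * pi * f_burst * tt + stats::runif(1, 0, 2 * pi))
      }
    }
  }
  out
}

#' Generate one plant's synthetic recording
#'
#' Deterministic given `seed`. Before `stimulus_time` the texture is drawn
#' from the normal-state process; afterwards the stressed texture is blended
#' in with a weight ramping linearly from 0 (at the stimulus) to the plant's
#' `responsiveness` (at symptom time), constant thereafter.
#'
#' @param profile a [plant_profile()].
#' @param config a [cohort_config()] (supplies fs, duration and the stimulus /
#'   symptom times).
#' @param seed integer seed for this plant's signal.
#' @return A [recording()].
#' @export
generate_plant_recording <- function(profile, config, seed = config$seed) {
  if (!inherits(profile, "plant_profile"))
    config_error("`profile` must be a plant_profile")
  if (!inherits(config, "cohort_config"))
    config_error("`config` must be a cohort_config")
  fs <- config$fs
  n <- round(config$duration_days * 86400 * fs)
  stimulus_time <- config$stimulus_day * 86400
  symptom_time <- (config$stimulus_day + config$symptom_lag_days) * 86400

  samples <- with_seed(seed, {
    drift <- ar1_drift(n, fs, profile$drift_spec$corner_hz,
                       profile$drift_spec$amp)
    tex_n <- texture_process(n, fs, profile$texture_normal)
    tex_s <- texture_process(n, fs, profile$texture_stressed)
    t <- (seq_len(n) - 1) / fs
    w <- pmin(pmax((t - stimulus_time) / (symptom_time - stimulus_time), 0), 1) *
      profile$responsiveness
    tex <- (1 - w) * tex_n + w * tex_s
    power <- if (profile$powerline_amp > 0)
      profile$powerline_amp * sin(2 * pi * 50 * t) else 0
    noise <- if (profile$noise_sd > 0) stats::rnorm(n, 0, profile$noise_sd) else 0
    profile$amplitude_scale * (drift + tex + power + noise)
  })
  recording(profile$plant_id, fs, samples, stimulus_time, symptom_time)
}

# Draw one plant profile from the cohort hyper-distributions. `responsive`
# says which responsiveness range to use.
sample_profile <- function(plant_id, hyper, responsive) {
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  plant_profile(
    plant_id = plant_id,
    amplitude_scale = exp(runif1(log(hyper$amp_scale_range))),
    drift_spec = list(corner_hz = runif1(hyper$drift_corner_range),
                      amp = runif1(hyper$drift_amp_range)),
    texture_normal = texture_spec(runif1(hyper$normal_freq_range),
                                  runif1(hyper$normal_amp_range),
                                  burst_rate_per_min = hyper$normal_burst_rate),
    texture_stressed = texture_spec(runif1(hyper$stressed_freq_range),
                                    runif1(hyper$stressed_amp_range),
                                    burst_rate_per_min = hyper$stressed_burst_rate),
    powerline_amp = if (stats::runif(1) < hyper$powerline_fraction)
      runif1(hyper$powerline_amp_range) else 0,
    noise_sd = runif1(hyper$noise_sd_range),
    responsiveness = if (responsive) runif1(hyper$responsiveness_range)
                     else runif1(hyper$resilient_range)
  )
}

#' Sample the per-plant profiles of a cohort
#'
#' Deterministic given `config$seed`. At least
#' `ceiling(responsive_fraction * n_plants)` plants draw their responsiveness
#' above the detectability floor; which plants are resilient is randomised.
#'
#' @param config a [cohort_config()].
#' @return A named list of [plant_profile()]s.
#' @export
sample_cohort_profiles <- function(config) {
  ids <- make_plant_ids(config$n_plants)
  if (anyDuplicated(ids)) config_error("duplicate plant_id in cohort")
  hyper <- config$hyper
  with_seed(derive_seed(config$seed, "profiles"), {
    n_resp <- min(config$n_plants,
                  ceiling(hyper$responsive_fraction * config$n_plants))
    responsive <- rep(FALSE, config$n_plants)
    responsive[sample.int(config$n_plants, n_resp)] <- TRUE
    profiles <- lapply(seq_along(ids), function(i)
      sample_profile(ids[i], hyper, responsive[i]))
    names(profiles) <- ids
    profiles
  })
}

#' Generate a full synthetic cohort
#'
#' @param config a [cohort_config()] with `n_plants >= 2`.
#' @return A named list of [recording()]s (one per plant).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config_error("`config` must be a cohort_config")
  if (config$n_plants < 2) config_error("a cohort needs n_plants >= 2")
  profiles <- sample_cohort_profiles(config)
  recs <- lapply(profiles, function(p)
    generate_plant_recording(p, config, seed = derive_seed(config$seed,
                                                           p$plant_id)))
  names(recs) <- names(profiles)
  recs
}
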