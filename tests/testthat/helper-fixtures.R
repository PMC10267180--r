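# Shared fixtures. Everything is generated in code; expensive objects are
# cached per test run so several test files can reuse them.
#
# Scale note: the emulated experiment is 16 plants x 15 days x 500 Hz. Tests
# keep the published processing parameters (S = 16 s, N = 50, F = 10, L,
# thresholds, plant-wise protocol structure) but run on shorter, lower-rate
# cohorts so the whole suite fits a single-CPU budget.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A tiny recording with explicit metadata for unit tests.
tiny_recording <- function(n = 100, fs = 10, plant_id = "B0") {
  recording(plant_id, fs, sin(seq_len(n) / 5),
            stimulus_time = n / fs * 0.4, symptom_time = n / fs * 0.7)
}

# Small encoder spec used wherever a trainable model is needed.
small_encoder <- function() list(block_filters = c(8, 8, 8),
                                 kernel_sizes = c(3, 5, 7),
                                 dropout = 0.2, pool = 2)

# The scaled acceptance cohort: 8 plants, all responsive (>= 0.8), 12 h at
# 50 Hz, stimulus after 4 h, symptoms 4 h later.
acceptance_cohort_config <- function(seed = 11)
  cohort_config(n_plants = 8, fs = 50, duration_days = 0.5,
                stimulus_day = 1 / 6, symptom_lag_days = 1 / 6, seed = seed,
                hyper = cohort_hyper(responsive_fraction = 1,
                                     responsiveness_range = c(0.8, 1),
                                     powerline_fraction = 0))

acceptance_cohort <- function() cached("acc_cohort",
                                       generate_cohort(acceptance_cohort_config()))

# Scaled pipeline configuration for the acceptance runs: published S/N/F,
# per-window min-max, encoder; epochs/filters shrunk to desk scale.
acceptance_config <- function(normalization = "per_window_minmax",
                              epochs = 2)
  experiment_config(
    notch_freqs = numeric(0),          # fs = 50 Hz < 2 x 50 Hz mains
    simplify = list(S = 16, N = 50, F = 10),
    normalization = normalization,
    architecture = "encoder",
    arch_params = list(encoder = small_encoder()),
    train_budget = list(epochs = epochs, lr = 1e-3, batch_size = 64),
    protocol = list(train_hours_per_state = 4, scheme = "symptom",
                    test_plants = c("B0", "B1")),
    seed = 11)

# Full plant-wise LOOCV of the encoder pipeline on the acceptance cohort
# (the expensive object: ~5 min; computed once).
acceptance_loocv <- function() cached("acc_loocv",
                                      loocv(acceptance_cohort(), acceptance_config(),
                                            return_traces = TRUE))

# Separable toy window set (class means +-1, sd 0.1).
toy_windows <- function(n = 400, Tlen = 32, seed = 3) {
  set.seed(seed)
  w <- rbind(matrix(stats::rnorm(n / 2 * Tlen, 1, 0.1), n / 2),
             matrix(stats::rnorm(n / 2 * Tlen, -1, 0.1), n / 2))
  window_set(w, rep("B0", n), seq_len(n) * 16,
             c(rep(1L, n / 2), rep(0L, n / 2)), 5, 16)
}

# Brute-force oracles --------------------------------------------------------

brute_rolling_median <- function(x, N) {
  n <- length(x)
  lo_off <- (N - 1) %/% 2
  hi_off <- N %/% 2
  vapply(seq_len(n), function(i)
    stats::median(x[max(1, i - lo_off):min(n, i + hi_off)]), numeric(1))
}

# window statistic used by the generator contracts: mean absolute successive
# difference of the simplified signal
window_masd <- function(ws) apply(ws$windows, 1, function(x) mean(abs(diff(x))))

rms <- function(x) sqrt(mean(x^2))
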