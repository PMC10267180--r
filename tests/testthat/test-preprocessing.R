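# Preprocessing chain: notch filtering, rolling median, decimation,
# simplification, raw windowing, labelling and normalization.

test_that("notch filter removes mains, passes DC and nearby bands", {
  fs <- 500
  t <- (0:(fs * 10 - 1)) / fs
  s50 <- sin(2 * pi * 50 * t)
  s5 <- sin(2 * pi * 5 * t)
  att50 <- 20 * log10(rms(notch_filter(s50, fs, 50)) / rms(s50))
  att5 <- 20 * log10(rms(notch_filter(s5, fs, 50)) / rms(s5))
  expect_lte(att50, -20)
  expect_gt(att5, -1)
  const <- notch_filter(rep(3, 1000), fs)
  expect_lt(max(abs(const - 3)) / 3, 1e-6)
  expect_length(notch_filter(s50, fs), length(s50))
  expect_error(notch_filter(s50, fs, freqs = 250),
               class = "phytostress_config_error")
})

test_that("rolling median matches the brute-force oracle on 1000 random cases", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    N <- sample(1:25, 1)
    x <- stats::rnorm(n)
    expect_equal(rolling_median(x, N), brute_rolling_median(x, N),
                 tolerance = 1e-12)
  }
})

test_that("rolling median edge cases follow the stated policy", {
  expect_equal(rolling_median(c(1, 9, 2, 8, 3), 3), c(5, 2, 8, 3, 5.5))
  x <- stats::rnorm(20)
  expect_identical(rolling_median(x, 1), x)
  expect_equal(rolling_median(rep(2.5, 30), 7), rep(2.5, 30))
  expect_error(rolling_median(x, 0), class = "phytostress_config_error")
})

test_that("decimation keeps every F-th sample from the first", {
  expect_equal(downsample(c(0, 1, 2, 3, 4, 5), 2), c(0, 2, 4))
  x <- stats::rnorm(33)
  expect_identical(downsample(x, 1), x)
  expect_length(downsample(stats::rnorm(8000), 10), 800)
  expect_error(downsample(x, 0), class = "phytostress_config_error")
})

test_that("simplify equals the per-window brute-force chain", {
  cc <- cohort_config(n_plants = 2, fs = 500, duration_days = 0.003,
                      stimulus_day = 0.001, symptom_lag_days = 0.001)
  r <- generate_plant_recording(plant_profile("B0"), cc, seed = 7)
  ws <- simplify(r, S = 16, N = 50, F = 10)
  # 0.003 d * 86400 s/d / 16 s = 16 windows of 16*500/10 = 800 samples
  expect_equal(nrow(ws$windows), floor(0.003 * 86400 / 16))
  expect_equal(ncol(ws$windows), 800)
  expect_equal(ws$fs_effective, 50)
  for (k in c(1, 3, 16)) {
    raw <- r$samples[((k - 1) * 8000 + 1):(k * 8000)]
    expect_equal(as.numeric(ws$windows[k, ]),
                 downsample(brute_rolling_median(raw, 50), 10),
                 tolerance = 1e-12)
  }
  # constant recording -> constant windows
  rc <- recording("B1", 100, rep(4, 3200), 10, 20)
  wc <- simplify(rc, S = 16, N = 50, F = 10)
  expect_true(all(wc$windows == 4))
  # too-short recording -> empty set with warning
  rs <- recording("B2", 100, stats::rnorm(100), 0.3, 0.6)
  expect_warning(we <- simplify(rs, S = 16), "shorter")
  expect_equal(nrow(we$windows), 0)
})

test_that("raw windowing yields the documented sample counts", {
  cc <- cohort_config(n_plants = 2, fs = 500, duration_days = 0.002,
                      stimulus_day = 0.0007, symptom_lag_days = 0.0007)
  r <- generate_plant_recording(plant_profile("B0"), cc, seed = 1)
  expect_equal(ncol(make_windows(r, 4)$windows), 2000)       # 4 s at 500 Hz
  expect_equal(ncol(make_windows(r, 30, 3)$windows), 5000)   # 30 s / factor 3
  r10 <- recording("B0", 10, stats::rnorm(100), 4, 7)
  ws <- make_windows(r10, 1)
  expect_equal(nrow(ws$windows), 10)
  expect_equal(diff(ws$start_times), rep(1, 9))              # non-overlapping
})

test_that("labelling follows the protocol spans and excludes partial overlap", {
  # 10 h recording at 2 Hz, stimulus 3 h, symptoms 6 h, 2 h per state
  r <- recording("B0", 2, stats::rnorm(10 * 3600 * 2),
                 stimulus_time = 3 * 3600, symptom_time = 6 * 3600)
  ws <- make_windows(r, 16)
  H <- 1.9                                                # hours per state
  lab <- label_windows(ws, r, list(train_hours_per_state = H,
                                   scheme = "symptom"))
  expect_equal(lab$labels[1], 0L)                         # window at t0
  i_sym <- which(lab$start_times == 6 * 3600)
  expect_equal(lab$labels[i_sym], 1L)                     # window at symptoms
  # window straddling t0 + H is excluded
  i_straddle <- which(lab$start_times < H * 3600 &
                        lab$start_times + 16 > H * 3600)
  expect_length(i_straddle, 1)
  expect_equal(lab$labels[i_straddle], -1L)
  # between spans -> -1
  i_mid <- which(lab$start_times == 4 * 3600)
  expect_equal(lab$labels[i_mid], -1L)
  # labelled spans never cross the stimulus
  expect_true(all(lab$start_times[lab$labels == 0L] + 16 <= r$stimulus_time))
  expect_true(all(lab$start_times[lab$labels == 1L] >= r$symptom_time))
  # extended scheme anchors the stressed span at the recording end
  ext <- label_windows(ws, r, list(train_hours_per_state = 3,
                                   scheme = "extended"))
  end_t <- recording_duration(r)
  expect_true(all(lab$start_times[ext$labels == 1L] >= end_t - 3 * 3600))
  # spans exceeding the recording -> labelling error
  expect_error(label_windows(ws, r, list(train_hours_per_state = 5,
                                         scheme = "symptom")),
               class = "phytostress_label_error")
})

test_that("normalization variants follow their formulas", {
  w <- rbind(c(2, 4, 6), c(0, 0.5, 1), c(5, 5, 5))
  ws <- window_set(w, rep("B0", 3), 1:3, c(0L, 1L, -1L), 1, 3)
  mm <- suppressMessages(normalize(ws, "per_window_minmax"))
  expect_equal(mm$windows[1, ], c(0, 0.5, 1))
  expect_equal(mm$windows[2, ], c(0, 0.5, 1))   # already [0,1]: unchanged
  expect_equal(mm$windows[3, ], c(0, 0, 0))     # constant -> zeros
  dm <- normalize(ws, "per_window_demean")
  expect_equal(dm$windows[1, ], c(-2, 0, 2))
  expect_lt(max(abs(rowMeans(dm$windows))), 1e-9)
  expect_identical(normalize(ws, "none")$windows, w)
  # per-plant min-max uses labelled windows only
  pp <- normalize(ws, "per_plant_minmax")
  expect_equal(min(pp$windows[1:2, ]), 0)
  expect_equal(max(pp$windows[1:2, ]), 1)
  # ... or explicit extrema
  pp2 <- normalize(ws, "per_plant_minmax",
                   per_plant_extrema = list(B0 = c(0, 10)))
  expect_equal(pp2$windows[1, ], c(0.2, 0.4, 0.6))
})

test_that("per-window min-max invariants hold on random window sets", {
  set.seed(5)
  w <- matrix(stats::rnorm(200 * 40, sd = runif(200, 0.1, 10)), 200, 40)
  ws <- window_set(w, rep("B0", 200), 1:200, rep(-1L, 200), 1, 40)
  mm <- normalize(ws, "per_window_minmax")
  expect_equal(apply(mm$windows, 1, min), rep(0, 200))
  expect_equal(apply(mm$windows, 1, max), rep(1, 200))
  dm <- normalize(ws, "per_window_demean")
  expect_lt(max(abs(rowMeans(dm$windows))), 1e-9)
})

test_that("simplification is plant-wise independent of processing order", {
  cc <- cohort_config(n_plants = 3, fs = 50, duration_days = 0.005,
                      stimulus_day = 0.002, symptom_lag_days = 0.002,
                      seed = 9)
  cohort <- generate_cohort(cc)
  ws_fwd <- lapply(cohort, simplify)
  ws_rev <- rev(lapply(rev(cohort), simplify))
  for (p in names(cohort))
    expect_identical(ws_fwd[[p]]$windows, ws_rev[[p]]$windows)
})
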