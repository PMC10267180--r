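# Synthetic-data module: determinism, degenerate profiles, cohort structure,
# and the statistical contracts the downstream pipeline relies on.

test_that("disabled processes yield an all-zero recording of the right length", {
  cc <- cohort_config(n_plants = 2, fs = 25, duration_days = 0.02,
                      stimulus_day = 0.007, symptom_lag_days = 0.005)
  pz <- plant_profile("B0",
                      drift_spec = list(corner_hz = 1e-3, amp = 0),
                      texture_normal = texture_spec(0.05, 0),
                      texture_stressed = texture_spec(0.3, 0),
                      powerline_amp = 0, noise_sd = 0)
  r <- generate_plant_recording(pz, cc, seed = 1)
  expect_equal(length(r$samples), round(0.02 * 86400 * 25))
  expect_true(all(r$samples == 0))
  expect_lte(r$t0, r$stimulus_time)
  expect_lte(r$stimulus_time, r$symptom_time)
  expect_lte(r$symptom_time, r$t0 + recording_duration(r))
})

test_that("generation is deterministic given the seed", {
  cc <- cohort_config(n_plants = 2, fs = 25, duration_days = 0.01,
                      stimulus_day = 0.004, symptom_lag_days = 0.003)
  p <- plant_profile("B0", powerline_amp = 0.05)
  r1 <- generate_plant_recording(p, cc, seed = 7)
  r2 <- generate_plant_recording(p, cc, seed = 7)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_plant_recording(p, cc, seed = 8)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_plants = 2, duration_days = -1),
               class = "phytostress_config_error")
  expect_error(cohort_config(n_plants = 2, stimulus_day = 10,
                             symptom_lag_days = 6, duration_days = 15),
               class = "phytostress_config_error")
  expect_error(plant_profile("B0", amplitude_scale = 0),
               class = "phytostress_config_error")
  expect_error(plant_profile("B0", responsiveness = 1.5),
               class = "phytostress_config_error")
  expect_error(generate_cohort(cohort_config(n_plants = 1)),
               class = "phytostress_config_error")
})

test_that("cohorts carry the device/channel plant ids and are reproducible", {
  cc <- cohort_config(n_plants = 16, fs = 5, duration_days = 0.02,
                      stimulus_day = 0.007, symptom_lag_days = 0.005,
                      seed = 3)
  cohort <- generate_cohort(cc)
  expect_length(cohort, 16)
  expect_identical(names(cohort),
                   c(paste0("B", 0:7), paste0("C", 0:7)))
  expect_false(anyDuplicated(names(cohort)) > 0)
  # minimum cohort
  cc2 <- cohort_config(n_plants = 2, fs = 5, duration_days = 0.02,
                       stimulus_day = 0.007, symptom_lag_days = 0.005)
  expect_length(generate_cohort(cc2), 2)
  # profile sampling reproducible: amplitude scales identical run-to-run
  a1 <- sort(vapply(sample_cohort_profiles(cc), `[[`, numeric(1),
                    "amplitude_scale"))
  a2 <- sort(vapply(sample_cohort_profiles(cc), `[[`, numeric(1),
                    "amplitude_scale"))
  expect_identical(a1, a2)
})

test_that("at least the configured fraction of plants is responsive", {
  cc <- cohort_config(n_plants = 16, fs = 5, duration_days = 0.02,
                      stimulus_day = 0.007, symptom_lag_days = 0.005,
                      seed = 4)
  prof <- sample_cohort_profiles(cc)
  resp <- vapply(prof, `[[`, numeric(1), "responsiveness")
  floor_ <- cc$hyper$detectability_floor
  expect_gte(sum(resp > floor_), ceiling(0.8 * 16))
})

test_that("pre/post-symptom window statistics separate with |d| > 1", {
  # published sampling rate, shortened duration (desk scale)
  cc <- cohort_config(n_plants = 2, fs = 500, duration_days = 0.03,
                      stimulus_day = 0.01, symptom_lag_days = 0.008)
  r <- generate_plant_recording(plant_profile("B0"), cc, seed = 5)
  ws <- simplify(r, S = 16, N = 50, F = 10)
  masd <- window_masd(ws)
  pre <- ws$start_times + 16 <= r$stimulus_time
  post <- ws$start_times >= r$symptom_time
  d <- (mean(masd[post]) - mean(masd[pre])) /
    sqrt((stats::var(masd[post]) + stats::var(masd[pre])) / 2)
  expect_gt(abs(d), 1)
})

test_that("responsiveness 0 leaves pre/post segments indistinguishable", {
  cc <- cohort_config(n_plants = 2, fs = 25, duration_days = 0.02,
                      stimulus_day = 0.007, symptom_lag_days = 0.005)
  p0 <- plant_profile("B0", responsiveness = 0)
  rejections <- 0
  for (s in 1:20) {
    r <- generate_plant_recording(p0, cc, seed = s)
    ws <- simplify(r, 16, 50, 10)
    masd <- window_masd(ws)
    pre <- ws$start_times + 16 <= r$stimulus_time
    post <- ws$start_times >= r$symptom_time
    pv <- stats::wilcox.test(masd[pre], masd[post])$p.value
    if (pv < 0.01) rejections <- rejections + 1
  }
  # must NOT reject on >= 95% of seeds
  expect_lte(rejections, 1)
})

test_that("a single threshold on the window statistic separates the cohort", {
  cohort <- acceptance_cohort()
  stats_all <- lapply(cohort, function(rec) {
    ws <- normalize(simplify(rec, 16, 50, 10), "per_window_minmax")
    masd <- window_masd(ws)
    pre <- ws$start_times + 16 <= rec$stimulus_time
    post <- ws$start_times >= rec$symptom_time
    list(x = c(masd[pre], masd[post]),
         y = c(rep(0, sum(pre)), rep(1, sum(post))))
  })
  x <- unlist(lapply(stats_all, `[[`, "x"))
  y <- unlist(lapply(stats_all, `[[`, "y"))
  ths <- stats::quantile(x, seq(0.02, 0.98, by = 0.02))
  best <- max(vapply(ths, function(th) mean((x >= th) == y), numeric(1)))
  expect_gte(best, 0.8)
})
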