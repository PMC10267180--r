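# Feature-based baseline: the 34-feature set, brute-force oracles, scaling
# behaviour, context assembly, boosted-tree training with plant-wise tuning.

test_that("the default set has 34 features in three families", {
  fs_ <- default_feature_set()
  expect_length(fs_, 34)
  expect_false(anyDuplicated(fs_) > 0)
  expect_equal(sum(startsWith(fs_, "t_")), 14)
  expect_equal(sum(startsWith(fs_, "f_")), 12)
  expect_equal(sum(startsWith(fs_, "w_")), 8)   # wavelet family present
})

test_that("feature extraction yields 34 named columns per window", {
  r <- recording("B0", 10, stats::rnorm(10 * 60 * 20), 300, 700)
  fm <- extract_features(r, feature_config(context_windows = 2))
  expect_equal(ncol(fm$features), 34)
  expect_identical(colnames(fm$features), default_feature_set())
  expect_equal(nrow(fm$features), 20)
  expect_false(anyNA(fm$features))
  # labels from the experiment timestamps
  expect_true(all(fm$labels[fm$start_times + 60 <= 300] == 0L))
  expect_true(all(fm$labels[fm$start_times >= 700] == 1L))
  # too-short recording errors
  r2 <- recording("B0", 10, stats::rnorm(100), 3, 7)
  expect_error(extract_features(r2, feature_config(15, 60)),
               class = "phytostress_extract_error")
})

test_that("constant windows give zero variance and zero crossings, no NAs", {
  r <- recording("B0", 10, rep(2, 10 * 60 * 3), 60, 120)
  fm <- extract_features(r, feature_config(context_windows = 1))
  expect_equal(unname(fm$features[, "t_var"]), rep(0, 3))
  expect_equal(unname(fm$features[, "t_zcr"]), rep(0, 3))
  expect_false(anyNA(fm$features))
})

test_that("variance and MASD columns match brute-force oracles on 100 windows", {
  ns <- asNamespace("phytostress")
  set.seed(12)
  for (i in 1:100) {
    x <- stats::rnorm(120, sd = stats::runif(1, 0.1, 5))
    f <- ns$compute_window_features(x, 10)
    # two-pass population variance
    expect_equal(unname(f["t_var"]), sum((x - mean(x))^2) / length(x),
                 tolerance = 1e-12)
    expect_equal(unname(f["t_masd"]), mean(abs(diff(x))), tolerance = 1e-12)
    expect_equal(unname(f["t_rms"]), sqrt(mean(x^2)), tolerance = 1e-12)
  }
})

test_that("documented scale behaviour holds under amplitude scaling", {
  ns <- asNamespace("phytostress")
  set.seed(13)
  for (i in 1:25) {
    x <- stats::rnorm(200)
    c_ <- stats::runif(1, 0.5, 20)
    f1 <- ns$compute_window_features(x, 10)
    f2 <- ns$compute_window_features(c_ * x, 10)
    expect_equal(unname(f2["t_var"]), unname(c_^2 * f1["t_var"]),
                 tolerance = 1e-9)                       # quadratic
    expect_equal(unname(f2["t_masd"]), unname(c_ * f1["t_masd"]),
                 tolerance = 1e-9)                       # linear
    expect_equal(unname(f2["t_zcr"]), unname(f1["t_zcr"]))   # invariant
    expect_equal(unname(f2["f_centroid"]), unname(f1["f_centroid"]),
                 tolerance = 1e-9)                       # invariant
    expect_equal(unname(f2["w_d3"]), unname(f1["w_d3"]),
                 tolerance = 1e-9)                       # relative energy
  }
})

test_that("context samples concatenate K windows and keep pure labels only", {
  r <- recording("B0", 10, stats::rnorm(10 * 60 * 12), 300, 500)
  fm <- extract_features(r, feature_config(context_windows = 3))
  ctx <- make_context_samples(fm)
  expect_equal(ncol(ctx$features), 34 * 3)
  expect_equal(nrow(ctx$features), 12 - 3 + 1)
  expect_true(all(ctx$labels %in% c(-1L, 0L, 1L)))
  # a context containing any transition window must be -1: transition
  # windows start in [300, 500), so contexts whose last window starts in
  # [300, 480 + 2*60] contain one
  mixed <- which(ctx$start_times >= 300 & ctx$start_times <= 600)
  expect_true(length(mixed) > 0 && all(ctx$labels[mixed] == -1L))
  expect_match(colnames(ctx$features)[1], "_w1$")
  expect_match(colnames(ctx$features)[35], "_w2$")
})

test_that("boosted trees separate synthetic features and rank all of them", {
  set.seed(14)
  n <- 80
  plants <- rep(paste0("B", 0:3), each = n / 4)
  y <- rep(c(0, 1), n / 2)
  X <- matrix(stats::rnorm(n * 34), n, 34,
              dimnames = list(NULL, default_feature_set()))
  X[, "t_masd"] <- X[, "t_masd"] + 6 * y      # separable by construction
  bl <- train_baseline(X, y, plants, seed = 1)
  expect_s3_class(bl$model, "gbt_model")
  # held-out plant accuracy on fresh draws from the same process
  Xh <- matrix(stats::rnorm(40 * 34), 40, 34,
               dimnames = list(NULL, default_feature_set()))
  yh <- rep(c(0, 1), 20)
  Xh[, "t_masd"] <- Xh[, "t_masd"] + 6 * yh
  pr <- gbt_predict(bl$model, Xh)
  expect_gte(mean(as.integer(pr >= 0.5) == yh), 0.9)
  # ranking covers all 34 base features with non-negative gains
  expect_length(bl$ranking, 34)
  expect_setequal(names(bl$ranking), default_feature_set())
  expect_true(all(bl$ranking >= 0))
  expect_equal(names(bl$ranking)[1], "t_masd")  # the planted feature wins
  # tuning folds = number of training plants
  expect_equal(sum(!is.na(bl$cv_table$mean_cv_accuracy)), nrow(bl$cv_table))
  expect_error(train_baseline(X, y, rep("B0", n)),
               class = "phytostress_tuning_error")
})

test_that("the full baseline pipeline classifies a responsive cohort", {
  cc <- cohort_config(n_plants = 4, fs = 10, duration_days = 0.05,
                      stimulus_day = 0.02, symptom_lag_days = 0.013,
                      seed = 21,
                      hyper = cohort_hyper(responsive_fraction = 1,
                                           responsiveness_range = c(0.8, 1),
                                           powerline_fraction = 0))
  cohort <- generate_cohort(cc)
  fcfg <- feature_config(context_windows = 3, window_length_s = 60)
  fms <- lapply(cohort, function(r)
    extract_features(scale_recording(r), fcfg))
  ctx <- make_context_samples(bind_features(fms))
  lab <- ctx$labels %in% c(0L, 1L)
  train_sel <- lab & ctx$plant_ids != "B3"
  test_sel <- lab & ctx$plant_ids == "B3"
  bl <- train_baseline(ctx$features[train_sel, ], ctx$labels[train_sel],
                       ctx$plant_ids[train_sel], seed = 2)
  rep_ <- evaluate_baseline(bl, ctx$features[test_sel, ],
                            ctx$labels[test_sel], ctx$plant_ids[test_sel])
  expect_gte(rep_$average_accuracy, 0.8)
})
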