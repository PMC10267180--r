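# Handcrafted window features for the classical-ML baseline: 34 features per
# 60-s window spanning three families — temporal (moments, order statistics,
# Hjorth parameters, zero crossings, successive differences), frequency
# (periodogram moments, band powers, spectral entropy/flatness/edge) and
# time-frequency (Haar wavelet-decomposition energies). The concrete formulas
# are this package's own, chosen to match the three documented families; the
# set is versioned and swappable.

#' Configuration of the feature-based baseline
#'
#' @param context_windows consecutive windows concatenated into one
#'   prediction sample (study operating point: 15).
#' @param window_length_s feature-window length, seconds (60 in the study).
#' @param feature_set character vector of feature names; the default set has
#'   exactly 34 members.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(context_windows = 15, window_length_s = 60,
                           feature_set = default_feature_set()) {
  if (context_windows < 1) config_error("`context_windows` must be >= 1")
  stopifnot_scalar_num(window_length_s, "window_length_s", positive = TRUE)
  structure(list(context_windows = as.integer(context_windows),
                 window_length_s = window_length_s,
                 feature_set = feature_set),
            class = "feature_config")
}

#' The default 34-feature set
#' @return Character vector of 34 feature names (14 temporal, 12 frequency,
#'   8 time-frequency).
#' @export
default_feature_set <- function() {
  c("t_mean", "t_var", "t_skew", "t_kurt", "t_min", "t_max", "t_range",
    "t_median", "t_iqr", "t_rms", "t_masd", "t_zcr",
    "t_hjorth_mobility", "t_hjorth_complexity",
    "f_total_power", "f_centroid", "f_spread", "f_flatness", "f_entropy",
    "f_peak_freq", "f_edge95",
    "f_band1", "f_band2", "f_band3", "f_band4", "f_band5",
    "w_d1", "w_d2", "w_d3", "w_d4", "w_d5", "w_d6",
    "w_approx_ratio", "w_entropy")
}

# Haar discrete wavelet transform energies: per-level detail energies plus
# the final approximation energy (levels truncate odd tails).
haar_energies <- function(x, levels = 6) {
  d_energy <- numeric(levels)
  a <- x
  for (l in seq_len(levels)) {
    n2 <- length(a) %/% 2
    if (n2 < 1) break
    a2 <- a[seq_len(2 * n2)]
    ev <- a2[seq(2, 2 * n2, by = 2)]
    od <- a2[seq(1, 2 * n2 - 1, by = 2)]
    d <- (od - ev) / sqrt(2)
    a <- (od + ev) / sqrt(2)
    d_energy[l] <- sum(d^2)
  }
  list(details = d_energy, approx = sum(a^2))
}

periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / n
  keep <- 2:(floor(n / 2) + 1)
  list(freq = (keep - 1) * fs / n, power = P[keep])
}

# One window -> named vector of 34 features. Degenerate (constant) windows
# yield zeros, never NA.
compute_window_features <- function(x, fs) {
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n              # population variance
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mu)^4) / s^4 - 3 else 0
  dx <- diff(x)
  masd <- if (n > 1) mean(abs(dx)) else 0
  xc <- x - mu
  zcr <- sum(xc[-n] * xc[-1] < 0)
  sd_dx <- stats::sd(dx)
  sd_x <- stats::sd(x)
  mob <- if (isTRUE(sd_x > 0)) sd_dx / sd_x else 0
  ddx <- diff(dx)
  mob2 <- if (isTRUE(sd_dx > 0)) stats::sd(ddx) / sd_dx else 0
  cplx <- if (mob > 0) mob2 / mob else 0

  pg <- periodogram(x, fs)
  tp <- sum(pg$power)
  if (tp > 0) {
    rel <- pg$power / tp
    centroid <- sum(pg$freq * rel)
    spread <- sqrt(sum((pg$freq - centroid)^2 * rel))
    flat <- exp(mean(log(pg$power + 1e-30))) / mean(pg$power + 1e-30)
    ent <- -sum(ifelse(rel > 0, rel * log(rel), 0)) / log(length(rel))
    pk <- pg$freq[which.max(pg$power)]
    edge <- pg$freq[min(which(cumsum(rel) >= 0.95))]
    nyq <- fs / 2
    bands <- vapply(1:5, function(b)
      sum(rel[pg$freq > (b - 1) * nyq / 5 & pg$freq <= b * nyq / 5]),
      numeric(1))
  } else {
    centroid <- spread <- flat <- ent <- pk <- edge <- 0
    bands <- numeric(5)
  }

  he <- haar_energies(x - mu, 6)
  wt <- sum(he$details) + he$approx
  if (wt > 0) {
    wd <- he$details / wt
    wa <- he$approx / wt
    shares <- c(wd, wa)
    went <- -sum(ifelse(shares > 0, shares * log(shares), 0)) /
      log(length(shares))
  } else {
    wd <- numeric(6); wa <- 0; went <- 0
  }

  stats::setNames(
    c(mu, v, skew, kurt, min(x), max(x), max(x) - min(x),
      stats::median(x), stats::IQR(x), sqrt(mean(x^2)), masd, zcr, mob, cplx,
      tp, centroid, spread, flat, ent, pk, edge, bands,
      wd, wa, went),
    default_feature_set())
}

#' Extract the baseline feature matrix from a recording
#'
#' Cuts the recording into non-overlapping windows of
#' `feature_config$window_length_s` seconds and computes the 34-feature
#' vector in each. Windows ending before the stimulus are labelled 0, windows
#' starting after the symptom time 1, the transition -1. Deterministic; no
#' missing values.
#'
#' @param rec a [recording()].
#' @param config a [feature_config()].
#' @return An object of class `feature_matrix`: `features` (n x 34 named
#'   matrix), `labels`, `plant_ids`, `start_times`, `fs`, `config`.
#' @export
extract_features <- function(rec, config = feature_config()) {
  win_len <- round(config$window_length_s * rec$fs)
  n_win <- floor(length(rec$samples) / win_len)
  if (n_win < config$context_windows)
    extract_error(sprintf(
      "recording too short: %d window(s), need >= %d (context)",
      n_win, config$context_windows))
  starts <- (seq_len(n_win) - 1) * config$window_length_s
  feats <- t(vapply(seq_len(n_win), function(i) {
    x <- rec$samples[((i - 1) * win_len + 1):(i * win_len)]
    compute_window_features(x, rec$fs)
  }, numeric(length(default_feature_set()))))
  ends <- starts + config$window_length_s
  labels <- rep(-1L, n_win)
  labels[ends <= rec$stimulus_time + 1e-9] <- 0L
  labels[starts >= rec$symptom_time - 1e-9] <- 1L
  if (anyNA(feats)) extract_error("feature extraction produced NA")
  structure(list(features = feats, labels = labels,
                 plant_ids = rep(rec$plant_id, n_win),
                 start_times = starts, fs = rec$fs, config = config),
            class = "feature_matrix")
}

#' Bind feature matrices from several plants
#' @param ... `feature_matrix` objects (or one list of them).
#' @return A combined `feature_matrix`.
#' @export
bind_features <- function(...) {
  fms <- list(...)
  if (length(fms) == 1 && is.list(fms[[1]]) &&
      !inherits(fms[[1]], "feature_matrix")) fms <- fms[[1]]
  structure(list(features = do.call(rbind, lapply(fms, `[[`, "features")),
                 labels = unlist(lapply(fms, `[[`, "labels")),
                 plant_ids = unlist(lapply(fms, `[[`, "plant_ids")),
                 start_times = unlist(lapply(fms, `[[`, "start_times")),
                 fs = fms[[1]]$fs, config = fms[[1]]$config),
            class = "feature_matrix")
}

#' Concatenate consecutive windows into context samples
#'
#' One prediction sample = the features of `context_windows` consecutive
#' windows of a plant, concatenated (columns suffixed `_w1.._wK`, oldest
#' first). A sample keeps a 0/1 label only when all its windows agree on it;
#' mixed or transition contexts get -1.
#'
#' @param fm a [extract_features()] result (possibly multi-plant).
#' @param context_windows windows per sample; defaults to the value in
#'   `fm$config`.
#' @return A `feature_matrix` whose rows are context samples.
#' @export
make_context_samples <- function(fm, context_windows = fm$config$context_windows) {
  K <- context_windows
  base_names <- colnames(fm$features)
  out_rows <- list(); labels <- integer(0); plants <- character(0)
  starts <- numeric(0)
  for (p in unique(fm$plant_ids)) {
    idx <- which(fm$plant_ids == p)
    if (length(idx) < K) next
    f <- fm$features[idx, , drop = FALSE]
    l <- fm$labels[idx]
    for (i in K:length(idx)) {
      ctx <- (i - K + 1):i
      out_rows[[length(out_rows) + 1]] <- as.numeric(t(f[ctx, , drop = FALSE]))
      lab <- unique(l[ctx])
      labels <- c(labels, if (length(lab) == 1 && lab != -1L) lab else -1L)
      plants <- c(plants, p)
      starts <- c(starts, fm$start_times[idx[i]])
    }
  }
  if (!length(out_rows)) extract_error("no context samples could be formed")
  mat <- do.call(rbind, out_rows)
  colnames(mat) <- as.vector(vapply(seq_len(K), function(k)
    paste0(base_names, "_w", k), character(length(base_names))))
  structure(list(features = mat, labels = labels, plant_ids = plants,
                 start_times = starts, fs = fm$fs, config = fm$config),
            class = "feature_matrix")
}
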