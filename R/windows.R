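# WindowSet: a batch of fixed-length signal windows with per-window plant id,
# start time and state label (0 normal, 1 stressed, -1 transition/unlabelled).

#' Construct a window set
#'
#' @param windows numeric matrix, one window per row.
#' @param plant_ids character vector, one id per row.
#' @param start_times numeric vector of window start times (seconds), strictly
#'   increasing within each plant.
#' @param labels integer vector in `{-1, 0, 1}` (`-1` = unlabelled/transition).
#' @param fs_effective sampling rate of the rows, Hz (after any decimation).
#' @param window_length_s window duration in seconds.
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, plant_ids, start_times, labels,
                       fs_effective, window_length_s) {
  windows <- as.matrix(windows)
  n <- nrow(windows)
  if (length(plant_ids) != n || length(start_times) != n ||
      length(labels) != n)
    shape_error("windows, plant_ids, start_times and labels must align")
  if (!all(labels %in% c(-1L, 0L, 1L)))
    label_error("labels must be in {-1, 0, 1}")
  for (p in unique(plant_ids)) {
    st <- start_times[plant_ids == p]
    if (length(st) > 1 && any(diff(st) <= 0))
      shape_error(sprintf(
        "start_times must be strictly increasing within plant %s", p))
  }
  stopifnot_scalar_num(fs_effective, "fs_effective", positive = TRUE)
  stopifnot_scalar_num(window_length_s, "window_length_s", positive = TRUE)
  structure(list(windows = windows, plant_ids = as.character(plant_ids),
                 start_times = as.numeric(start_times),
                 labels = as.integer(labels),
                 fs_effective = fs_effective,
                 window_length_s = window_length_s),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %d windows x %d samples (%g s @ %g Hz), %d plants; labels: %s\n",
    nrow(x$windows), ncol(x$windows), x$window_length_s, x$fs_effective,
    length(unique(x$plant_ids)),
    paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
          collapse = " ")))
  invisible(x)
}

#' Subset a window set by row index
#' @param ws a [window_set()].
#' @param idx integer or logical row index.
#' @return A `window_set` with the selected rows.
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[idx, , drop = FALSE], ws$plant_ids[idx],
             ws$start_times[idx], ws$labels[idx],
             ws$fs_effective, ws$window_length_s)
}

#' Bind window sets row-wise
#' @param ... `window_set`s with identical geometry.
#' @return A combined `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) sets <- sets[[1]]
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (ncol(s$windows) != ncol(ref$windows) ||
        s$fs_effective != ref$fs_effective ||
        s$window_length_s != ref$window_length_s)
      shape_error("window sets have incompatible geometry")
  }
  window_set(do.call(rbind, lapply(sets, `[[`, "windows")),
             unlist(lapply(sets, `[[`, "plant_ids")),
             unlist(lapply(sets, `[[`, "start_times")),
             unlist(lapply(sets, `[[`, "labels")),
             ref$fs_effective, ref$window_length_s)
}

#' Cut a recording into non-overlapping raw-signal windows
#'
#' Windows of the (filtered) raw signal, optionally decimated — the variant
#' used before signal simplification was introduced (e.g. 30 s windows
#' decimated by 3). The trailing partial window is discarded. Stride equals
#' the window length: windows never overlap.
#'
#' @param rec a [recording()].
#' @param window_length_s window duration, seconds.
#' @param extra_downsample keep every k-th sample of each window (default 1).
#' @return A [window_set()] with all labels `-1`.
#' @export
make_windows <- function(rec, window_length_s, extra_downsample = 1) {
  stopifnot_scalar_num(window_length_s, "window_length_s", positive = TRUE)
  if (extra_downsample < 1 || extra_downsample != round(extra_downsample))
    config_error("`extra_downsample` must be a positive integer")
  win_len <- round(window_length_s * rec$fs)
  n_win <- floor(length(rec$samples) / win_len)
  if (n_win == 0) {
    warning("recording shorter than one window; empty window set")
    return(window_set(matrix(numeric(0), 0,
                             length(seq(1, win_len, by = extra_downsample))),
                      character(0), numeric(0), integer(0),
                      rec$fs / extra_downsample, window_length_s))
  }
  m <- matrix(rec$samples[seq_len(n_win * win_len)], nrow = n_win,
              byrow = TRUE)
  if (extra_downsample > 1)
    m <- m[, seq(1, win_len, by = extra_downsample), drop = FALSE]
  window_set(m, rep(rec$plant_id, n_win),
             rec$t0 + (seq_len(n_win) - 1) * window_length_s,
             rep(-1L, n_win), rec$fs / extra_downsample, window_length_s)
}

#' Label windows according to a training protocol
#'
#' Windows fully inside `[t0, t0 + H]` are labelled 0 (normal). Under the
#' symptom-anchored protocol (the 48-h scheme) windows fully inside
#' `[symptom_time, symptom_time + H]` are labelled 1 (stressed); under the
#' extended protocol the stressed span is the `H` hours ending at the end of
#' the recording. All other windows get `-1`: excluded from training but kept
#' for full-trace evaluation.
#'
#' @param ws a [window_set()] derived from `rec`.
#' @param rec the source [recording()] (provides the timestamps).
#' @param protocol list with `train_hours_per_state` (H, hours; 48 and 108 in
#'   the emulated study) and `scheme` (`"symptom"` or `"extended"`).
#' @return The window set with labels filled in.
#' @export
label_windows <- function(ws, rec,
                          protocol = list(train_hours_per_state = 48,
                                          scheme = "symptom")) {
  H <- protocol$train_hours_per_state
  stopifnot_scalar_num(H, "train_hours_per_state", positive = TRUE)
  scheme <- match.arg(protocol$scheme %||% "symptom",
                      c("symptom", "extended"))
  span_s <- H * 3600
  end_time <- rec$t0 + recording_duration(rec)
  normal_span <- c(rec$t0, rec$t0 + span_s)
  stressed_span <- if (scheme == "symptom")
    c(rec$symptom_time, rec$symptom_time + span_s)
  else c(end_time - span_s, end_time)
  if (normal_span[2] > rec$stimulus_time)
    label_error("normal training span crosses the stimulus time")
  if (stressed_span[2] > end_time + 1e-9)
    label_error("stressed training span exceeds the recording")
  if (stressed_span[1] < rec$stimulus_time)
    label_error("stressed training span starts before the stimulus")
  ours <- ws$plant_ids == rec$plant_id
  starts <- ws$start_times
  ends <- starts + ws$window_length_s
  labels <- ws$labels
  inside <- function(span) starts >= span[1] - 1e-9 & ends <= span[2] + 1e-9
  labels[ours] <- -1L
  labels[ours & inside(normal_span)] <- 0L
  labels[ours & inside(stressed_span)] <- 1L
  ws$labels <- labels
  ws
}
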