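# Causal fusion of consecutive prediction confidences and early stress-onset
# detection. Plant states persist for hours, so the confidence of the current
# window can borrow strength from the previous L windows without touching the
# classifier itself.

#' Construct a prediction trace
#'
#' Time-ordered per-window stressed-state confidences. A trace may span
#' several plants (e.g. straight out of [predict_confidences()] on a pooled
#' window set); per-plant operations subset or group by `plant_id`.
#'
#' @param plant_id character vector (scalar or per-window).
#' @param start_times window start times, seconds, strictly increasing within
#'   each plant.
#' @param confidences stressed-class probabilities in `[0, 1]`.
#' @param window_length_s window duration, seconds.
#' @param fused logical: has fusion been applied?
#' @param fusion_params list with `L` and `method` when fused.
#' @return An object of class `prediction_trace`.
#' @export
prediction_trace <- function(plant_id, start_times, confidences,
                             window_length_s, fused = FALSE,
                             fusion_params = NULL) {
  n <- length(confidences)
  if (length(plant_id) == 1L) plant_id <- rep(plant_id, n)
  if (length(plant_id) != n || length(start_times) != n)
    shape_error("plant_id, start_times and confidences must align")
  if (n && (min(confidences) < 0 || max(confidences) > 1))
    shape_error("confidences must lie in [0, 1]")
  for (p in unique(plant_id)) {
    st <- start_times[plant_id == p]
    if (length(st) > 1 && any(diff(st) <= 0))
      shape_error("start_times must be strictly increasing within a plant")
  }
  structure(list(plant_id = as.character(plant_id),
                 start_times = as.numeric(start_times),
                 confidences = as.numeric(confidences),
                 window_length_s = window_length_s,
                 fused = fused, fusion_params = fusion_params),
            class = "prediction_trace")
}

#' @export
print.prediction_trace <- function(x, ...) {
  cat(sprintf("<prediction_trace> %d windows (%g s), %d plant(s)%s\n",
              length(x$confidences), x$window_length_s,
              length(unique(x$plant_id)),
              if (x$fused) sprintf(", fused (%s, L=%d)",
                                   x$fusion_params$method,
                                   x$fusion_params$L) else ", raw"))
  invisible(x)
}

#' Subset a trace to one plant
#' @param trace a [prediction_trace()].
#' @param plant plant id.
#' @return A single-plant `prediction_trace`.
#' @export
subset_trace <- function(trace, plant) {
  keep <- trace$plant_id == plant
  if (!any(keep)) onset_error(sprintf("no windows for plant %s", plant))
  prediction_trace(trace$plant_id[keep], trace$start_times[keep],
                   trace$confidences[keep], trace$window_length_s,
                   trace$fused, trace$fusion_params)
}

causal_fuse <- function(conf, L, method) {
  n <- length(conf)
  out <- numeric(n)
  if (method == "mean") {
    cs <- cumsum(conf)
    full <- L:n
    if (L <= n) out[full] <- (cs[full] - c(0, cs)[full - L + 1]) / L
    warm <- seq_len(min(L - 1, n))
    out[warm] <- cs[warm] / warm
  } else {
    for (i in seq_len(n))
      out[i] <- stats::median(conf[max(1, i - L + 1):i])
  }
  out
}

#' Fuse consecutive prediction confidences causally
#'
#' The fused confidence at index `i` is the mean or median of the raw
#' confidences at indices `max(1, i - L + 1) .. i` — only past windows, so
#' the system stays causal. During the warm-up (fewer than `L` predecessors)
#' the window shrinks rather than emitting no prediction, keeping the trace
#' full-length. Multi-plant traces are fused per plant.
#'
#' @param trace an unfused [prediction_trace()].
#' @param L number of consecutive predictions to combine (the study used 10
#'   and 1000).
#' @param method `"mean"` or `"median"`.
#' @return A fused `prediction_trace` of the same length.
#' @export
combine_predictions <- function(trace, L, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.numeric(L) || length(L) != 1 || L < 1 || L != round(L))
    config_error("`L` must be a positive integer")
  if (trace$fused) config_error("trace is already fused")
  conf <- trace$confidences
  out <- numeric(length(conf))
  for (p in unique(trace$plant_id)) {
    ours <- trace$plant_id == p
    out[ours] <- causal_fuse(conf[ours], L, method)
  }
  prediction_trace(trace$plant_id, trace$start_times, out,
                   trace$window_length_s, fused = TRUE,
                   fusion_params = list(L = as.integer(L), method = method))
}

#' Decision delay introduced by fusing L predictions
#'
#' The time the fused system needs to fully reflect a state change:
#' `L * window_length_s` seconds. With 16-s windows this is 4.44 h for
#' L = 1000 and 2.66 min for L = 10.
#'
#' @param L fusion length.
#' @param window_length_s window duration, seconds.
#' @return Numeric scalar (seconds) with attribute-free formatting available
#'   via [format_duration()].
#' @export
prediction_delay <- function(L, window_length_s) {
  if (L < 1) config_error("`L` must be >= 1")
  stopifnot_scalar_num(window_length_s, "window_length_s", positive = TRUE)
  L * window_length_s
}

#' Threshold a confidence trace into binary state labels
#'
#' @param trace a [prediction_trace()].
#' @param threshold decision threshold in (0, 1); confidence `>= threshold`
#'   maps to 1 (ties go to the stressed class).
#' @return Integer vector of 0/1 labels.
#' @export
threshold_trace <- function(trace, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    config_error("`threshold` must lie in (0, 1)")
  as.integer(trace$confidences >= threshold)
}

#' Detect the onset of the stressed state in a fused trace
#'
#' The onset is the first local maximum of the fused confidence whose value
#' reaches `onset_threshold`. A local maximum is strictly greater than its
#' predecessor and `>=` its successor; the final index counts as a peak (so
#' late-rising traces still yield an onset), the first index does not (it has
#' no predecessor to exceed). When the trace carries a `search_from` time
#' (e.g. the stimulus), earlier windows are ignored.
#'
#' @param fused_trace a fused, single-plant [prediction_trace()].
#' @param onset_threshold threshold in (0.5, 1); the study used 0.65.
#' @param search_from optional time (seconds): only windows starting at or
#'   after it are searched.
#' @return An object of class `onset_result` with `onset_time` (seconds, or
#'   `NA` if no qualifying peak), `threshold` and `rule`.
#' @export
detect_stress_onset <- function(fused_trace, onset_threshold = 0.65,
                                search_from = NULL) {
  if (onset_threshold <= 0.5 || onset_threshold >= 1)
    config_error("`onset_threshold` must lie in (0.5, 1)")
  if (length(unique(fused_trace$plant_id)) > 1)
    onset_error("onset detection needs a single-plant trace")
  conf <- fused_trace$confidences
  times <- fused_trace$start_times
  if (!length(conf)) onset_error("empty trace")
  keep <- if (is.null(search_from)) rep(TRUE, length(conf))
          else times >= search_from
  conf_s <- conf[keep]; times_s <- times[keep]
  n <- length(conf_s)
  onset_time <- NA_real_
  if (n >= 2) {
    for (i in 2:n) {
      is_peak <- conf_s[i] > conf_s[i - 1] &&
        (i == n || conf_s[i] >= conf_s[i + 1])
      if (is_peak && conf_s[i] >= onset_threshold) {
        onset_time <- times_s[i]
        break
      }
    }
  }
  structure(list(onset_time = onset_time, threshold = onset_threshold,
                 rule = "first local max >= threshold (end counts as peak)",
                 plant_id = unique(fused_trace$plant_id)),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (is.na(x$onset_time))
    cat(sprintf("<onset_result> plant %s: no onset (threshold %.2f)\n",
                x$plant_id, x$threshold))
  else
    cat(sprintf("<onset_result> plant %s: onset at %s (threshold %.2f)\n",
                x$plant_id, format_duration(x$onset_time, "h"), x$threshold))
  invisible(x)
}
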