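# Window normalization variants. Per-plant extrema are computed from
# training-visible (labelled) windows only, so test-period data never leaks
# into the scaling.

#' Per-plant extrema from training-visible windows
#'
#' @param ws a labelled [window_set()].
#' @return Named list mapping plant id to `c(min, max)`. Plants without any
#'   labelled window fall back to all their windows, with a warning.
#' @export
plant_extrema <- function(ws) {
  out <- list()
  for (p in unique(ws$plant_ids)) {
    ours <- ws$plant_ids == p
    vis <- ours & ws$labels %in% c(0L, 1L)
    if (!any(vis)) {
      warning(sprintf(
        "plant %s has no labelled windows; extrema use all its windows", p))
      vis <- ours
    }
    out[[p]] <- range(ws$windows[vis, , drop = FALSE])
  }
  out
}

#' Normalize the windows of a window set
#'
#' * `none` — identity;
#' * `per_plant_minmax` — `(x - min_p) / (max_p - min_p)` with each plant's
#'   extrema (from its training-visible data, or `per_plant_extrema`);
#' * `per_window_minmax` — each window rescaled to span `[0, 1]`; constant
#'   windows map to all-zeros (no division), with a message;
#' * `per_window_demean` — each window shifted to mean zero.
#'
#' @param ws a [window_set()].
#' @param method one of the four variants above.
#' @param per_plant_extrema optional named list of `c(min, max)` per plant,
#'   e.g. computed on a training set via [plant_extrema()].
#' @return The window set with normalized rows.
#' @export
normalize <- function(ws,
                      method = c("none", "per_plant_minmax",
                                 "per_window_minmax", "per_window_demean"),
                      per_plant_extrema = NULL) {
  method <- match.arg(method)
  if (method == "none") return(ws)
  w <- ws$windows
  if (method == "per_plant_minmax") {
    ext <- per_plant_extrema %||% plant_extrema(ws)
    for (p in unique(ws$plant_ids)) {
      if (is.null(ext[[p]]))
        config_error(sprintf("no extrema provided for plant %s", p))
      r <- ext[[p]]
      ours <- ws$plant_ids == p
      denom <- r[2] - r[1]
      if (denom == 0) denom <- 1
      w[ours, ] <- (w[ours, , drop = FALSE] - r[1]) / denom
    }
  } else if (method == "per_window_minmax") {
    lo <- apply(w, 1, min)
    hi <- apply(w, 1, max)
    rng <- hi - lo
    flat <- rng == 0
    if (any(flat)) {
      message(sprintf("%d constant window(s) mapped to all-zeros", sum(flat)))
      rng[flat] <- 1
      lo[flat] <- w[flat, 1]
    }
    w <- (w - lo) / rng
  } else if (method == "per_window_demean") {
    w <- w - rowMeans(w)
  }
  ws$windows <- w
  ws
}
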