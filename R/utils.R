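# Internal helpers: classed conditions, seed derivation, small numerics.

#' @keywords internal
ps_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "phytostress_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

config_error  <- function(msg) ps_abort(msg, "phytostress_config_error")
format_error  <- function(msg) ps_abort(msg, "phytostress_format_error")
shape_error   <- function(msg) ps_abort(msg, "phytostress_shape_error")
split_error   <- function(msg) ps_abort(msg, "phytostress_split_error")
label_error   <- function(msg) ps_abort(msg, "phytostress_label_error")
train_error   <- function(msg) ps_abort(msg, "phytostress_train_error")
onset_error   <- function(msg) ps_abort(msg, "phytostress_onset_error")
extract_error <- function(msg) ps_abort(msg, "phytostress_extract_error")
tuning_error  <- function(msg) ps_abort(msg, "phytostress_tuning_error")

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    config_error(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0)
    config_error(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

#' Derive a child seed from a master seed and a string tag
#'
#' Deterministic 31-bit hash so that per-fold / per-plant seeds do not change
#' when unrelated plants are added to a cohort.
#'
#' @param seed master seed (integer-valued scalar).
#' @param tag character scalar mixed into the hash (e.g. a plant id).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot_scalar_num(seed, "seed")
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + code) %% mod
  }
  as.integer(h)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code does not disturb user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Format a duration given in seconds
#'
#' Two decimals, truncated rather than rounded (160 s prints as
#' `"2.66 min"`, 16,000 s as `"4.44 h"` — the convention the reported
#' decision delays follow).
#'
#' @param seconds duration in seconds.
#' @param unit one of `"auto"`, `"s"`, `"min"`, `"h"`.
#' @return Character scalar, e.g. `"4.44 h"`.
#' @export
format_duration <- function(seconds, unit = c("auto", "s", "min", "h")) {
  unit <- match.arg(unit)
  if (unit == "auto") {
    unit <- if (seconds >= 3600) "h" else if (seconds >= 60) "min" else "s"
  }
  value <- switch(unit, s = seconds, min = seconds / 60, h = seconds / 3600)
  sprintf("%.2f %s", floor(value * 100 + 1e-9) / 100, unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
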