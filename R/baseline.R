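# The classical-ML comparison approach: per-window handcrafted features over
# a multi-window context, boosted-tree classification with plant-wise
# hyperparameter tuning, and gain-based feature ranking.

default_tuning_grid <- function() {
  expand.grid(n_trees = 40, max_depth = c(2, 3), eta = 0.1,
              lambda = 1, alpha = 0, subsample = 0.8)
}

#' Train the feature-based baseline with plant-wise tuning
#'
#' Hyperparameters (number of trees, max depth, lambda, alpha, subsampling
#' fraction) are tuned by a cross-validation in which each fold holds out the
#' samples of one training plant; the grid point with the highest mean
#' per-plant-fold accuracy wins and is refitted on all training samples.
#' Feature ranking aggregates each boosted tree's split gains over the
#' context copies of every base feature.
#'
#' @param features numeric matrix of context samples (named columns).
#' @param labels 0/1 labels per row.
#' @param plant_ids plant id per row (>= 2 distinct plants).
#' @param tuning_grid data frame of hyperparameter combinations; default a
#'   small grid over depth.
#' @param seed RNG seed.
#' @return List of class `baseline_model`: the fitted `gbt_model`, the
#'   per-base-feature gain `ranking` (all features, non-negative, decreasing),
#'   the winning parameters and the CV table.
#' @export
train_baseline <- function(features, labels, plant_ids,
                           tuning_grid = default_tuning_grid(), seed = 0) {
  plants <- unique(plant_ids)
  if (length(plants) < 2)
    tuning_error("plant-wise tuning needs >= 2 training plants")
  if (!all(labels %in% c(0, 1))) train_error("labels must be 0/1")
  features <- as.matrix(features)
  cv_scores <- numeric(nrow(tuning_grid))
  for (gi in seq_len(nrow(tuning_grid))) {
    par <- tuning_grid[gi, ]
    fold_acc <- vapply(plants, function(p) {
      tr <- plant_ids != p
      if (length(unique(labels[tr])) < 2) return(NA_real_)
      m <- gbt_train(features[tr, , drop = FALSE], labels[tr],
                     n_trees = par$n_trees, max_depth = par$max_depth,
                     eta = par$eta, lambda = par$lambda, alpha = par$alpha,
                     subsample = par$subsample,
                     seed = derive_seed(seed, paste0("cv", gi, p)))
      pr <- gbt_predict(m, features[!tr, , drop = FALSE])
      mean(as.integer(pr >= 0.5) == labels[!tr])
    }, numeric(1))
    cv_scores[gi] <- mean(fold_acc, na.rm = TRUE)
  }
  best <- which.max(cv_scores)
  par <- tuning_grid[best, ]
  model <- gbt_train(features, labels,
                     n_trees = par$n_trees, max_depth = par$max_depth,
                     eta = par$eta, lambda = par$lambda, alpha = par$alpha,
                     subsample = par$subsample,
                     seed = derive_seed(seed, "final"))
  # fold context copies (feat_w1..feat_wK) back onto base feature names
  base_names <- sub("_w[0-9]+$", "", names(model$importance))
  ranking <- sort(tapply(model$importance, base_names, sum), decreasing = TRUE)
  structure(list(model = model, ranking = ranking,
                 best_params = as.list(par),
                 cv_table = cbind(tuning_grid, mean_cv_accuracy = cv_scores)),
            class = "baseline_model")
}

#' Evaluate a baseline model per plant
#'
#' @param baseline a [train_baseline()] result.
#' @param features context-sample matrix.
#' @param labels 0/1 labels.
#' @param plant_ids plant id per row.
#' @return An [evaluation_report()] over the plants present.
#' @export
evaluate_baseline <- function(baseline, features, labels, plant_ids) {
  per_plant <- list()
  for (p in unique(plant_ids)) {
    sel <- plant_ids == p & labels %in% c(0, 1)
    if (!any(sel)) next
    pr <- gbt_predict(baseline$model, as.matrix(features)[sel, , drop = FALSE])
    per_plant[[p]] <- mean(as.integer(pr >= 0.5) == labels[sel])
  }
  evaluation_report(per_plant)
}

#' Full-trace per-plant min-max scaling for the baseline
#'
#' The classical approach scales each plant's signal with extrema of the
#' full-length recording; here the extrema come from training-period data
#' only, to keep evaluation leakage-free.
#'
#' @param rec a [recording()].
#' @param extrema `c(min, max)`; defaults to the pre-symptom segment range.
#' @return The scaled [recording()].
#' @export
scale_recording <- function(rec, extrema = NULL) {
  if (is.null(extrema)) {
    train_part <- rec$samples[seq_len(max(2, floor(rec$stimulus_time * rec$fs)))]
    extrema <- range(train_part)
  }
  denom <- extrema[2] - extrema[1]
  if (denom == 0) denom <- 1
  recording(rec$plant_id, rec$fs, (rec$samples - extrema[1]) / denom,
            rec$stimulus_time, rec$symptom_time, rec$t0)
}
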