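# phytostress

Detecting nitrogen-deficiency stress in greenhouse plants from raw
electrophysiological recordings.

Plants respond to environmental stress with variations of electrical
potential measurable on the stem. `phytostress` implements an end-to-end
workflow that classifies fixed-length windows of a univariate voltage trace
(sampled at 500 Hz) as *normal* vs *stressed* and estimates the stress onset
time, typically before symptoms become visible:

1. **conditioning** — zero-phase notch filtering (50/100 Hz), then the
   *simplification transform*: non-overlapping `S = 16 s` windows, an
   `N = 50`-sample rolling median per window, decimation by `F = 10`;
2. **normalization** — per-window min–max by default;
3. **window classification** — a 1-D convolutional encoder with time-wise
   softmax attention (plus MLP/FCN/ResNet comparison architectures),
   implemented and trained in base R and verified against numerical
   gradients;
4. **causal fusion** — the confidence of window *i* becomes the mean (or
   median) of the previous `L` raw confidences; the decision delay is
   `L × 16 s` (2.66 min at `L = 10`, 4.44 h at `L = 1000`);
5. **plant-wise evaluation** — held-out plants and leave-one-out
   cross-validation, never mixing a plant's windows across the split;
6. **onset detection** — the first local peak of the fused confidence above
   a threshold (default 0.65).

A handcrafted-feature baseline (34 temporal/spectral/wavelet features per
60-s window, 15-window context, gradient-boosted trees with plant-wise
tuning) is included for comparison, and a synthetic multi-plant cohort
generator stands in for the proprietary recordings the method was developed
on. Audience: researchers in plant phenotyping / biosignal classification
who need a tested, reproducible reference pipeline rather than a one-off
script.

## Worked example

A scaled cohort (8 plants, 12 h at 50 Hz, nitrogen cut after 4 h, symptoms
4 h later, all plants responsive) through the encoder pipeline:

```r
library(phytostress)

cc <- cohort_config(n_plants = 8, fs = 50, duration_days = 0.5,
                    stimulus_day = 1/6, symptom_lag_days = 1/6, seed = 11,
                    hyper = cohort_hyper(responsive_fraction = 1,
                                         responsiveness_range = c(0.8, 1),
                                         powerline_fraction = 0))
cohort <- generate_cohort(cc)

cfg <- experiment_config(
  notch_freqs = numeric(0),              # 50 Hz sampling: no mains band
  simplify = list(S = 16, N = 50, F = 10),
  normalization = "per_window_minmax",
  architecture = "encoder",
  arch_params = list(encoder = list(block_filters = c(8, 8, 8),
                                    kernel_sizes = c(3, 5, 7),
                                    dropout = 0.2, pool = 2)),
  train_budget = list(epochs = 2, batch_size = 64),
  protocol = list(train_hours_per_state = 4, scheme = "symptom",
                  test_plants = "B0"),
  seed = 11)

res <- loocv(cohort, cfg)
round(res$summary$per_plant, 3)
#>    B0    B1    B2    B3    B4    B5    B6    B7
#> 0.989 0.997 0.881 0.984 0.984 0.981 0.994 0.975
res$summary$mean_test_accuracy
#> [1] 0.9733
```

Each number is the window-level accuracy on the held-out plant's labelled
windows (first 4 h = normal, 4 h from symptom onset = stressed) for the fold
that excluded that plant from training; the mean is the plant-wise LOOCV
accuracy. Fusing each held-out trace with the mean of the previous 10
confidences (`combine_predictions(trace, 10, "mean")`) raises the mean
accuracy to 1.00 on this cohort — label persistence makes isolated window
errors recoverable.

Full-trace onset detection (a lighter 4-plant cohort through the whole
orchestrated pipeline — simulate, preprocess, train, predict, fuse,
evaluate, detect-onset — writing traces and a manifest):

```r
cfg$cohort <- list(n_plants = 4, fs = 50, duration_days = 0.5,
                   stimulus_day = 1/6, symptom_lag_days = 1/6,
                   hyper = list(responsive_fraction = 1,
                                responsiveness_range = c(0.8, 1),
                                powerline_fraction = 0))
cfg$fusion <- list(L = 10, method = "mean")
res <- run_pipeline(cfg, out_dir = "run")
res$report
#> <evaluation_report>
#>   B0    93.72%
#>   average 93.72% (sd NA%), training 96.09%
res$fused_accuracy
#>  B0
#>   1
res$onsets$B0
#> <onset_result> plant B0: onset at 5.09 h (threshold 0.65)
```

The nitrogen cut happens at 4.00 h and visual symptoms at 8.00 h: the fused
confidence trace of the held-out plant crosses the 0.65 first-peak rule at
5.09 h — about an hour into the stress and almost three hours before
"symptoms", which is the early-detection behaviour the workflow is built
for. Fusing L = 10 confidences also lifts the 93.7% raw window accuracy to
100% on this trace.

## Layout

```
R/                 modules: synthetic cohort, I/O + config, preprocessing,
                   NN architectures + training, evaluation/LOOCV, fusion +
                   onset, features + boosted trees, pipeline orchestration
src/               C++ rolling median
inst/cli/          `phytostress` command-line entry point
tests/testthat/    unit, property and acceptance suites (all data generated)
vignettes/         methods vignette: model, assumptions, design decisions
scripts/           acceptance.R
```
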