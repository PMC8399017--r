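# pdgait

Objective, clinically interpretable quantification of gait impairment in
Parkinson's disease from markerless pose estimation.

During a standard MDS-UPDRS gait assessment (item 3.10) the patient walks
away from and back towards the examiner, who assigns a severity score from
0 (normal) to 3 (moderate impairment). The score is subjective: trained
raters commonly differ by a point. `pdgait` computes an objective second
opinion from an ordinary video of that walk, processed by a pose network
into BODY_25 key-point time series — no markers, wearables, or gait
laboratory.

The pipeline:

1. **Pose I/O** — read per-frame BODY_25 JSON, select the patient among
   multiple detections, window clinician-annotated regions of interest
   (straight walking towards/away, turns excluded), and interpolate short
   key-point dropouts.
2. **Signals** — seven normalised time series per ROI (leg-length ratio
   difference, vertical body angle, horizontal ankle/wrist angles,
   heel separation, per-ankle speed), all invariant to image translation
   and scale, with peak/trough gait-cycle events detected by a
   MAD-thresholded prominence rule.
3. **Cadence** — a conjugate Gamma-Poisson model over pooled events of the
   three leg-driven signals. With prior λ ~ Gamma(α₀ = 2, β₀ = 1) — mean
   2 Hz, 95% credible interval (0.24, 5.57) Hz — the posterior after frame
   *i* is Gamma(α₀ + ΣYⱼ, β₀ + 3i/F), reported at the frame of the last
   detected event as a point estimate with credible interval.
4. **Features** — speed, arm swing velocity and amplitude, postural
   control (stride-width CV), and movement roughness (min/max across
   ankles).
5. **Ordinal classifier** — three binary random forests for the questions
   score > 0, > 1, > 2, trained on SMOTE-balanced features; class
   probabilities are differences of monotonicity-clipped cumulative
   probabilities, e.g. p₁ = P(y > 0) − P(y > 1). Evaluation uses grouped,
   stratified 10-fold CV that never splits a video's two ROIs across
   folds, plus a label-permutation test.
6. **Interpretability** — per-prediction eccentricity tables (per-feature,
   per-severity empirical CDF positions against a rated cohort), exact
   Shapley decompositions of each binary sub-classifier, and Gini
   importances.

Because clinical recordings cannot be redistributed, the package ships a
synthetic walking-skeleton generator (`simulate_walk()`,
`simulate_cohort()`) with controllable step frequency, arm swing,
stride-width variability, jerk noise, camera direction, key-point jitter
and dropout; every stage is validated end-to-end against its ground truth.

## Worked example

```r
library(pdgait)

# a synthetic patient: slowed cadence, attenuated arm swing
walk <- simulate_walk(gait_sim_params(step_frequency = 1.8,
                                      arm_swing_amplitude_factor = 0.4,
                                      seed = 7, duration = 8))
res <- extract_gait_features(walk$sequence)
res$step_frequency
#> step frequency: 1.864 Hz, 95% CI (1.35, 2.45) [42 events]
round(res$features, 3)
#>               speed  arm_swing_velocity arm_swing_amplitude    postural_control
#>               1.864               0.016               0.257               0.253
#>       roughness_min       roughness_max
#>               0.318               0.374
```

The cadence estimate (1.86 Hz against a ground truth of 1.80) comes with a
posterior credible interval; the feature vector shows the attenuated arm
swing (amplitude 0.257 rad versus ≈0.6 rad for a full swing).

```r
cohort <- simulate_cohort(n_videos = 100,
                          class_probs = c(0.25, 0.30, 0.25, 0.20), seed = 11)
model <- train_ordinal_model(cohort[, GAIT_FEATURES], cohort$rating,
                             groups = cohort$video_id, seed = 1)
round(predict_ordinal_proba(model, res$features), 3)
#>         p0    p1    p2 p3
#> [1,] 0.002 0.366 0.632  0
```

The model places this walk between severities 1 and 2. The eccentricity
table says why — each entry is the percentile of the patient's feature
value within one severity stratum of the cohort, so values near 0.5 mark
the stratum the patient is typical of:

```r
round(compute_eccentricity_table(res$features,
                                 cohort[, GAIT_FEATURES], cohort$rating), 2)
#>                        0    1    2 3
#> speed               0.15 0.58 0.95 1
#> arm_swing_velocity  0.00 0.00 0.67 1
#> arm_swing_amplitude 0.00 0.00 0.50 1
#> postural_control    0.12 0.63 0.97 1
#> roughness_min       0.85 0.22 0.00 0
#> roughness_max       0.85 0.33 0.00 0
```

Speed and postural control look like severity 1, the arm swing like
severity 2; `shap_decompose(model, res$features, cohort[, GAIT_FEATURES])`
attributes each sub-classifier's probability to the individual features.

Cross-validated performance on a synthetic cohort (grouped so both ROIs of
a video share a fold):

```r
cv <- grouped_stratified_cv(cohort[, GAIT_FEATURES], cohort$rating,
                            cohort$video_id, k = 10, seed = 1)
#> balanced accuracy: 0.90 | accuracy(+/-1): 1.00 | Spearman rho: 0.97
```

A command-line front end wrapping these functions (subcommands `simulate`,
`signals`, `stepfreq`, `features`, `train`, `cv`, `predict`, `explain`)
is installed at `system.file("cli", "pdgait.R", package = "pdgait")`.

See `vignettes/gait-quantification.Rmd` for the models, parameter choices,
and what the synthetic validation does and does not show.

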