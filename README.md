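# stagewalk

Functional-data tests and stage classifiers for smartphone accelerometry of
Alzheimer's patients.

## The problem

Alzheimer's disease alters gait, and the severity of the disease — staged
clinically with the Global Deterioration Scale and grouped here into
**early** (GDS 2–3), **middle** (GDS 4–5) and **late** (GDS 6–7) — leaves a
signature in free-movement accelerometer recordings taken by the smartphone
a patient simply carries in a pocket. Such recordings are awkward data:
each one is a three-axis curve (x, y, z accelerations in m/s²) sampled
irregularly at a nominal 8 Hz, on its own time grid, for its own duration,
with its own unknown device orientation. `stagewalk` implements an analysis
pipeline for exactly this kind of cohort, for biostatisticians working on
movement biomarkers:

1. **Synthetic cohorts** (`cohort_config()`, `generate_cohort()`,
   `write_cohort()`/`read_cohort()`) — a generator whose defaults mirror a
   35-patient study (7 early / 18 middle / 10 late; 187 recordings split
   41/100/46 by stage; 2–8 recordings per patient). Each recording is a
   randomly oriented gravity constant plus a stage-dependent gait sinusoid
   plus stationary AR(1) noise, so the within-recording process is
   stationary and stage effects live in the xy-plane.
2. **Preprocessing** (`interpolate_to_seconds()`, `random_windows()`) —
   linear interpolation onto the integer-second grid t = 1, …, Tᵢ
   (Tᵢ = round of the final timestamp), then equal-length datasets by
   windows of length l = min Tᵢ at offsets lᵢ ~ U{0, …, Tᵢ − l}, redrawn
   per repetition: stationarity makes the windows exchangeable.
3. **Equality-of-means tests** (`anova_rp()`, `anova_maxf()`,
   `l2_mean_test()`, `repeated_test()`) — for stage groups with mean curves
   μ₁, μ₂, μ₃, tests of H₀: μ₁ = μ₂ = μ₃ by (i) k = 30 random projections
   onto the unit sphere with one-way ANOVA F tests combined by Bonferroni or
   Benjamini–Hochberg, and (ii) the bootstrap sup-F statistic
   T = supₜ F(r(t), s(t), u(t)); and the two-sample bootstrap L2 test with
   T = ∫ (s̄(t) − ū(t))² dt. Bootstrap p-values are
   (1 + #{T*ᵦ ≥ T})/(B + 1) with B = 999 by default, resampling curves
   within groups and centering at the original group means. Repeated
   windowings are summarised by the mean, SD, and proportion ≤ 0.05 of the
   J p-values.
4. **Functional classification** (`hmode_depth()`, `depth_transform()`,
   `nw_classify()`, `lopo_evaluate()`) — each curve is reduced to R³ by its
   h-mode depth with respect to the three stage groups, then classified by
   a Nadaraya–Watson kernel rule (class-conditional Gaussian KDE × empirical
   prior), evaluated leave-one-patient-out with majority votes over a
   patient's curves and over windowing repetitions.
5. **Feature extraction** (`aggregate_recording()`, `summarize_series()`,
   `integrate_kinematics()`, `extract_features()`) — every recording,
   whatever its length, becomes 90 features: per-second and per-minute
   sum/median/mean series per axis, each summarised by sum, mean, median,
   min, max; optional speed/displacement features via cumulative trapezoids.
6. **Stage classifiers** (`split_cohort()`, `train_nn()`,
   `classify_patients()`, `layer_sweep()`, `stage_baselines()`) —
   patient-grouped ~80/20 splits (a patient's recordings never straddle the
   split), a feed-forward network (logistic activations, 175 hidden neurons,
   one output unit, resilient backpropagation with weight backtracking)
   against tree / random-forest / SVM baselines, with patient-level
   majority votes.

Everything takes and returns tibbles, pipes cleanly, and supports
`tidy()`/`glance()`/`autoplot()`. `run_study()` reproduces a full study
end-to-end from a `study_config()` (or YAML via `read_study_config()` and
`inst/scripts/stagewalk-run.R`), writing every table as seed-stamped CSV.

## Worked example

A cohort with the default study composition and clearly separated stages in
the xy-plane:

```r
library(stagewalk)

cfg <- cohort_config(
  stage_shift = rbind(early = c(0, 0, 0), middle = c(10, 9, 0.1),
                      late = c(20, 18, 0.2)),
  gait_amplitude = rbind(early = c(1, 1, 0.3), middle = c(2, 2, 0.3),
                         late = c(3, 3, 0.3)),
  gait_freq_hz = c(early = 1, middle = 0.8, late = 0.6),
  duration_range = c(60, 180))
cohort <- generate_cohort(cfg, seed = 1)
cohort
#> <sw_cohort> 187 recordings, 35 patients (early: 41, middle: 100, late: 46)

curves <- interpolate_to_seconds(cohort)
l2 <- repeated_test(curves, axis = "x", test = "l2", n_reps = 50, seed = 2,
                    stages = c("early", "middle"), B = 199)
tidy(l2)
#> # A tibble: 1 × 7
#>   test  axis  comparison       mean    sd prop_le_05 n_reps
#> 1 l2    x     early vs middle 0.005     0          1     50
```

Every one of the 50 random windowings rejects H₀: μ_early = μ_middle on the
x-axis at the bootstrap floor p = 1/(B+1) = 0.005 — the stage effect is
detected regardless of the offset draw. The machine-learning track:

```r
feats <- extract_features(cohort)           # 187 × (3 + 90)
sp <- split_cohort(feats, test_fraction = 0.2, seed = 3)
sp
#> <sw_split> 28 training / 7 test patients

model <- train_nn(split_side(feats, sp, "train"), hidden = 30,
                  seed = 4, max_iter = 300)
classify_patients(model, split_side(feats, sp, "test"), method = "nn")
#> <sw_report> nn
#>   stage n misclassified success_rate
#>   early 1             0            1
#>  middle 3             0            1
#>    late 3             0            1
#>   total 7             0            1
```

All 7 held-out patients are staged correctly by majority vote over their
recordings. With weaker stage effects (the generator's defaults) the same
pipeline degrades gracefully toward the calibration/chance levels the tests
document.

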