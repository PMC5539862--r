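---
title: "Methods: functional tests and stage classifiers for smartphone accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional tests and stage classifiers for smartphone accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stagewalk` analyses free-movement smartphone-accelerometer cohorts of
Alzheimer's patients staged early / middle / late by the Global
Deterioration Scale grouping (GDS 2–3, 4–5, 6–7). This vignette is the
package's account of the models it implements, the choices that were
genuinely open, and what its synthetic experiments do and do not show.

## The data model

A recording is a three-axis acceleration curve $o_i(t) = (x_i(t), y_i(t),
z_i(t))$ in m/s², observed at irregular timestamps at a nominal 8 Hz, for a
duration chosen ad hoc by whoever switched the logger on and off. Three
features make such cohorts awkward: every recording lives on its own grid;
durations differ; and the device's orientation in the pocket — hence the
meaning of the axes — differs between recordings, even for one patient.

### The synthetic-cohort generator

No public dataset with this structure exists, so the generator is a
first-class part of the package. Its defaults reproduce the motivating
study's composition: 35 patients (7 early, 18 middle, 10 late), a fixed
per-patient schedule of 2–8 recordings totalling 187 (41/100/46 by stage),
durations uniform on 120–900 s, and timestamps on an 8 Hz grid with ±20%
uniform jitter. Each recording's signal per axis is

$$a(t) \;=\; g\,u + \delta_{\text{stage}} +
A_{\text{stage}} \sin(2\pi f_{\text{stage}} t + \varphi) + \varepsilon(t),$$

with $g = 9.81$ m/s² projected on a per-recording uniform-sphere
orientation $u$ (pocket placement varies per recording), a constant
per-stage per-axis mean shift $\delta$, a gait sinusoid with stage-dependent
amplitude and frequency and a uniform random phase $\varphi$ per recording,
and AR(1) noise ($\phi = 0.5$, $\sigma = 0.5$ m/s²).

Three modelling decisions deserve justification:

* **Stationarity is load-bearing.** The windowing argument below requires
  the within-recording process to be (strictly) stationary. A random-phase
  sinusoid is stationary; a fixed-phase one is not; and a stationary
  process has a constant mean, so the stage effect on the *mean* must be a
  constant shift $\delta_{\text{stage}}$, not a time-varying curve. The
  simplest model satisfying every assumption the analysis invokes won.
* **Stage effects live in the xy-plane.** Shifts and amplitudes separate
  stages strongly on x and y and weakly on z, because patients move in the
  horizontal plane. `stage_mean_functions()` exposes the noiseless means so
  this geometry is testable.
* **Gravity orientation is redrawn per recording**, not per patient,
  mimicking placement variability; it contributes a between-recording
  constant with per-axis standard deviation $\approx g/\sqrt{3} \approx
  5.7$ m/s², which is the dominant nuisance the classifiers must overcome.

Default effect sizes ($\delta_x$ = 0 / 0.6 / 1.2 m/s² for early / middle /
late, slightly smaller on y, an order of magnitude smaller on z) were
chosen once as "present but subtle relative to orientation noise" —
realistic for a gait effect. Experiments that need clear separability pass
larger shifts explicitly and say so.

What the generator does **not** emulate: gait pathology structure (stride
variability, cadence asymmetry), device clipping at the accelerometer's
±3.27 g range (never exercised by the analysis, so not implemented),
activity switching within a recording, and the device-computed Euclidean
norm channel (redundant, excluded from the analysis). Tests passing on
synthetic cohorts therefore certify the pipeline's statistical behaviour
under the stated model, not clinical performance on real patients.

## Preprocessing

`interpolate_to_seconds()` linearly interpolates each axis and records the
values at $t = 1, \dots, T_i$ with $T_i$ the rounded final timestamp.
Open points the package had to close:

* *Rounding rule* for $T_i$: round-half-to-even, documented and tested.
* *Edges*: a grid point before the first (or after the last) observation
  takes the nearest observed value (constant extrapolation). At 8 Hz the
  affected margin is at most ~an eighth of a second.
* Recordings shorter than 2 s are rejected as degenerate.

`random_windows()` makes the curves comparable: with $l = \min_i T_i$,
each curve contributes its values at $t = 1 + l_i, \dots, l + l_i$, with
$l_i$ uniform on $\{0, \dots, T_i - l\}$, independently per curve and per
repetition. Under stationarity the windowed datasets are exchangeable in
distribution, so no information is "thrown away" in expectation; the whole
analysis is repeated over $J$ draws (default 1000) and summarised. Seeds:
one master seed, with repetition $j$ on a derived stream, so increasing $J$
never perturbs earlier repetitions.

## The three equality-of-means tests

For stage groups $r, s, u$ on the common grid:

* **Random-projection ANOVA** (`anova_rp()`): $k = 30$ directions uniform
  on the unit sphere of $\mathbb{R}^l$ (normalised standard normal
  vectors); each projection gets the classical parametric one-way ANOVA F
  test (equal variances, df $(2, n-3)$); the $k$ p-values are combined by
  Bonferroni, $p = \min(1, k \min_j p_j)$, or by FDR, $p = \min_j
  p^{BH}_j$ (reject at $\alpha$ iff Benjamini–Hochberg rejects anything).
  The FDR combination is never larger than the Bonferroni one.
* **Bootstrap sup-F** (`anova_maxf()`): $T = \max_t F(r(t), s(t), u(t))$;
  the null distribution comes from resampling curves with replacement
  within each group and centering each bootstrap group at its original
  mean curve; $p = (1 + \#\{T^*_b \ge T\})/(B+1)$, $B = 999$. If the
  within-group variance vanishes at some grid point, a machine-epsilon
  scaled ridge is added to the denominator with a warning (degenerate
  synthetic inputs must not crash a 1000-repetition study); it is an error
  only if the variance vanishes everywhere.
* **Two-sample L2 test** (`l2_mean_test()`): $T = \int (\bar s - \bar u)^2$
  by the trapezoidal rule on the unit-spaced grid (for constant curves
  $T = (c_1 - c_2)^2 (l - 1)$, which the tests pin down), with the centered
  bootstrap statistic $T^*_b = \int (\bar s^*_b - \bar s - \bar u^*_b +
  \bar u)^2$. Applied pairwise to the three stages.

Bootstrap p-values live in $[1/(B+1), 1]$ by construction. The bootstrap
resamples **curves**, never time points — resampling time points would
destroy the within-curve dependence the statistics rely on.

A calibration caveat the test suite documents: with very small groups
(~10 curves) the naive centered bootstrap is visibly mis-calibrated (the
L2 test slightly anticonservative, roughly the $1 - 1/n$ bootstrap variance
factor; the sup-F test conservative). Calibration checks therefore run at
group sizes comparable to the study's 41/100/46 curves per group, where
both tests sit within two binomial standard errors of the nominal 5% level
over 200 null datasets.

`repeated_test()` wraps any of the tests over $J$ fresh windowings and
returns the mean, SD and proportion $\le 0.05$ of the p-values — the
summary-table row format — plus the raw p-values for histogramming
(`autoplot()`).

## The depth classifier

`hmode_depth()` implements the h-mode depth: the depth of a curve $f$ with
respect to a sample $\{x_i\}$ is $\frac{1}{m}\sum_i K(d(f, x_i)/h)$ with
$K$ the standard Gaussian kernel and $d$ the trapezoidal L2 distance. The
bandwidth $h$ is the 15th percentile of the within-group pairwise distances
— a common convention for mode depths; the choice is logged with the
report. `depth_transform()` computes the depth with respect to each stage
group, reducing every curve to a point in $\mathbb{R}^3$.

`nw_classify()` then estimates each stage's class-conditional density at a
depth vector by a Gaussian KDE (Euclidean norm, isotropic bandwidth by
Scott's rule $\bar\sigma\, n^{-1/7}$ in three dimensions) and predicts the
stage maximising density × empirical prior. Empirical rather than uniform
priors, because the groups are unbalanced by design. Ties — exact score
ties, curve-vote ties, repetition-vote ties — resolve toward the stage with
the largest training prevalence, then the fixed order early < middle <
late: deterministic and reproducible.

`lopo_evaluate()` holds out one patient at a time; for each of $J = 10$
windowing repetitions every held-out curve is classified against the other
34 patients; a patient's per-repetition label is the majority over their
curves and the final label the majority over repetitions. The held-out
patient's curves never enter the reference groups, the bandwidths, or the
KDE training set. For the "xyz" axis set, the three per-axis windows (one
shared offset) are concatenated into a single vector for the L2 distance —
the joint-depth alternative was the open question; concatenation was chosen
because it keeps one depth computation per group and one distance
structure.

## Feature extraction

`extract_features()` maps any recording to a fixed-width vector. For each
axis, per-second bins $(t-1, t]$, $t = 1, \dots, s_i$ with $s_i$ the
ceiling of the final timestamp (800.21 s → 801 bins), and per-minute bins
likewise ($\lceil 800.21/60 \rceil = 14$), carry the per-bin sum, median
and mean; each of those six series is summarised by sum, mean, median, min
and max. That is $3 \times 2 \times 3 \times 5 = 90$ features — matching
the network's 90 input neurons, which is the only unambiguous width anchor;
an alternative reading of the construction (90 features per axis) is
available as the opt-in `extended` mode, which additionally applies the
scheme to the speed and displacement curves obtained by cumulative
trapezoidal integration (270 features total). Bins left empty by sampling
jitter carry the previous bin forward (leading empties are backfilled);
at 8 Hz empty one-second bins are rare. Extraction is deterministic.

## Stage classifiers

`split_cohort()` assigns whole patients to training or test, targeting a
recording-level test fraction of ~20%: patients are shuffled, a prefix
whose recording count is closest to the target becomes the test side, and
seeds are retried deterministically until every stage appears in training.
With the default composition a 29-training / 6-test-patient split (the
studied shape) is attainable.

`train_nn()` is a feed-forward network with logistic activations trained by
resilient backpropagation with weight backtracking (rprop+; $\eta^+ = 1.2$,
$\eta^- = 0.5$, $\Delta_0 = 0.1$, $\Delta \in [10^{-6}, 50]$), full batch,
at most 1000 iterations, converged when the largest absolute gradient drops
below 0.01. The reference architecture is 90 inputs, one hidden layer of
175 neurons, and a **single output unit** with ordinal targets early = 0,
middle = 0.5, late = 1 and thresholds 0.25 / 0.75 — the simplest faithful
reading of a one-output three-class network; a three-unit softmax variant
is available via `encoding = "softmax"`. Features are z-scored with
training-side statistics stored in the model (constant features get unit
scale); logistic units need bounded inputs, and computing the statistics on
the training side only avoids leakage. A degenerate corner the tests pin
down: with all-constant features the ordinal output converges to the target
mean, i.e. the predicted class is the one nearest that mean — the majority
class under the study's unbalanced 7/18/10 composition.

`layer_sweep()` re-reads "eleven different layers" as hidden depth 1–11,
splitting ~175 hidden neurons across the layers (the alternative, width
sweeps, is reachable by passing explicit `hidden` layouts to `train_nn()`);
each setting trains `n_networks` networks from derived seeds and records
patient-level misclassification on the test side, boxplot-ready via
`autoplot()`.

`stage_baselines()` fits the three reference classifiers — `rpart` tree,
`randomForest`, `e1071` SVM — on the same standardised features with
ecosystem-default hyperparameters and reports patient-level majority-vote
performance in the same layout. (If every training feature is constant,
all three fall back to an explicit majority-class predictor; one of the
underlying fitters does not terminate on such input.) On full-scale
synthetic cohorts (35 patients, 187 recordings, xy-plane effects) the
network's patient-level accuracy exceeds all three baselines on average
over repeated splits — the suite asserts this at that scale; on much
smaller cohorts the ordering can invert, which the package does not claim
to rule out.

## Orchestration and reproducibility

`run_study()` executes the whole pipeline from a `study_config()` (or YAML
via `read_study_config()`): cohort files, repeated-test summary tables per
axis, the depth-classifier report, `features.csv`, the split table, the
network-vs-baselines report, the sweep table, and a JSON manifest. Every
CSV carries the master seed and a config hash; every stage derives its own
seed stream from the master seed, so reruns are bit-identical apart from
manifest timings. Problem sizes are fully configurable; the test suite
exercises the pipeline at smoke scale (a dozen patients, $J \le 5$,
$B \le 199$, small networks), and the package's own calibration studies use
200 null datasets with $B$ of 199–499 — sizes chosen so the whole suite
runs comfortably on a laptop while keeping every Monte Carlo band at two
binomial standard errors.

## Known limitations

* The generator's stationary-sinusoid gait model is deliberately minimal;
  it supports the analysis' assumptions but cannot stand in for real
  pathological gait.
* The centered bootstrap's small-sample miscalibration (above) is a
  property of the prescribed procedure, not corrected here.
* The h-mode depth bandwidth and the KDE bandwidth follow fixed
  conventions (15th-percentile distances; Scott's rule); neither is tuned.
* Interpolation to a 1 Hz grid discards sub-second gait detail by design;
  frequency-domain features are out of scope.
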