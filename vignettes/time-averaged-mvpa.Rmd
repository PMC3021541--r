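---
title: "Predicting individual outcomes from time-averaged voxel patterns"
author: "mvpasvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individual outcomes from time-averaged voxel patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpasvr)
```

## The analysis this package implements

Individual differences in how much people improve with training can be
predicted from brain structure and persistent physiology. One signal that
carries such information is the *time-averaged* T2\*-weighted EPI image:
instead of contrasting task conditions (as functional MRI does), all EPI
volumes acquired during a session are intensity-normalized and averaged
over time, yielding one stable T2\* volume per subject. Multi-voxel
pattern analysis (MVPA) then treats every voxel inside an anatomical
region of interest (ROI) — in the motivating application, the dorsal
striatum — as a feature, and learns a linear map from the
subjects-by-voxels feature matrix to a behavioural outcome such as the
improvement in a video-game score between two scanning sessions.

The pipeline has five stages, each exposed as package functions:

1. **Cohort generation** (`generate_cohort()`): synthetic subjects with a
   known ground-truth pattern signal, because the original raw data are
   not deposited anywhere.
2. **Preprocessing** (`normalize_volume()`, `temporal_average()`,
   `extract_features()`, `consensus_segmentation()`,
   `split_roi_coronal()`, `subsample_volume()`).
3. **Support vector regression** (`fit_svr()`, `predict()`): a linear
   ε-insensitive SVR written from the primal/dual formulation.
4. **Leave-one-subject-out cross-validation** (`loso_predict()`,
   `run_roi_battery()`) plus the spatial-mean baseline, median-split
   group tests and good-minus-poor difference maps.
5. **Correlation inference** (`pearson_r()`, `fisher_z()`,
   `compare_correlations()`, `partial_correlation()`,
   `relative_improvement()`).

## The regression model

Given training pairs $(x_i, y_i)$, $x_i \in \mathbb{R}^d$ (ROI voxel
intensities) and $y_i \in \mathbb{R}$ (score improvement), ε-SVR finds
the flattest linear function $f(x) = w \cdot x + b$ whose training
errors beyond an insensitivity half-width $\varepsilon$ are penalized
linearly:

$$
\min_{w, b, \xi, \xi^*} \; \tfrac12 \lVert w \rVert^2 +
C \sum_i (\xi_i + \xi_i^*)
\quad \text{s.t.} \quad
\begin{aligned}
y_i - w \cdot x_i - b &\le \varepsilon + \xi_i \\
w \cdot x_i + b - y_i &\le \varepsilon + \xi_i^* \\
\xi_i, \xi_i^* &\ge 0.
\end{aligned}
$$

The solver works on the dual, with multipliers
$0 \le \alpha_i, \alpha_i^* \le C$ and the equality constraint
$\sum_i (\alpha_i - \alpha_i^*) = 0$, from which
$w = \sum_i (\alpha_i - \alpha_i^*) x_i$. Internally the package
optimizes the signed variables $\beta_i = \alpha_i - \alpha_i^*$
(box $[-C, C]$), which enforces $\alpha_i \alpha_i^* = 0$ exactly,
and recovers $\alpha = \beta^+$, $\alpha^* = \beta^-$.

### Numerical choices in the solver

* **Working-set strategy.** Pairwise (SMO-style) ascent on the
  maximal-KKT-violating pair: every sample bounds the feasible bias from
  below ($L_i$) or above ($U_i$) depending on which side of the tube it
  sits; the pair (argmax $L$, argmin $U$) is updated until
  $\max L - \min U \le$ `kkt_tol`. Ties resolve to the lowest index.
* **Exact two-variable subproblem.** Along the constraint the objective
  is a convex piecewise quadratic in the step $\delta$ (breakpoints where
  $\beta_i$ or $\beta_j$ crosses zero). The minimizer is found by walking
  the segment slopes rather than by evaluating the objective, because
  slope comparisons stay accurate at step sizes of order `kkt_tol`
  where objective differences cancel in double precision. The inner loop
  is compiled (C++), as is usual for SVM solvers in R.
* **Bias recovery.** Averaged over free support vectors
  ($0 < \alpha_i < C \Rightarrow b = y_i - w\cdot x_i - \varepsilon$,
  and with $+\varepsilon$ for starred ones); when no free support vector
  exists, the midpoint of the KKT-feasible interval
  $[\max L, \min U]$.
* **Defaults.** `kkt_tol = 1e-6` (in target units), `max_iter = 1e5`
  pair updates, `C = 1`, and a scale-aware `epsilon = NULL` meaning
  $0.1 \cdot \mathrm{SD}(y)$ of the training fold. C is scale-dependent:
  for targets in the hundreds (game points) the cohort analyses in this
  package use `C = 1000`. Exceeding `max_iter` is an error that reports
  the achieved violation; with strongly rank-deficient Gram matrices
  (very few voxels, huge C, pure-noise targets) the pairwise method can
  legitimately hit this.
* **No per-feature standardization** by default: inputs are already
  globally intensity-normalized volumes, and fold-internal
  standardization is available via `svr_config(standardize = TRUE)`.

## Cross-validated prediction and its statistics

`loso_predict()` trains on $n-1$ subjects and predicts the held-out one,
repeating so that each subject is excluded exactly once; accuracy is the
Pearson correlation between the pooled predicted and measured outcomes,
computed once over all subjects (not per fold). The correlation’s
significance uses the exact-under-normality t test
($t = r\sqrt{n-2}/\sqrt{1-r^2}$); the Fisher-z normal test is available
via `pearson_r(..., method = "fisher")`. The t route was chosen as the
default because it reproduces the magnitude of published p values for
correlations of this size; the published description ("Fisher transform,
then t tests") does not pin down the degrees of freedom.

Differences between ROI correlations use the classical independent-sample
Fisher-z comparison
$Z = (z_1 - z_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}$. When both
correlations come from the same subjects this independence is an
approximation; results carry `assumption = "independent samples"` to
keep that visible rather than silently applying a dependent-correlation
correction the original analysis did not use.

`partial_correlation()` residualizes target and predictor on up to two
covariates by least squares and correlates the residuals with
$df = n - 2 - k$ ("second order" at $k = 2$), assessing e.g. whether
SVR predictions retain unique predictive power once ROI volume and
initial score are controlled. Pearson residualization is assumed; a
rank-based variant is deliberately out of scope.

`relative_improvement()` implements the percentile-rank construction for
scores whose raw scale admits negative values: session-1 scores become
Hazen percentile ranks $100(\mathrm{rank}-0.5)/n$ (average ranks on
ties), session-2 scores become $100\,\Phi((s_2-\bar s_1)/\mathrm{sd}(s_1))$,
and the relative improvement is $(R_2 - R_1)/R_1$. The Hazen convention
and average-rank tie handling are fixed choices documented here because
the construction is otherwise underdetermined.

## What the synthetic cohorts emulate

Real inputs would be per-subject 4D EPI series registered to a common
grid. `generate_cohort()` emulates exactly the statistical structure the
analysis assumes, with known ground truth:

* a 13-block acquisition (PW-OB-PW-SF-PW-SO-PW-SO-PW-SF-PW-OB-PW; 46-s
  passive blocks, 4-minute active blocks, TR 2 s — 480 active SF/SO
  volumes at full scale; `default_block_schedule()`), usually shortened
  per block for simulation studies (`toy_block_schedule()`);
* voxel intensity
  $\text{baseline} + g\,y_s\,[\text{in ROI}] + \gamma\,y_s m_v +
  \zeta_{sv} + \eta_{svt}$ inside an ellipsoidal brain mask, where $m$
  is a fixed zero-mean unit-RMS weight map on the signal subregion,
  $\zeta$ is per-subject spatial noise (constant over time) and $\eta$
  is fresh temporal noise;
* a two-box left/right ROI with an anterior/posterior subdivision, the
  signal confined by default to the anterior half of the left box
  (mirroring the laterality and anterior/posterior findings the analysis
  is designed to detect);
* tissue partial-volume maps built from a common template (clear white
  matter and gray matter inside the ROI, a CSF pocket above it,
  sub-threshold mixed tissue elsewhere) jittered per subject, so
  consensus segmentation produces all four outcomes (WM, GM, CSF,
  unassigned);
* total scores split into four sub-scores (control, velocity, speed,
  points) that sum exactly to the session totals, and two covariates
  (ROI volume, initial score) independent of the true improvement by
  default, with configuration switches to induce correlation.

### Default magnitudes and why

The defaults were fixed once, from a design analysis, before the test
suite was run, and are the package's definition of "study conditions":

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 34 | cohort size of the motivating study |
| `grid_shape`, `voxel_size` | 16×16×12 at 3.4375×3.4375×4 mm | EPI resolution at toy grid scale |
| `baseline` | 1000 a.u. | scanner-like intensity scale |
| `score_mean`, `score_sd` | 500, 200 points | plausible improvement spread; scale is arbitrary but fixed |
| `noise_sd_temporal` | 200 a.u. | ~20% per-volume noise; after averaging 32 active volumes contributes ~3.5% |
| `noise_sd_spatial` | 100 a.u. | 10% stable anatomical variability; dominates the averaged noise (~10.6% total) |
| `signal_gain` | 0.3 a.u./point | aggregate pattern SNR ≈ 4.5 over the 64-voxel signal region: strong but not noise-free recovery |
| `global_gain` | 0.017 a.u./point | calibrated so the spatial-mean correlation sits near 0.5, the qualitative regime where pattern analysis clearly outperforms the mean |

The weight map is centered to zero mean so the pattern signal is
invisible to the spatial-mean analysis by construction, and the global
component is uniform over the ROI so the two information channels are
cleanly separable.

The generator does **not** emulate BOLD hemodynamics, motion, slice
timing, field inhomogeneity, registration error, spatial autocorrelation
of noise, or non-Gaussian score distributions. Passing tests on these
cohorts therefore demonstrate correctness of the *computations* under
the stated generative model, not robustness of the method on real
scanner data.

## Conventions and tie-breaks

* Voxel indices are 1-based (R convention) with axis order (x, y, z),
  +x left-to-right and +y anterior. (A language-neutral description of
  the same conventions would use 0-based indices; only the base differs.)
* Per-volume normalization divides by the in-brain mean *before*
  temporal averaging; averaging first is not equivalent and is not
  offered. The brain mask is an explicit input.
* The coronal split minimizes the anterior/posterior count difference;
  ties go to the smaller anterior count. An ROI occupying a single
  coronal slice cannot be split and errors.
* Consensus segmentation uses a strict > 50% rule on the averaged
  fractions; voxels where no tissue passes are labeled UNASSIGNED and
  flagged for exclusion.
* Median splits assign subjects tied exactly at the median alternately
  in ascending subject id, each tie to the currently smaller group. The
  group t test uses pooled variance by default (group sizes are equal by
  construction); Welch is a flag.
* Downsampling to a coarser grid uses exact block averaging (means over
  nested blocks), which preserves volume means on nested grids;
  interpolation variants are not offered.

## Problem sizes used by the test and acceptance suites

Simulation-heavy properties run on reduced cohorts chosen as the
package's own trade-off between statistical resolution and runtime: a
10×10×8 grid with 2 passive / 5 active timepoints per block (the
pattern-signal gain rescaled to 0.6 to keep the aggregate SNR at the
default ≈4.5), 34 subjects unless a smaller cohort suffices. The
parameter-recovery and null-calibration suites use the full default
16×16×12 configuration at 50 and 200 seeds respectively; the solver
oracle suite compares 50 random small instances (n ≤ 12, d ≤ 6) against
an interior-point QP solver and libsvm.

## Known limitations

* **Parametric inference on cross-validated correlations is
  anticonservative.** Leave-one-subject-out predictions are not
  independent of the held-out scores under the null: every fold's
  weights and bias are refit on the remaining subjects, which couples
  the prediction negatively to the held-out target, and all folds share
  training data, which correlates predictions across subjects. The
  package's null-calibration suite measures the consequence directly:
  on no-signal cohorts the nominal 5% test on the LOSO correlation
  rejects far more often than 5% (and the null correlation is biased
  negative, increasingly so as the voxel count grows). This is a
  property of the analysis design itself — it equally affects any study
  that reports parametric p values for CV prediction correlations — and
  no generator setting was found (or should be sought) that hides it.
  Permutation-based inference would fix it but is deliberately out of
  scope here, matching the original parametric analysis.
* The independent-samples Fisher-z comparison between overlapping-ROI
  correlations ignores their dependence (flagged in the output).
* The solver targets dense, small-n problems (cohort sizes); it is not
  tuned for thousands of samples.
* Registration, motion correction and atlas-based anatomical
  delineation are out of scope; synthetic cohorts are generated directly
  in a common grid.
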