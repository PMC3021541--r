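# mvpasvr

Multi-voxel pattern analysis (MVPA) of **time-averaged T2\*-weighted MRI
signal** for predicting per-subject behavioural outcomes — e.g. how much
a person's score in a demanding video game will improve after training,
predicted from a single pre-training scanning session.

Instead of contrasting task conditions the way functional MRI does, the
analysis normalizes every EPI volume by its in-brain mean, averages the
normalized volumes over the active task blocks, and uses *all voxels of
an anatomical ROI* of that time-averaged volume as features
`x_i ∈ R^d`. A linear ε-insensitive support vector regression (SVR)

```
f(x) = w·x + b,   minimize  ½‖w‖² + C Σ(ξᵢ + ξᵢ*)
subject to        |yᵢ − f(xᵢ)| ≤ ε + slack
```

is trained in leave-one-subject-out (LOSO) cross-validation: each
subject is predicted by a model fit on all the others, and accuracy is
the Pearson correlation r between pooled predicted and measured
outcomes (with Fisher-z based inference, correlation comparisons across
ROIs, second-order partial correlations against covariates, median-split
group tests, and a spatial-mean baseline). The SVR dual is solved by a
from-scratch pairwise working-set ascent (maximal KKT-violating pair,
compiled inner loop); independent QP and libsvm solvers are used only as
test oracles.

Because the motivating study's raw data are not publicly deposited, the
package ships a first-class **synthetic cohort generator** with known
ground truth — per-subject 4D series on a common grid, a linear voxel
pattern signal confined to a configurable subregion, a weaker
spatial-mean component, tissue partial-volume maps for consensus
segmentation, behavioural scores with sub-scores, and independent
covariates — so every stage of the pipeline is testable with
parameter-recovery, leakage, and calibration experiments.

## Worked example

```r
library(mvpasvr)

cohort <- cohort_config(seed = 1)        # 34 subjects, default study scale
dat <- generate_cohort(cohort)

volumes <- lapply(dat$subjects, temporal_average,
                  include_blocks = c("SF", "SO"),   # active game-play blocks
                  brain_mask = dat$brain_mask)
y <- dat$scores$score_improvement

feats <- extract_features(volumes, dat$rois$dorsal)
cv <- loso_predict(feats, y, svr_config(C = 1000))
cv
#> LOSO prediction over 34 subjects (ROI: dorsal)
#> Pearson correlation: r = 0.9741 (n = 34)
#>   Fisher z = 2.1669; t = 24.3718 (df = 32); two-tailed p = 3.12e-22

sm <- spatial_mean_analysis(volumes, dat$rois$dorsal, y)
sm$correlation
#> Pearson correlation: r = 0.5688 (n = 34)
#>   Fisher z = 0.6457; t = 3.9121 (df = 32); two-tailed p = 0.000448

round(r_squared(c(cv$correlation$r, sm$correlation$r)), 2)
#> [1] 0.95 0.32

cmp <- compare_correlations(cv$correlation$r, 34, sm$correlation$r, 34)
round(cmp$stat, 2); signif(cmp$p, 2)
#> [1] 5.99
#> [1] 2.1e-09
```

Reading the output: the voxel-pattern model recovers the generator's
embedded signal almost perfectly (r = 0.97, i.e. ~95% of the variance in
simulated score improvements), while the spatial-mean baseline — which
only sees the ROI's average intensity — reaches r ≈ 0.57 (~32%), and the
Fisher-z comparison shows the pattern analysis is significantly more
accurate. Splitting the left ROI with `split_roi_coronal()` localizes
the accuracy to the anterior half, where the generator placed the
signal; `run_roi_battery()` repeats the analysis over ROIs × scores and
`partial_correlation()` confirms predictions keep their predictive power
after controlling for ROI volume and initial score.

A command-line wrapper over the same functions is installed at
`inst/scripts/mvpa-pipeline.R` with subcommands `simulate`,
`preprocess`, `predict`, `report`, and `run-all`.

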