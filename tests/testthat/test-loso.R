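test_that("LOSO produces one prediction per subject from n-1 training folds", {
  dat <- generate_cohort(test_cohort_config(n_subjects = 12, seed = 201))
  feats <- extract_features(average_cohort(dat), dat$rois$left)
  cv <- loso_predict(feats, dat$scores$score_improvement, test_svr_config())
  expect_equal(nrow(cv$predictions), 12L)
  expect_equal(cv$fold_sizes, rep(11L, 12))
  expect_equal(cv$predictions$subject_id, dat$scores$subject_id)
  expect_identical(cv$roi_name, "left")
  expect_s3_class(cv$correlation, "correlation_result")
})

test_that("no subject's target can influence their own prediction", {
  dat <- generate_cohort(test_cohort_config(n_subjects = 10, seed = 202))
  feats <- extract_features(average_cohort(dat), dat$rois$left)
  y <- dat$scores$score_improvement
  cfg <- test_svr_config()
  base <- loso_predict(feats, y, cfg)$predictions$y_predicted
  for (s in c(1, 4, 10)) {
    y2 <- y
    y2[s] <- y2[s] + 750
    pert <- loso_predict(feats, y2, cfg)$predictions$y_predicted
    expect_identical(pert[s], base[s])
  }
})

test_that("a strong noise-free linear signal is recovered almost perfectly", {
  cfg <- test_cohort_config(n_subjects = 12, noise_sd_temporal = 0,
                            noise_sd_spatial = 0, global_gain = 0,
                            seed = 203)
  dat <- generate_cohort(cfg)
  feats <- extract_features(average_cohort(dat), dat$rois$left)
  cv <- loso_predict(feats, dat$scores$score_improvement, test_svr_config())
  expect_gt(cv$correlation$r, 0.99)
  expect_equal(cv$predictions$y_predicted, cv$predictions$y_measured,
               tolerance = 0.15)
})

test_that("spatial-mean analysis reduces to ROI means and flags degeneracy", {
  dims <- c(4, 4, 4)
  m <- array(FALSE, dims); m[2, 2, 2] <- TRUE
  roi <- mask3(m, name = "one")
  vols <- list(a = vol3(array(1:64, dims)), b = vol3(array(2 * (1:64), dims)),
               c = vol3(array(64:1, dims)), d = vol3(array(rep(3, 64), dims)))
  out <- spatial_mean_analysis(vols, roi, c(1, 2, 3, 4))
  expect_equal(unname(out$means),
               sapply(vols, function(v) v$data[2, 2, 2]),
               ignore_attr = TRUE)

  same <- list(a = vols$a, b = vols$a, c = vols$a, d = vols$a)
  degen <- spatial_mean_analysis(same, roi, c(1, 2, 3, 4))
  expect_null(degen$correlation)
  expect_match(degen$degenerate, "undefined")
})

test_that("a pure spatial-mean signal is detected by the baseline analysis", {
  cfg <- test_cohort_config(signal_gain = 0, global_gain = 0.05, seed = 204)
  dat <- generate_cohort(cfg)
  sm <- spatial_mean_analysis(average_cohort(dat), dat$rois$dorsal,
                              dat$scores$score_improvement)
  expect_gt(sm$correlation$r, 0.5)
  expect_lt(sm$correlation$p, 0.01)
})

test_that("median split groups and pooled t test match hand computation", {
  # scores 1..4 -> groups {1,2} vs {3,4}; values give mean difference 10
  res <- median_split_compare(c(10, 10, 20, 20), c(1, 2, 3, 4))
  expect_equal(unname(res$n), c(2L, 2L))
  expect_equal(unname(res$means["good"] - res$means["poor"]), 10)
  expect_equal(res$p, 0)                       # zero within-group variance

  set.seed(205)
  scores <- sample(100, 34)                    # distinct: clean 17/17
  grp <- median_split(scores)
  expect_equal(as.vector(table(grp)), c(17L, 17L))

  vals <- rnorm(34)
  res2 <- median_split_compare(vals, scores)
  ht <- t.test(vals[grp == "good"], vals[grp == "poor"], var.equal = TRUE)
  expect_equal(res2$t, unname(ht$statistic))
  expect_equal(res2$p, ht$p.value)

  same <- median_split_compare(rep(2, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(median_split(rep(1, 8)), "all scores are equal")
})

test_that("median-split ties are assigned alternately and deterministically", {
  scores <- c(1, 5, 5, 9, 5, 2)       # three subjects tied at the median 5
  grp <- median_split(scores, subject_id = c("a", "b", "c", "d", "e", "f"))
  expect_equal(sum(grp == "good"), 3)
  expect_equal(sum(grp == "poor"), 3)
  # ties b, c, e in id order fill the smaller group first: with 2 poor and
  # 1 good already fixed, the alternation runs good, poor, good
  expect_equal(as.character(grp[c(2, 3, 5)]), c("good", "poor", "good"))
  expect_identical(grp, median_split(scores, c("a", "b", "c", "d", "e", "f")))
})

test_that("difference patterns are centered, ROI-bounded, and signal-localized", {
  dims <- c(4, 6, 4)
  m <- array(FALSE, dims); m[2:3, 2:5, 2:3] <- TRUE
  roi <- mask3(m, name = "box")
  base <- array(100, dims)
  mk <- function(bump) {
    v <- base
    v[2, 5, 2] <- v[2, 5, 2] + bump     # anterior voxel
    vol3(v)
  }
  vols <- list(a = mk(0), b = mk(0), c = mk(8), d = mk(8))
  dp <- difference_pattern(vols, roi, scores = c(1, 2, 3, 4))
  expect_true(all(dp$data[!m] == 0))
  # each centered pattern has zero in-ROI mean, so the map does too
  expect_equal(mean(dp$data[m]), 0, tolerance = 1e-12)
  # magnitude concentrates on the manipulated anterior voxel (2, 5, 2)
  expect_equal(which.max(abs(dp$data)), 2L + (5L - 1L) * 4L + (2L - 1L) * 24L)

  # identical groups give the zero map
  vols0 <- list(a = mk(3), b = mk(3), c = mk(3), d = mk(3))
  dp0 <- difference_pattern(vols0, roi, scores = c(1, 2, 3, 4))
  expect_equal(max(abs(dp0$data)), 0)
})

test_that("the ROI battery emits one row per ROI-score pair plus comparisons", {
  dat <- generate_cohort(test_cohort_config(n_subjects = 10, seed = 206))
  vols <- average_cohort(dat)
  battery <- run_roi_battery(
    vols, dat$rois[c("left", "right")], dat$scores,
    score_columns = c("score_improvement", "speed_s1"),
    config = test_svr_config(),
    comparisons = list(c("left", "right")))
  expect_equal(nrow(battery$results), 4L)
  expect_setequal(battery$results$roi, c("left", "right"))
  expect_equal(nrow(battery$comparisons), 2L)

  # the same ROI under two names gives identical correlations and p = 1
  twice <- run_roi_battery(
    vols, list(one = dat$rois$left, two = dat$rois$left), dat$scores,
    score_columns = "score_improvement", config = test_svr_config(),
    comparisons = list(c("one", "two")))
  expect_equal(twice$results$r[1], twice$results$r[2])
  expect_equal(twice$comparisons$p, 1)
})

test_that("a left-lateralized signal yields higher left than right accuracy", {
  set.seed(207)
  wins <- 0L
  sig <- 0L
  nseeds <- 60
  for (s in seq_len(nseeds)) {
    dat <- generate_cohort(test_cohort_config(seed = 5000 + s))
    vols <- average_cohort(dat)
    battery <- run_roi_battery(
      vols, dat$rois[c("left", "right")], dat$scores,
      score_columns = "score_improvement", config = test_svr_config(),
      comparisons = list(c("left", "right")))
    rs <- battery$results
    wins <- wins + (rs$r[rs$roi == "left"] > rs$r[rs$roi == "right"])
    sig <- sig + (battery$comparisons$p < 0.05)
  }
  expect_gt(wins / nseeds, 0.9)
  expect_gt(sig / nseeds, 0.6)    # comparison rejects in most seeds
})
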