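# Leave-one-subject-out prediction and the surrounding group analyses:
# spatial-mean baseline, median-split comparison, good-minus-poor
# difference patterns, and the multi-ROI / multi-score battery.

#' Leave-one-subject-out SVR prediction
#'
#' For each subject s, a linear epsilon-SVR is trained on the feature
#' rows and targets of all other subjects and then predicts subject s
#' from their own features, so no subject ever contributes to their own
#' prediction. Accuracy is summarized once, as the Pearson correlation
#' between the pooled predicted and measured targets over all subjects.
#'
#' @param features A subjects-by-voxels matrix (see [extract_features()]).
#' @param scores Numeric target vector aligned with the rows of
#'   `features` (e.g. score improvements).
#' @param config An [svr_config()]. When `epsilon` is `NULL` it is
#'   resolved per training fold as 0.1 * SD of that fold's targets.
#' @return A `cv_prediction`: data frame `predictions` (`subject_id`,
#'   `y_measured`, `y_predicted`), `correlation`
#'   (a [pearson_r()] result), `fold_sizes`, and `roi_name`.
#' @export
loso_predict <- function(features, scores, config = svr_config()) {
  X <- unclass(features)
  if (is.null(dim(X))) stop("features must be a matrix")
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects for LOSO prediction")
  scores <- as.numeric(scores)
  if (length(scores) != n) stop("scores must align with feature rows")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("subject%02d", seq_len(n))

  preds <- numeric(n)
  for (s in seq_len(n)) {
    fit <- tryCatch(
      fit_svr(X[-s, , drop = FALSE], scores[-s], config),
      error = function(e) {
        stop(sprintf("SVR fit failed in LOSO fold for subject '%s': %s",
                     ids[s], conditionMessage(e)), call. = FALSE)
      })
    preds[s] <- predict(fit, X[s, , drop = FALSE])
  }

  structure(list(
    predictions = data.frame(subject_id = ids,
                             y_measured = scores,
                             y_predicted = preds),
    correlation = pearson_r(preds, scores),
    fold_sizes = rep(n - 1L, n),
    roi_name = attr(features, "roi_name")
  ), class = "cv_prediction")
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat(sprintf("LOSO prediction over %d subjects%s\n",
              nrow(x$predictions),
              if (is.null(x$roi_name)) "" else paste0(" (ROI: ", x$roi_name, ")")))
  print(x$correlation)
  invisible(x)
}

#' Spatial-mean baseline analysis
#'
#' Averages the intensity of all voxels inside the ROI per subject and
#' correlates those means with the targets -- the summary-statistic
#' baseline that pattern analysis is compared against. If the per-subject
#' means are constant the correlation is undefined and reported as such
#' (`correlation = NULL` with a `degenerate` note) rather than an error.
#'
#' @param volumes Named list of [brain_volume()]s, one per subject.
#' @param roi An [roi_mask()] on the same grid.
#' @param scores Numeric target vector aligned with `volumes`.
#' @return List with `means` (named per-subject in-ROI means) and
#'   `correlation` ([pearson_r()] result or `NULL` if degenerate).
#' @export
spatial_mean_analysis <- function(volumes, roi, scores) {
  stopifnot(inherits(roi, "roi_mask"))
  feats <- extract_features(volumes, roi)
  means <- rowMeans(feats)
  scores <- as.numeric(scores)
  if (length(scores) != length(means)) {
    stop("scores must align with the subject volumes")
  }
  if (stats::sd(means) == 0 || stats::sd(scores) == 0) {
    return(list(means = means, correlation = NULL,
                degenerate = "zero variance: correlation undefined"))
  }
  list(means = means, correlation = pearson_r(means, scores))
}

#' Median split of subjects into good and poor learners
#'
#' Subjects scoring above the median go to the `good` group, below to
#' `poor`. For even n the median is the midpoint of the two central
#' order statistics. Subjects tied exactly at the median are assigned
#' alternately in ascending `subject_id` order, each tie going to the
#' currently smaller group (poor on a standing tie), keeping the groups
#' as balanced as possible and the assignment deterministic.
#'
#' @param scores Numeric vector of score improvements.
#' @param subject_id Optional ids used for deterministic tie assignment.
#' @return Factor with levels `poor`, `good`, one per subject.
#' @export
median_split <- function(scores, subject_id = NULL) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 4L) stop("need at least 4 subjects for a median split")
  if (length(unique(scores)) == 1L) {
    stop("median split impossible: all scores are equal")
  }
  if (is.null(subject_id)) subject_id <- seq_len(n)
  med <- stats::median(scores)
  grp <- rep(NA_character_, n)
  grp[scores > med] <- "good"
  grp[scores < med] <- "poor"
  ties <- which(scores == med)
  if (length(ties)) {
    ties <- ties[order(subject_id[ties])]
    # alternate starting with whichever group is currently smaller
    # (poor first on a tie) to balance group sizes
    for (i in seq_along(ties)) {
      n_poor <- sum(grp == "poor", na.rm = TRUE)
      n_good <- sum(grp == "good", na.rm = TRUE)
      grp[ties[i]] <- if (n_good < n_poor) "good" else "poor"
    }
  }
  factor(grp, levels = c("poor", "good"))
}

#' Compare a per-subject measure between good and poor learners
#'
#' Splits subjects by the median of their score improvements (see
#' [median_split()]) and runs a two-sample t test on `values` between the
#' groups -- pooled variance by default since the split keeps group sizes
#' (nearly) equal; Welch's correction available via `var_equal = FALSE`.
#'
#' @param values Per-subject values to compare (e.g. mean ROI intensity).
#' @param scores Score improvements defining the split.
#' @param subject_id Optional ids for deterministic tie handling.
#' @param var_equal Use the pooled-variance t test (default `TRUE`).
#' @return List with `group` (the split), per-group `n` and `means`,
#'   `t`, `df`, `p`.
#' @export
median_split_compare <- function(values, scores, subject_id = NULL,
                                 var_equal = TRUE) {
  values <- as.numeric(values)
  scores <- as.numeric(scores)
  if (length(values) != length(scores)) {
    stop("values and scores must have equal length")
  }
  grp <- median_split(scores, subject_id)
  good <- values[grp == "good"]
  poor <- values[grp == "poor"]
  if (stats::sd(values) == 0) {
    # identical values in every subject: no group difference by definition
    return(list(group = grp, n = c(poor = length(poor), good = length(good)),
                means = c(poor = mean(poor), good = mean(good)),
                t = 0, df = length(values) - 2L, p = 1))
  }
  ht <- tryCatch(
    stats::t.test(good, poor, var.equal = var_equal),
    error = function(e) {
      # both groups internally constant: zero pooled variance, so the
      # statistic degenerates to +/-Inf for unequal means
      d <- mean(good) - mean(poor)
      list(statistic = c(t = sign(d) * Inf),
           parameter = c(df = length(values) - 2),
           p.value = if (d == 0) 1 else 0)
    })
  list(group = grp,
       n = c(poor = length(poor), good = length(good)),
       means = c(poor = mean(poor), good = mean(good)),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Good-minus-poor difference pattern within an ROI
#'
#' Subtracts each subject's mean in-ROI intensity from their in-ROI
#' voxels (so only the pattern, not the level, remains), averages the
#' centered patterns within the good and the poor group of a median
#' split, and returns the good-minus-poor map, zero outside the ROI.
#'
#' @param volumes Named list of [brain_volume()]s, one per subject.
#' @param roi An [roi_mask()].
#' @param scores Score improvements defining the split.
#' @return A `difference_pattern`: list with `data` (3D map), `roi_name`,
#'   and the `group` assignment.
#' @export
difference_pattern <- function(volumes, roi, scores) {
  feats <- extract_features(volumes, roi)
  grp <- median_split(scores, rownames(feats))
  if (sum(grp == "good") < 2L || sum(grp == "poor") < 2L) {
    stop("need at least 2 subjects per group for a difference pattern")
  }
  centered <- feats - rowMeans(feats)
  diff_vec <- colMeans(centered[grp == "good", , drop = FALSE]) -
    colMeans(centered[grp == "poor", , drop = FALSE])
  map <- array(0, dim = dim(roi$data))
  map[which(roi$data)] <- diff_vec
  structure(list(data = map, roi_name = roi$name, group = grp),
            class = "difference_pattern")
}

#' Run the LOSO analysis over a battery of ROIs and score columns
#'
#' For every combination of ROI and score column, extracts features,
#' runs [loso_predict()], and collects the prediction correlation; then
#' compares the requested ROI pairs per score column with
#' [compare_correlations()].
#'
#' @param volumes Named list of per-subject [brain_volume()]s.
#' @param rois Named list of [roi_mask()]s.
#' @param scores_table Data frame with one row per subject containing the
#'   score columns.
#' @param score_columns Character vector of columns of `scores_table` to
#'   predict.
#' @param config An [svr_config()].
#' @param comparisons List of length-2 character vectors naming ROI pairs
#'   to compare (e.g. `list(c("left", "right"))`).
#' @return List of two data frames: `results` (roi, score, n, r,
#'   z_fisher, stat, p) and `comparisons` (roi1, roi2, score, stat, p).
#' @export
run_roi_battery <- function(volumes, rois, scores_table, score_columns,
                            config = svr_config(),
                            comparisons = list()) {
  stopifnot(length(rois) >= 1L, all(score_columns %in% names(scores_table)))
  feats <- lapply(rois, function(roi) extract_features(volumes, roi))
  grid <- expand.grid(roi = names(rois), score = score_columns,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cv <- loso_predict(feats[[grid$roi[k]]],
                       scores_table[[grid$score[k]]], config)
    fits[[k]] <- cv
    cr <- cv$correlation
    rows[[k]] <- data.frame(roi = grid$roi[k], score = grid$score[k],
                            n = cr$n, r = cr$r, z_fisher = cr$z_fisher,
                            stat = cr$stat, p = cr$p)
  }
  results <- do.call(rbind, rows)
  comp_rows <- list()
  for (pair in comparisons) {
    stopifnot(length(pair) == 2L, all(pair %in% names(rois)))
    for (sc in score_columns) {
      r1 <- results[results$roi == pair[1] & results$score == sc, ]
      r2 <- results[results$roi == pair[2] & results$score == sc, ]
      cmp <- compare_correlations(r1$r, r1$n, r2$r, r2$n)
      comp_rows[[length(comp_rows) + 1L]] <-
        data.frame(roi1 = pair[1], roi2 = pair[2], score = sc,
                   r1 = r1$r, r2 = r2$r, stat = cmp$stat, p = cmp$p,
                   assumption = cmp$assumption)
    }
  }
  comparisons_df <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(roi1 = character(), roi2 = character(), score = character(),
               r1 = numeric(), r2 = numeric(), stat = numeric(),
               p = numeric(), assumption = character())
  structure(list(results = results, comparisons = comparisons_df),
            class = "roi_battery")
}
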