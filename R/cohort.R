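# Synthetic cohort generation: per-subject 4D T2*-like series on a
# common grid with a known linear voxel-pattern signal, a weaker
# spatial-mean component, tissue partial-volume maps, behavioural scores
# with sub-scores, and covariates -- everything the downstream analysis
# assumes, with ground truth retained for parameter-recovery tests.

#' Block schedule of the emulated acquisition
#'
#' Thirteen blocks in the order PW-OB-PW-SF-PW-SO-PW-SO-PW-SF-PW-OB-PW:
#' seven 46-second passive-watching (PW) blocks interleaved with six
#' 4-minute active blocks (two odd-ball OB, two game-play SF, two
#' game-plus-oddball SO). At the default TR of 2 s this gives 23
#' timepoints per PW block and 120 per active block, so the four active
#' game-play blocks (SF + SO) contribute 480 volumes.
#'
#' @param tr Repetition time in seconds.
#' @return Data frame with columns `label` and `n_timepoints`.
#' @export
default_block_schedule <- function(tr = 2) {
  labels <- c("PW", "OB", "PW", "SF", "PW", "SO", "PW",
              "SO", "PW", "SF", "PW", "OB", "PW")
  n <- ifelse(labels == "PW", round(46 / tr), round(240 / tr))
  data.frame(label = labels, n_timepoints = as.integer(n))
}

#' Reduced block schedule for simulation studies
#'
#' Same 13-block structure as [default_block_schedule()] but with a
#' configurable (small) number of timepoints per block, keeping
#' simulated cohorts cheap.
#'
#' @param n_pw Timepoints per passive-watching block.
#' @param n_active Timepoints per active (OB/SF/SO) block.
#' @return Data frame with columns `label` and `n_timepoints`.
#' @export
toy_block_schedule <- function(n_pw = 3, n_active = 8) {
  sched <- default_block_schedule()
  sched$n_timepoints <- ifelse(sched$label == "PW",
                               as.integer(n_pw), as.integer(n_active))
  sched
}

expand_schedule <- function(schedule) {
  rep(schedule$label, schedule$n_timepoints)
}

#' Default two-box ROI specification
#'
#' Places one rectangular "dorsal striatum" box per hemisphere,
#' proportionally inside the grid (+x left, +y anterior), mirrored about
#' the mid-sagittal plane.
#'
#' @param grid_shape Integer length-3 grid shape.
#' @return Named list of boxes, each a list with 1-based inclusive index
#'   ranges `x`, `y`, `z`.
#' @export
default_roi_spec <- function(grid_shape = c(16, 16, 12)) {
  g <- as.integer(grid_shape)
  span <- function(lo, hi, n) c(max(1L, ceiling(lo * n)), min(n, floor(hi * n)))
  xl <- span(0.18, 0.44, g[1])
  y <- span(0.28, 0.78, g[2])
  z <- span(0.36, 0.70, g[3])
  xr <- c(g[1] + 1L - xl[2], g[1] + 1L - xl[1])
  list(left = list(x = xl, y = y, z = z),
       right = list(x = xr, y = y, z = z))
}

box_mask <- function(box, grid_shape) {
  m <- array(FALSE, dim = grid_shape)
  m[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]] <- TRUE
  m
}

#' Configuration of a synthetic cohort
#'
#' Default magnitudes (chosen once, see the methods vignette for the
#' design analysis): intensities in arbitrary scanner-like units around a
#' baseline of 1000 inside the brain; per-timepoint noise SD 200 and
#' per-voxel per-subject baseline variation SD 100, i.e. roughly 10%
#' residual feature noise after normalization and temporal averaging;
#' score improvements in game points, N(500, 200^2); pattern signal 0.3
#' units per point confined to the anterior half of the left ROI;
#' spatial-mean component 0.017 units per point over the whole ROI.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param grid_shape Voxel counts per axis (each >= 4).
#' @param voxel_size Voxel edge lengths in mm.
#' @param block_schedule Data frame (`label`, `n_timepoints`); see
#'   [default_block_schedule()].
#' @param roi_spec Named list of boxes as from [default_roi_spec()];
#'   `NULL` uses the default for `grid_shape`.
#' @param signal_roi Name of the ROI box carrying the pattern signal.
#' @param signal_part Portion of that box carrying it: `"anterior"`,
#'   `"posterior"`, or `"all"`.
#' @param baseline In-brain baseline intensity (arbitrary units).
#' @param signal_gain Pattern signal scale, intensity units per score
#'   point (applied to a unit-RMS zero-mean weight map).
#' @param global_gain Spatial-mean signal scale, intensity units per
#'   score point, added uniformly over the whole ROI.
#' @param noise_sd_temporal Per-timepoint Gaussian noise SD.
#' @param noise_sd_spatial Per-voxel per-subject (time-constant)
#'   baseline variation SD.
#' @param score_mean,score_sd Distribution of true score improvements.
#' @param initial_score_mean,initial_score_sd Distribution of session-1
#'   scores.
#' @param roi_volume_cor,initial_score_cor Correlation of the two
#'   covariates with the true improvement (0 by default, giving a known
#'   null for partial-correlation tests).
#' @param seed RNG seed; identical configurations with identical seeds
#'   reproduce cohorts bit for bit.
#' @return A validated `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 34,
                          grid_shape = c(16, 16, 12),
                          voxel_size = c(3.4375, 3.4375, 4),
                          block_schedule = toy_block_schedule(),
                          roi_spec = NULL,
                          signal_roi = "left",
                          signal_part = c("anterior", "posterior", "all"),
                          baseline = 1000,
                          signal_gain = 0.3,
                          global_gain = 0.017,
                          noise_sd_temporal = 200,
                          noise_sd_spatial = 100,
                          score_mean = 500,
                          score_sd = 200,
                          initial_score_mean = 2000,
                          initial_score_sd = 500,
                          roi_volume_cor = 0,
                          initial_score_cor = 0,
                          seed = 1L) {
  signal_part <- match.arg(signal_part)
  grid_shape <- as.integer(grid_shape)
  if (n_subjects < 4L) stop("invalid config: n_subjects must be >= 4")
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop("invalid config: grid dimensions must each be >= 4")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("invalid config: voxel_size must be three positive lengths")
  }
  if (!is.data.frame(block_schedule) ||
      !all(c("label", "n_timepoints") %in% names(block_schedule)) ||
      any(block_schedule$n_timepoints < 1)) {
    stop("invalid config: block_schedule needs label and n_timepoints >= 1")
  }
  sds <- c(noise_sd_temporal, noise_sd_spatial, score_sd, initial_score_sd)
  if (any(sds < 0)) stop("invalid config: all SDs must be >= 0")
  if (baseline <= 0) stop("invalid config: baseline must be positive")
  if (abs(roi_volume_cor) > 1 || abs(initial_score_cor) > 1) {
    stop("invalid config: covariate correlations must lie in [-1, 1]")
  }
  if (is.null(roi_spec)) roi_spec <- default_roi_spec(grid_shape)
  for (nm in names(roi_spec)) {
    box <- roi_spec[[nm]]
    lims <- rbind(box$x, box$y, box$z)
    if (any(lims[, 1] < 1L) || any(lims[, 2] > grid_shape) ||
        any(lims[, 1] > lims[, 2])) {
      stop("invalid config: ROI box '", nm, "' exceeds the grid")
    }
  }
  if (!signal_roi %in% names(roi_spec)) {
    stop("invalid config: signal_roi '", signal_roi, "' not in roi_spec")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
    voxel_size = as.numeric(voxel_size), block_schedule = block_schedule,
    n_timepoints = sum(block_schedule$n_timepoints),
    roi_spec = roi_spec, signal_roi = signal_roi, signal_part = signal_part,
    baseline = baseline, signal_gain = signal_gain, global_gain = global_gain,
    noise_sd_temporal = noise_sd_temporal, noise_sd_spatial = noise_sd_spatial,
    score_mean = score_mean, score_sd = score_sd,
    initial_score_mean = initial_score_mean,
    initial_score_sd = initial_score_sd,
    roi_volume_cor = roi_volume_cor, initial_score_cor = initial_score_cor,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

brain_ellipsoid <- function(grid_shape) {
  g <- grid_shape
  ctr <- (g + 1) / 2
  ax <- 0.48 * g
  xi <- (seq_len(g[1]) - ctr[1]) / ax[1]
  yi <- (seq_len(g[2]) - ctr[2]) / ax[2]
  zi <- (seq_len(g[3]) - ctr[3]) / ax[3]
  d2 <- outer(outer(xi^2, yi^2, `+`), zi^2, `+`)
  d2 <= 1
}

cohort_masks <- function(config) {
  g <- config$grid_shape
  brain <- brain_ellipsoid(g)
  boxes <- lapply(config$roi_spec, box_mask, grid_shape = g)
  roi_all <- Reduce(`|`, boxes)
  if (!all(roi_all[!brain] == FALSE)) {
    # ROI boxes must sit inside the brain so normalization sees them
    brain <- brain | roi_all
  }
  sig_box <- config$roi_spec[[config$signal_roi]]
  sig <- box_mask(sig_box, g)
  if (config$signal_part != "all") {
    ymid <- floor(mean(sig_box$y))  # split the box's own y range
    keep_y <- if (config$signal_part == "anterior") {
      seq_len(g[2]) > ymid
    } else {
      seq_len(g[2]) <= ymid
    }
    sig <- sig & array(rep(keep_y, each = g[1]), dim = g)
  }
  vs <- config$voxel_size
  rois <- c(
    list(dorsal = roi_mask(roi_all, "dorsal", vs)),
    lapply(stats::setNames(names(boxes), names(boxes)), function(nm) {
      roi_mask(boxes[[nm]], nm, vs)
    })
  )
  list(brain = roi_mask(brain, "brain", vs),
       rois = rois,
       signal = roi_mask(sig, "signal_region", vs))
}

# correlate a standard-normal draw with target z to correlation rho
mix_cor <- function(z_target, rho, n) {
  eps <- stats::rnorm(n)
  rho * z_target + sqrt(1 - rho^2) * eps
}

draw_scores <- function(config) {
  n <- config$n_subjects
  y <- stats::rnorm(n, config$score_mean, config$score_sd)
  zy <- if (config$score_sd > 0) (y - config$score_mean) / config$score_sd else
    stats::rnorm(n)
  s1 <- config$initial_score_mean +
    config$initial_score_sd * mix_cor(zy, config$initial_score_cor, n)
  s2 <- s1 + y
  base_prop <- c(control = 0.3, velocity = 0.2, speed = 0.3, points = 0.2)
  split4 <- function(total) {
    p <- base_prop * stats::runif(4, 0.7, 1.3)
    p <- p / sum(p)
    parts <- p * total
    parts[4] <- total - sum(parts[1:3])  # exact sum by construction
    parts
  }
  subs1 <- t(vapply(s1, split4, numeric(4)))
  subs2 <- t(vapply(s2, split4, numeric(4)))
  colnames(subs1) <- paste0(names(base_prop), "_s1")
  colnames(subs2) <- paste0(names(base_prop), "_s2")
  df <- data.frame(subject_id = subject_ids(n),
                   score_s1 = s1, score_s2 = s2,
                   score_improvement = s2 - s1)
  cbind(df, subs1, subs2)
}

tissue_template <- function(config, masks) {
  g <- config$grid_shape
  brain <- masks$brain$data
  roi <- masks$rois$dorsal$data
  wm <- array(0, g); gm <- array(0, g); csf <- array(0, g)
  # mixed tissue everywhere in the brain: below consensus threshold
  wm[brain] <- 0.40; gm[brain] <- 0.40; csf[brain] <- 0.15
  # inside the ROI: clear white matter below mid-z, gray matter above
  zmid <- floor((min(which(roi, arr.ind = TRUE)[, 3]) +
                   max(which(roi, arr.ind = TRUE)[, 3])) / 2)
  zlow <- array(rep(seq_len(g[3]) <= zmid, each = g[1] * g[2]), dim = g)
  wm[roi & zlow] <- 0.85; gm[roi & zlow] <- 0.10; csf[roi & zlow] <- 0.02
  wm[roi & !zlow] <- 0.10; gm[roi & !zlow] <- 0.85; csf[roi & !zlow] <- 0.02
  # a small ventricle-like CSF pocket just anterior-superior of the ROI
  idx <- which(roi, arr.ind = TRUE)
  ytop <- max(idx[, 2]); ztop <- max(idx[, 3])
  if (ztop < g[3]) {
    pocket <- array(FALSE, g)
    pocket[range(idx[, 1])[1]:range(idx[, 1])[2],
           max(1, ytop - 1):ytop, min(g[3], ztop + 1)] <- TRUE
    pocket <- pocket & brain
    wm[pocket] <- 0.05; gm[pocket] <- 0.05; csf[pocket] <- 0.85
  }
  list(wm = wm, gm = gm, csf = csf, brain = brain)
}

jitter_tissue <- function(tpl, sd = 0.05) {
  g <- dim(tpl$wm)
  jit <- function(f) {
    f2 <- f + stats::rnorm(length(f), 0, sd) * (f > 0)
    array(pmin(pmax(f2, 0), 1), dim = g)
  }
  wm <- jit(tpl$wm); gm <- jit(tpl$gm); csf <- jit(tpl$csf)
  tot <- wm + gm + csf
  over <- tot > 1
  if (any(over)) {
    wm[over] <- wm[over] / tot[over]
    gm[over] <- gm[over] / tot[over]
    csf[over] <- csf[over] / tot[over]
  }
  tissue_pv(wm, gm, csf)
}

#' Generate per-subject tissue partial-volume maps
#'
#' Builds a common tissue template on the cohort grid (clear white and
#' gray matter inside the ROI, a CSF pocket above it, sub-threshold mixed
#' tissue elsewhere in the brain) and jitters it per subject, so that
#' consensus thresholding over subjects produces all four label outcomes
#' (WM, GM, CSF, UNASSIGNED).
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed for the per-subject jitter.
#' @return List of [tissue_pv()] objects, one per subject.
#' @export
generate_tissue_maps <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  masks <- cohort_masks(config)
  tpl <- tissue_template(config, masks)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(config$n_subjects), function(s) jitter_tissue(tpl))
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' For subject s at timepoint t the generated intensity is
#' `baseline + global_gain * y_s * [in ROI] + signal_gain * y_s * m +
#' zeta_s + eta_{s,t}` inside the brain (zero outside), where `m` is a
#' fixed zero-mean unit-RMS weight map supported on the configured signal
#' subregion, `zeta_s` is a per-subject spatial noise field constant over
#' time, and `eta` is fresh Gaussian noise per timepoint. Scores split
#' into four sub-scores that sum exactly to the session totals, and the
#' two covariates (ROI volume, initial score) are by default independent
#' of the true improvements. Identical config and seed reproduce the
#' cohort bit for bit.
#'
#' @param config A [cohort_config()].
#' @return List with `subjects` (named list of [epi_series()]),
#'   `brain_mask`, `rois` (named [roi_mask()] list: `dorsal` plus one
#'   mask per configured box), `signal_mask`, `tissue` (per-subject
#'   [tissue_pv()]), `scores` (subject table including sub-scores and
#'   covariates), `truth` (`weight_map`, `scores`, `covariates`), and the
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  g <- config$grid_shape
  masks <- cohort_masks(config)
  brain <- masks$brain$data
  roi_all <- masks$rois$dorsal$data
  sig <- masks$signal$data
  labels <- expand_schedule(config$block_schedule)
  tn <- length(labels)
  nvox <- prod(g)
  brain_lin <- which(brain)
  ids <- subject_ids(config$n_subjects)

  withr::with_seed(config$seed, {
    scores <- draw_scores(config)
    y <- scores$score_improvement

    # ground-truth pattern: zero-mean, unit-RMS over the signal subregion
    m <- array(0, g)
    if (config$signal_gain != 0) {
      if (sum(sig) < 4L) {
        stop("signal subregion has fewer than 4 voxels; ",
             "enlarge the grid or the signal ROI")
      }
      raw <- stats::rnorm(sum(sig))
      raw <- raw - mean(raw)
      raw <- raw / sqrt(mean(raw^2))
      m[sig] <- raw
    }

    nominal_vol <- sum(roi_all) * prod(config$voxel_size)
    zy <- if (config$score_sd > 0) {
      (y - config$score_mean) / config$score_sd
    } else stats::rnorm(length(y))
    roi_volume <- nominal_vol *
      (1 + 0.1 * mix_cor(zy, config$roi_volume_cor, config$n_subjects))
    scores$roi_volume <- roi_volume
    scores$initial_score <- scores$score_s1

    tpl <- tissue_template(config, masks)
    tissue <- lapply(seq_len(config$n_subjects), function(s) {
      jitter_tissue(tpl)
    })

    subjects <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      static <- config$baseline +
        config$global_gain * y[s] * roi_all +
        config$signal_gain * y[s] * m
      zeta <- stats::rnorm(length(brain_lin), 0, config$noise_sd_spatial)
      flat <- matrix(0, nrow = nvox, ncol = tn)
      eta <- matrix(stats::rnorm(length(brain_lin) * tn, 0,
                                 config$noise_sd_temporal),
                    nrow = length(brain_lin), ncol = tn)
      flat[brain_lin, ] <- static[brain_lin] + zeta + eta
      subjects[[s]] <- epi_series(array(flat, dim = c(g, tn)),
                                  block_labels = labels,
                                  voxel_size = config$voxel_size,
                                  subject_id = ids[s])
    }
    names(subjects) <- ids
    names(tissue) <- ids

    list(subjects = subjects,
         brain_mask = masks$brain,
         rois = masks$rois,
         signal_mask = masks$signal,
         tissue = tissue,
         scores = scores,
         truth = list(
           weight_map = brain_volume(m, voxel_size = config$voxel_size),
           scores = y,
           covariates = data.frame(subject_id = ids,
                                   roi_volume = roi_volume,
                                   initial_score = scores$score_s1)
         ),
         config = config)
  })
}
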