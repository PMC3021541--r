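# Preprocessing: per-volume intensity normalization, temporal averaging
# over selected task blocks, ROI feature extraction, consensus tissue
# segmentation, coronal ROI splitting, and block-average resampling.

#' Normalize a volume by its mean intensity inside the brain
#'
#' Divides every voxel by the mean intensity inside `brain_mask`, so that
#' the in-mask mean of the result is exactly 1 (up to float tolerance).
#' Applied per volume, this compensates for drift in scanner adjustments
#' and for global intensity differences between runs and subjects.
#'
#' @param volume A [brain_volume()].
#' @param brain_mask An [roi_mask()] delimiting the brain on the same grid.
#' @return The normalized [brain_volume()].
#' @export
normalize_volume <- function(volume, brain_mask) {
  stopifnot(inherits(volume, "brain_volume"), inherits(brain_mask, "roi_mask"))
  stop_unless_same_grid(volume, brain_mask, "volume vs brain mask")
  m <- mean(volume$data[brain_mask$data])
  if (!is.finite(m) || m <= 0) {
    stop(sprintf("cannot normalize volume (space '%s'): in-mask mean is %g",
                 volume$space, m))
  }
  out <- volume
  out$data <- volume$data / m
  out
}

#' Average normalized EPI volumes over selected blocks
#'
#' Each timepoint whose block tag is in `include_blocks` is first
#' normalized by its in-brain mean (see [normalize_volume()]) and the
#' normalized volumes are then averaged voxelwise. Timepoints with other
#' tags contribute nothing. The number of volumes averaged is returned in
#' the `n_volumes` field of the result.
#'
#' @param series An [epi_series()].
#' @param include_blocks Character vector of block tags to average
#'   (e.g. `c("SF", "SO")` for the active game-play blocks).
#' @param brain_mask An [roi_mask()] used for the per-volume mean.
#' @return A [brain_volume()] with an extra `n_volumes` field.
#' @export
temporal_average <- function(series, include_blocks, brain_mask) {
  stopifnot(inherits(series, "epi_series"), inherits(brain_mask, "roi_mask"))
  dims <- dim(series$data)
  if (!identical(dims[1:3], dim(brain_mask$data))) {
    stop(sprintf("grid mismatch for subject '%s': series %s vs mask %s",
                 series$subject_id, paste(dims[1:3], collapse = "x"),
                 paste(dim(brain_mask$data), collapse = "x")))
  }
  keep <- series$block_labels %in% include_blocks
  if (!any(keep)) {
    stop("no timepoint carries any of the requested block tags: ",
         paste(include_blocks, collapse = ", "))
  }
  nvox <- prod(dims[1:3])
  flat <- matrix(series$data, nrow = nvox, ncol = dims[4])[, keep, drop = FALSE]
  means <- colMeans(flat[as.vector(brain_mask$data), , drop = FALSE])
  if (any(!is.finite(means)) || any(means <= 0)) {
    bad <- which(!is.finite(means) | means <= 0)[1]
    stop(sprintf("cannot normalize volume %d of subject '%s': in-mask mean is %g",
                 which(keep)[bad], series$subject_id, means[bad]))
  }
  avg <- rowMeans(sweep(flat, 2, means, "/"))
  out <- brain_volume(array(avg, dim = dims[1:3]),
                      voxel_size = series$voxel_size)
  out$n_volumes <- sum(keep)
  out
}

#' Extract an ROI feature matrix across subjects
#'
#' Builds the subjects-by-voxels matrix used as MVPA input: row s holds
#' subject s's intensities at the ROI voxels, with no further scaling or
#' voxel selection. Columns follow the grid's column-major linear order
#' (x fastest, then y, then z); the voxel coordinate of each column is
#' kept in the `voxel_index` attribute (1-based (x, y, z) indices).
#'
#' @param volumes Named list of [brain_volume()]s, one per subject; names
#'   are the subject ids and fix the row order.
#' @param roi An [roi_mask()] on the same grid.
#' @return A numeric matrix of class `feature_matrix` with attributes
#'   `voxel_index` and `roi_name`.
#' @export
extract_features <- function(volumes, roi) {
  stopifnot(inherits(roi, "roi_mask"), length(volumes) >= 1L)
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("subject%02d", seq_along(volumes))
  sel <- which(roi$data)
  rows <- lapply(seq_along(volumes), function(s) {
    v <- volumes[[s]]
    stopifnot(inherits(v, "brain_volume"))
    if (!identical(dim(v$data), dim(roi$data))) {
      stop(sprintf("grid mismatch for subject '%s': volume %s vs ROI %s",
                   ids[s], paste(dim(v$data), collapse = "x"),
                   paste(dim(roi$data), collapse = "x")))
    }
    v$data[sel]
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- ids
  structure(mat,
            voxel_index = which(roi$data, arr.ind = TRUE),
            roi_name = roi$name,
            class = c("feature_matrix", class(mat)))
}

#' Consensus tissue segmentation across subjects
#'
#' Averages per-subject partial-volume maps voxelwise and accepts a voxel
#' as white matter, gray matter, or CSF only if the averaged fraction of
#' that tissue exceeds 50% (strictly). Voxels where no tissue reaches the
#' threshold are labeled `UNASSIGNED` and flagged for exclusion from
#' analysis.
#'
#' @param tissue_maps List of [tissue_pv()] objects, one per subject, on
#'   a shared grid.
#' @return A `tissue_labels` object: `data` is a character 3D array with
#'   values in `WM`, `GM`, `CSF`, `UNASSIGNED`; `consensus` holds the
#'   averaged fractions; `excluded` is the logical UNASSIGNED mask.
#' @export
consensus_segmentation <- function(tissue_maps) {
  stopifnot(length(tissue_maps) >= 1L)
  dims <- dim(tissue_maps[[1]]$wm)
  for (tm in tissue_maps) {
    stopifnot(inherits(tm, "tissue_pv"))
    if (!identical(dim(tm$wm), dims)) stop("tissue maps must share one grid")
  }
  ns <- length(tissue_maps)
  wm <- Reduce(`+`, lapply(tissue_maps, `[[`, "wm")) / ns
  gm <- Reduce(`+`, lapply(tissue_maps, `[[`, "gm")) / ns
  csf <- Reduce(`+`, lapply(tissue_maps, `[[`, "csf")) / ns
  labels <- array("UNASSIGNED", dim = dims)
  labels[wm > 0.5] <- "WM"
  labels[gm > 0.5] <- "GM"
  labels[csf > 0.5] <- "CSF"
  structure(list(data = labels,
                 consensus = tissue_pv(wm, gm, csf),
                 excluded = labels == "UNASSIGNED",
                 n_subjects = ns),
            class = "tissue_labels")
}

#' Split an ROI into anterior and posterior halves with a coronal plane
#'
#' Scans all coronal (constant-y) cutting planes and keeps the one that
#' minimizes the absolute difference between the anterior and posterior
#' voxel counts; ties are broken toward the smaller anterior count.
#' Convention: +y is anterior, so the anterior part consists of the
#' higher y indices.
#'
#' @param roi An [roi_mask()] spanning at least two coronal slices.
#' @return List with `anterior` and `posterior` [roi_mask()]s that
#'   partition the ROI, and `cut` (voxels with y > cut are anterior).
#' @export
split_roi_coronal <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  idx <- which(roi$data, arr.ind = TRUE)
  ys <- sort(unique(idx[, 2]))
  if (length(ys) < 2L) {
    stop("ROI '", roi$name, "' spans a single coronal slice and cannot be split")
  }
  counts <- table(factor(idx[, 2], levels = ys))
  total <- sum(counts)
  cuts <- ys[-length(ys)]  # cut after each slice except the last
  anterior_counts <- vapply(cuts, function(cut) sum(counts[ys > cut]), numeric(1))
  diffs <- abs(anterior_counts - (total - anterior_counts))
  best <- which(diffs == min(diffs))
  # ties: prefer the smaller anterior count, i.e. the larger cut index
  cut <- max(cuts[best][anterior_counts[best] == min(anterior_counts[best])])
  ant <- roi$data
  ant[, seq_len(dim(roi$data)[2]) <= cut, ] <- FALSE
  post <- roi$data & !ant
  list(anterior = roi_mask(ant, name = paste0(roi$name, "_anterior"),
                           voxel_size = roi$voxel_size),
       posterior = roi_mask(post, name = paste0(roi$name, "_posterior"),
                            voxel_size = roi$voxel_size),
       cut = cut)
}

#' Downsample a volume by block averaging
#'
#' Resamples a high-resolution volume onto a coarser grid whose shape
#' divides the source shape exactly, replacing each block of source
#' voxels by its mean (as when bringing an anatomical MPRAGE volume down
#' to EPI resolution). Exact nesting keeps the volume mean unchanged.
#'
#' @param hi_res A [brain_volume()].
#' @param target_shape Integer length-3 target grid shape; each source
#'   extent must be an integer multiple of it.
#' @return A [brain_volume()] on the target grid, with voxel size scaled
#'   by the per-axis factors.
#' @export
subsample_volume <- function(hi_res, target_shape) {
  stopifnot(inherits(hi_res, "brain_volume"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    stop("target_shape must be three positive integers")
  }
  src <- dim(hi_res$data)
  fac <- src / target_shape
  if (any(fac != round(fac)) || any(fac < 1)) {
    stop("target grid must divide the source grid exactly (per axis)")
  }
  fac <- as.integer(fac)
  v <- array(hi_res$data,
             dim = c(fac[1], target_shape[1], fac[2], target_shape[2],
                     fac[3], target_shape[3]))
  out <- apply(v, c(2, 4, 6), mean)
  brain_volume(out, voxel_size = hi_res$voxel_size * fac,
               space = hi_res$space)
}
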