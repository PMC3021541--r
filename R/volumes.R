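# Lightweight S3 containers for volumetric data. Grid convention
# throughout the package: array axis order (x, y, z) with 1-based voxel
# indices, +x running left to right of the subject and +y pointing
# anterior. All subjects share one grid; registration is out of scope.

#' Create a 3D brain volume
#'
#' @param data Numeric 3D array (x, y, z), finite values.
#' @param voxel_size Numeric length-3 voxel edge lengths in mm.
#' @param space Common-space identifier tag.
#' @return A `brain_volume`.
#' @export
brain_volume <- function(data, voxel_size = c(1, 1, 1), space = "cohort") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("brain_volume data must be 3D")
  if (any(!is.finite(data))) stop("brain_volume data must be finite")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 space = space),
            class = "brain_volume")
}

#' Create a 4D EPI series
#'
#' @param data Numeric 4D array (x, y, z, t).
#' @param block_labels Character vector of per-timepoint block tags
#'   (e.g. "PW", "OB", "SF", "SO"), length matching the t extent.
#' @param voxel_size Numeric length-3 voxel edge lengths in mm.
#' @param subject_id Subject identifier.
#' @return An `epi_series`.
#' @export
epi_series <- function(data, block_labels, voxel_size = c(1, 1, 1),
                       subject_id = "subject") {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("epi_series data must be 4D (x, y, z, t)")
  if (any(!is.finite(data))) stop("epi_series data must be finite")
  block_labels <- as.character(block_labels)
  if (length(block_labels) != dim(data)[4]) {
    stop("block_labels length must equal the number of timepoints")
  }
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(data = data, block_labels = block_labels,
                 voxel_size = as.numeric(voxel_size),
                 subject_id = subject_id),
            class = "epi_series")
}

#' Create a region-of-interest mask
#'
#' @param data Logical (or 0/1 numeric) 3D array; must select at least
#'   one voxel.
#' @param name Label for the region (e.g. "dorsal_striatum_left").
#' @param voxel_size Numeric length-3 voxel edge lengths in mm.
#' @return An `roi_mask`.
#' @export
roi_mask <- function(data, name = "roi", voxel_size = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("roi_mask data must be 3D")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) {
      stop("mask values must be 0/1 or logical")
    }
    data <- array(data > 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask values must be 0/1 or logical")
  if (anyNA(data)) stop("mask must not contain NA")
  if (!any(data)) stop("mask '", name, "' is empty")
  structure(list(data = data, name = name,
                 voxel_size = as.numeric(voxel_size)),
            class = "roi_mask")
}

#' Create per-voxel tissue partial-volume maps
#'
#' @param wm,gm,csf 3D arrays of tissue fractions in \[0, 1\]; at every
#'   voxel the three fractions must sum to at most 1 (plus a small
#'   tolerance).
#' @return A `tissue_pv`.
#' @export
tissue_pv <- function(wm, gm, csf) {
  wm <- as.array(wm); gm <- as.array(gm); csf <- as.array(csf)
  if (!identical(dim(wm), dim(gm)) || !identical(dim(wm), dim(csf))) {
    stop("tissue fraction grids must share one shape")
  }
  for (frac in list(wm, gm, csf)) {
    if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1)) {
      stop("tissue fractions must lie in [0, 1]")
    }
  }
  if (any(wm + gm + csf > 1 + 1e-6)) {
    stop("tissue fractions must sum to at most 1 per voxel")
  }
  structure(list(wm = wm, gm = gm, csf = csf), class = "tissue_pv")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat(sprintf("brain_volume %s, voxels %.4g x %.4g x %.4g mm (space: %s)\n",
              paste(dim(x$data), collapse = " x "),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$space))
  invisible(x)
}

#' @export
print.epi_series <- function(x, ...) {
  tab <- table(x$block_labels)
  cat(sprintf("epi_series '%s': grid %s, %d timepoints (%s)\n",
              x$subject_id, paste(dim(x$data)[1:3], collapse = " x "),
              dim(x$data)[4],
              paste(names(tab), tab, sep = ":", collapse = ", ")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s': %d voxels in a %s grid\n",
              x$name, sum(x$data), paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

same_grid <- function(a, b) identical(dim(a$data), dim(b$data))

stop_unless_same_grid <- function(a, b, what) {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch: %s (%s vs %s)", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  }
  invisible(TRUE)
}
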