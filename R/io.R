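# NIfTI-1 and table I/O plus the end-to-end pipeline runner. Tables are
# tab-delimited UTF-8 with a single header row; provenance (seed, config
# hash, package version) travels in '#'-prefixed comment lines.

#' Write a 3D volume or mask to NIfTI-1
#'
#' Data are stored as float32; masks as 0/1. Voxel sizes go into pixdim.
#'
#' @param volume A [brain_volume()] or [roi_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "roi_mask")) {
    dat <- array(as.numeric(volume$data), dim = dim(volume$data))
  } else if (inherits(volume, "brain_volume")) {
    dat <- volume$data
  } else {
    stop("write_volume expects a brain_volume or roi_mask")
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- volume$voxel_size
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a 3D volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @return A [brain_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3D volume in '%s' but found %dD data",
                 path, length(d)))
  }
  brain_volume(array(as.numeric(img), dim = d),
               voxel_size = RNifti::pixdim(img)[1:3])
}

#' Read a 0/1 mask from NIfTI-1
#'
#' @param path NIfTI file path; voxel values must be exactly 0 or 1.
#' @param name Label to attach to the mask.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, name = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3D mask in '%s' but found %dD data",
                 path, length(d)))
  }
  vals <- as.numeric(img)
  if (!all(vals %in% c(0, 1))) {
    stop(sprintf("mask '%s' contains values other than 0/1", path))
  }
  roi_mask(array(vals > 0, dim = d), name = name,
           voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a 4D EPI series with its block-schedule sidecar
#'
#' The volume goes to `path` as float32 NIfTI-1; the per-timepoint block
#' tags go to a tab-delimited sidecar (`timepoint`, `block_tag`) whose
#' path replaces the NIfTI extension with `_blocks.tsv`.
#'
#' @param series An [epi_series()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "epi_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  side <- sidecar_path(path)
  utils::write.table(
    data.frame(timepoint = seq_along(series$block_labels),
               block_tag = series$block_labels),
    side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, side))
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_blocks.tsv")
}

#' Read a 4D EPI series and its block-schedule sidecar
#'
#' @param path `.nii`/`.nii.gz` path written by [write_series()] (the
#'   `_blocks.tsv` sidecar must sit next to it).
#' @param subject_id Subject identifier to attach.
#' @return An [epi_series()].
#' @export
read_series <- function(path, subject_id = sub("\\.nii(\\.gz)?$", "",
                                               basename(path))) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop(sprintf("expected a 4D series in '%s' but found %dD data",
                 path, length(d)))
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing block-schedule sidecar: ", side)
  blocks <- utils::read.table(side, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (nrow(blocks) != d[4]) {
    stop(sprintf("sidecar '%s' has %d rows but the series has %d timepoints",
                 side, nrow(blocks), d[4]))
  }
  epi_series(array(as.numeric(img), dim = d),
             block_labels = blocks$block_tag,
             voxel_size = RNifti::pixdim(img)[1:3],
             subject_id = subject_id)
}

#' Write a table with provenance header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Named character vector written as `# key: value`
#'   comment lines before the header row.
#' @return `path`, invisibly.
#' @export
write_table_prov <- function(df, path, provenance = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table_prov()]
#'
#' @param path Input path.
#' @return Data frame; provenance lines are attached as the
#'   `provenance` attribute.
#' @export
read_table_prov <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  prov <- grep("^# ", lines, value = TRUE)
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  attr(df, "provenance") <- prov
  df
}

# order-dependent FNV-style hash of the deparsed configuration, so two
# runs agree iff their configurations deparse identically
config_hash <- function(config) {
  txt <- paste(deparse(config, control = "all"), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(txt)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the full pipeline: simulate, preprocess, predict, report
#'
#' Generates a synthetic cohort, temporally averages the normalized
#' active-block volumes, runs LOSO SVR prediction over the requested
#' ROIs together with the spatial-mean baseline, and writes
#' `predictions.tsv` and `report.tsv` (tab-delimited, with seed, config
#' hash and package version in comment lines). Re-running with an
#' identical configuration reproduces the outputs byte for byte.
#'
#' @param cohort A [cohort_config()].
#' @param out_dir Output directory (created if missing).
#' @param include_blocks Block tags averaged into the feature volumes.
#' @param roi_names ROIs to analyse; must exist in the generated cohort.
#' @param svr An [svr_config()]; default is scale-aware for score-point
#'   targets (C = 1000).
#' @param comparisons ROI pairs passed to [run_roi_battery()].
#' @return Invisibly, a list with the `battery`, `spatial_mean` result,
#'   averaged `volumes`, and the two output `paths`.
#' @export
run_end_to_end <- function(cohort = cohort_config(),
                           out_dir,
                           include_blocks = c("SF", "SO"),
                           roi_names = c("dorsal", "left", "right"),
                           svr = svr_config(C = 1000),
                           comparisons = list(c("left", "right"))) {
  stopifnot(inherits(cohort, "cohort_config"))
  bad <- setdiff(roi_names, c("dorsal", names(cohort$roi_spec)))
  if (length(bad)) {
    stop("unknown ROI name(s): ", paste(bad, collapse = ", "))
  }
  if (!all(include_blocks %in% cohort$block_schedule$label)) {
    stop("include_blocks not present in the block schedule")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dat <- generate_cohort(cohort)
  volumes <- lapply(dat$subjects, temporal_average,
                    include_blocks = include_blocks,
                    brain_mask = dat$brain_mask)

  battery <- run_roi_battery(volumes, dat$rois[roi_names], dat$scores,
                             score_columns = "score_improvement",
                             config = svr, comparisons = comparisons)
  sm <- spatial_mean_analysis(volumes, dat$rois[[roi_names[1]]],
                              dat$scores$score_improvement)

  prov <- c(seed = as.character(cohort$seed),
            config_hash = config_hash(cohort),
            package = paste0("mvpasvr ",
                             as.character(utils::packageVersion("mvpasvr"))))

  cv <- loso_predict(extract_features(volumes, dat$rois[[roi_names[1]]]),
                     dat$scores$score_improvement, svr)
  pred_path <- file.path(out_dir, "predictions.tsv")
  write_table_prov(cv$predictions, pred_path, prov)

  report <- battery$results
  sm_row <- data.frame(roi = paste0(roi_names[1], "_spatial_mean"),
                       score = "score_improvement",
                       n = sm$correlation$n, r = sm$correlation$r,
                       z_fisher = sm$correlation$z_fisher,
                       stat = sm$correlation$stat, p = sm$correlation$p)
  report_path <- file.path(out_dir, "report.tsv")
  write_table_prov(rbind(report, sm_row), report_path, prov)

  invisible(list(battery = battery, spatial_mean = sm, loso = cv,
                 volumes = volumes, cohort = dat,
                 paths = c(predictions = pred_path, report = report_path)))
}
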