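# Shared fixtures, built in code at test time.

# Reduced-scale cohort configuration for simulation-heavy tests: same
# aggregate pattern SNR as the package default (~4.5; signal_gain scaled
# for the smaller 18-voxel signal region), smaller grid and schedule.
test_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(10, 10, 8),
         block_schedule = toy_block_schedule(n_pw = 2, n_active = 5),
         signal_gain = 0.6),
    list(...))
  do.call(cohort_config, args)
}

# scale-aware SVR configuration for score-point targets
test_svr_config <- function(...) {
  svr_config(C = 1000, ...)
}

# temporally averaged active-block volumes for a generated cohort
average_cohort <- function(dat, blocks = c("SF", "SO")) {
  lapply(dat$subjects, temporal_average,
         include_blocks = blocks, brain_mask = dat$brain_mask)
}

# tiny deterministic volume helpers
vol3 <- function(values, dims = NULL, voxel_size = c(1, 1, 1)) {
  if (is.null(dims)) dims <- dim(values)
  brain_volume(array(values, dim = dims), voxel_size = voxel_size)
}

mask3 <- function(values, dims = NULL, name = "m") {
  if (is.null(dims)) dims <- dim(values)
  roi_mask(array(as.logical(values), dim = dims), name = name)
}
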