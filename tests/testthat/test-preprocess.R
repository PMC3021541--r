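test_that("normalization scales to unit in-mask mean and is idempotent", {
  dims <- c(4, 4, 4)
  const <- vol3(rep(7, 64), dims)
  brain <- mask3(rep(TRUE, 64), dims)
  norm <- normalize_volume(const, brain)
  expect_equal(norm$data, array(1, dims))

  # two-voxel mask with values (2, 4): mean 3 -> (2/3, 4/3)
  v <- array(9, dims); v[1, 1, 1] <- 2; v[2, 1, 1] <- 4
  m <- array(FALSE, dims); m[1:2, 1, 1] <- TRUE
  out <- normalize_volume(vol3(v), mask3(m))
  expect_equal(out$data[1, 1, 1], 2 / 3)
  expect_equal(out$data[2, 1, 1], 4 / 3)
  expect_equal(mean(out$data[m]), 1)

  # idempotence
  again <- normalize_volume(out, mask3(m))
  expect_equal(again$data, out$data, tolerance = 1e-15)

  zero <- vol3(array(0, dims))
  expect_error(normalize_volume(zero, brain), "in-mask mean")
})

test_that("temporal averaging uses exactly the requested blocks", {
  dims <- c(4, 4, 3)
  sched <- default_block_schedule()
  labels <- rep(sched$label, sched$n_timepoints)
  tn <- length(labels)
  set.seed(61)
  dat <- array(1000 + rnorm(prod(dims) * tn, 0, 10), dim = c(dims, tn))
  series <- epi_series(dat, labels, subject_id = "t01")
  brain <- mask3(rep(TRUE, prod(dims)), dims)

  active <- temporal_average(series, c("SF", "SO"), brain)
  expect_equal(active$n_volumes, 480L)    # four 4-minute blocks at TR 2 s
  ob <- temporal_average(series, "OB", brain)
  expect_equal(ob$n_volumes, 240L)        # the two odd-ball blocks

  # manual recomputation for the OB selection
  keep <- labels == "OB"
  flat <- matrix(dat, ncol = tn)[, keep]
  manual <- rowMeans(sweep(flat, 2, colMeans(flat), "/"))
  expect_equal(as.vector(ob$data), manual, tolerance = 1e-12)

  expect_error(temporal_average(series, "XX", brain), "block tags")
})

test_that("temporal averaging is order-invariant and trivial for constant series", {
  dims <- c(3, 3, 3)
  brain <- mask3(rep(TRUE, 27), dims)
  set.seed(62)
  vols <- array(rnorm(27 * 6, 100, 5), dim = c(dims, 6))
  s1 <- epi_series(vols, c("A", "B", "A", "B", "A", "B"))
  s2 <- epi_series(vols[, , , c(5, 1, 3, 2, 4, 6)],
                   c("A", "A", "A", "B", "B", "B"))
  a1 <- temporal_average(s1, "A", brain)
  a2 <- temporal_average(s2, "A", brain)
  expect_equal(a1$data, a2$data, tolerance = 1e-12)

  const <- epi_series(array(rep(vols[, , , 1], 4), dim = c(dims, 4)),
                      rep("A", 4))
  avg <- temporal_average(const, "A", brain)
  one <- normalize_volume(vol3(vols[, , , 1]), brain)
  expect_equal(avg$data, one$data, tolerance = 1e-12)
})

test_that("feature extraction follows the documented voxel order", {
  dims <- c(3, 3, 2)
  set.seed(63)
  m <- array(FALSE, dims); m[c(1, 5, 9, 14)] <- TRUE
  roi <- mask3(m, name = "probe")
  vols <- list(a = vol3(array(rnorm(18), dims)),
               b = vol3(array(rnorm(18), dims)),
               c = vol3(array(rnorm(18), dims)))
  fm <- extract_features(vols, roi)
  expect_equal(dim(fm), c(3L, 4L))
  expect_equal(rownames(fm), c("a", "b", "c"))
  expect_equal(unname(fm["b", ]), vols$b$data[which(m)])
  expect_identical(attr(fm, "roi_name"), "probe")
  expect_equal(nrow(attr(fm, "voxel_index")), 4L)

  # permuting subject order permutes rows identically
  fm2 <- extract_features(vols[c(3, 1, 2)], roi)
  expect_equal(unclass(fm2), unclass(fm)[c(3, 1, 2), ], ignore_attr = TRUE)

  # single-voxel ROI reduces to that voxel's values
  one <- mask3(array(c(TRUE, rep(FALSE, 17)), dims))
  f1 <- extract_features(vols, one)
  expect_equal(unname(f1[, 1]),
               unname(sapply(vols, function(v) v$data[1])))

  bad <- list(a = vol3(array(1, c(2, 2, 2))))
  expect_error(extract_features(bad, roi), "grid mismatch.*'a'")
})

test_that("consensus segmentation applies the strict majority rule", {
  dims <- c(2, 2, 1)
  zero <- array(0, dims)
  mk <- function(wm, gm, csf) {
    w <- zero; g <- zero; c <- zero
    w[] <- wm; g[] <- gm; c[] <- csf
    tissue_pv(w, g, c)
  }
  # voxelwise averaged fractions: (0.6,0.3,0.1) WM; (0.5,0.4,0.1)
  # UNASSIGNED (strict >); WM 0.9/0.2 averaging to 0.55 -> WM
  t1 <- tissue_pv(array(c(0.6, 0.5, 0.9, 0.2), dims),
                  array(c(0.3, 0.4, 0.05, 0.3), dims),
                  array(c(0.1, 0.1, 0.05, 0.2), dims))
  t2 <- tissue_pv(array(c(0.6, 0.5, 0.2, 0.9), dims),
                  array(c(0.3, 0.4, 0.3, 0.05), dims),
                  array(c(0.1, 0.1, 0.2, 0.05), dims))
  labs <- consensus_segmentation(list(t1, t2))
  expect_equal(as.vector(labs$data), c("WM", "UNASSIGNED", "WM", "WM"))
  expect_equal(as.vector(labs$excluded), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(labs$consensus$wm[2, 1, 1], 0.5)

  # an exactly assigned label always has consensus fraction > 0.5
  assigned <- labs$data != "UNASSIGNED"
  top <- pmax(labs$consensus$wm, labs$consensus$gm, labs$consensus$csf)
  expect_true(all(top[assigned] > 0.5))

  expect_error(consensus_segmentation(list(t1, mk(0.5, 0.2, 0.1))), NA)
  expect_error(
    consensus_segmentation(list(t1, tissue_pv(array(0.5, c(3, 1, 1)),
                                              array(0.2, c(3, 1, 1)),
                                              array(0.1, c(3, 1, 1))))),
    "share one grid")
})

test_that("the coronal split balances voxel counts and partitions the ROI", {
  dims <- c(4, 10, 4)
  # symmetric ROI: exact 50/50 split
  m <- array(FALSE, dims); m[2, 3:8, 2] <- TRUE
  sp <- split_roi_coronal(mask3(m, name = "sym"))
  expect_equal(sum(sp$anterior$data), 3)
  expect_equal(sum(sp$posterior$data), 3)
  expect_false(any(sp$anterior$data & sp$posterior$data))
  expect_equal(sp$anterior$data | sp$posterior$data, m)

  # slice populations 1,1,5 front to back (front = high y): the best cut
  # puts the first two slices anterior (|2-5| = 3 beats |1-6| = 5)
  m2 <- array(FALSE, dims)
  m2[1, 10, 1] <- TRUE                 # most anterior slice: 1 voxel
  m2[1, 9, 1] <- TRUE                  # next slice: 1 voxel
  m2[1:4, 8, 1] <- TRUE; m2[1, 8, 2] <- TRUE   # back slice: 5 voxels
  sp2 <- split_roi_coronal(mask3(m2, name = "lop"))
  expect_equal(sum(sp2$anterior$data), 2)
  expect_equal(sum(sp2$posterior$data), 5)
  expect_equal(sp2$cut, 8)

  single <- array(FALSE, dims); single[1:3, 5, 1] <- TRUE
  expect_error(split_roi_coronal(mask3(single)), "single coronal slice")
})

test_that("block-average subsampling matches hand arithmetic", {
  # one 2x2x2 block holding 1..8 collapses to its mean 4.5
  v <- vol3(array(1:8, c(2, 2, 2)), voxel_size = c(1, 2, 3))
  out <- subsample_volume(v, c(1, 1, 1))
  expect_equal(as.vector(out$data), 4.5)
  expect_equal(out$voxel_size, c(2, 4, 6))

  # constant volumes stay constant; identity grid is a no-op
  cv <- vol3(array(3, c(4, 4, 2)))
  expect_equal(unique(as.vector(subsample_volume(cv, c(2, 2, 1))$data)), 3)
  set.seed(64)
  rv <- vol3(array(rnorm(32), c(4, 4, 2)))
  expect_equal(subsample_volume(rv, c(4, 4, 2))$data, rv$data)

  # nesting grids preserve the overall mean
  expect_equal(mean(subsample_volume(rv, c(2, 2, 1))$data), mean(rv$data),
               tolerance = 1e-12)

  expect_error(subsample_volume(rv, c(3, 4, 2)), "divide")
  expect_error(subsample_volume(rv, c(4, 4, 0)), "positive")
})
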