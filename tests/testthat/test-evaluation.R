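test_that("MSSIM identity, symmetry and structural-change cases", {
  set.seed(2)
  x <- matrix(runif(400), 20, 20)
  y <- matrix(runif(400), 20, 20)
  expect_equal(mssim(x, x), 1)
  expect_equal(mssim(x, y), mssim(y, x), tolerance = 1e-12)
  expect_lt(mssim(x, max(x) - x), 1)
  expect_error(mssim(x, matrix(0, 10, 10)), "grid")
  expect_error(mssim(matrix(0, 5, 5), matrix(0, 5, 5)), "window")
})

test_that("all-pairs MSSIM enumerates unordered pairs with self-pairs", {
  set.seed(5)
  fr <- array(runif(16 * 16 * 51), c(16, 16, 51))
  ap <- all_pairs_mssim(fr)
  expect_equal(nrow(ap), 51 * 52 / 2)
  expect_equal(sum(ap$i == ap$j), 51)
  expect_true(all(ap$mssim[ap$i == ap$j] == 1))
  expect_equal(nrow(all_pairs_mssim(fr, include_self = FALSE)),
               51 * 50 / 2)
  ident <- array(rep(fr[, , 1], 5), c(16, 16, 5))
  expect_true(all(all_pairs_mssim(ident)$mssim == 1))
  expect_true(all(ap$mssim >= -1 & ap$mssim <= 1))
})

test_that("Dice overlap formula and edge cases", {
  a <- matrix(FALSE, 4, 4); b <- matrix(FALSE, 4, 4)
  a[1, 1:4] <- TRUE
  b[1, 3:4] <- TRUE; b[2, 1:2] <- TRUE
  expect_equal(dice(a, b), 2 * 2 / (4 + 4))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_warning(d0 <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
                 "empty")
  expect_equal(d0, 1)
})

test_that("ground-truth masks transform correctly through deformations", {
  mask <- matrix(FALSE, 20, 20)
  mask[8:12, 8:12] <- TRUE
  id <- array(0, c(20, 20, 2))
  expect_identical(transform_gt_mask(mask, id), mask)

  shift <- id; shift[, , 1] <- 1   # pull-back by +1 row
  tm <- transform_gt_mask(mask, shift)
  expect_identical(tm[7:11, 8:12], matrix(TRUE, 5, 5))
  expect_equal(sum(tm), sum(mask))

  # smooth small deformation approximately preserves area
  sm <- id
  sm[, , 1] <- 0.3 * sin(seq(0, pi, length.out = 20))
  tm2 <- transform_gt_mask(mask, sm)
  expect_lt(abs(sum(tm2) - sum(mask)) / sum(mask), 0.1)
})

test_that("line profiles have the right shape and smoothness ordering", {
  ds <- noise_free_dataset("PCASL")
  fr <- series_frames(ds$series)
  pr <- line_profile(fr, "row", 20)
  expect_equal(dim(pr), c(dim(fr)[2], 51))
  pc <- line_profile(fr, "column", 60)
  expect_equal(dim(pc), c(dim(fr)[1], 51))
  expect_error(line_profile(fr, "row", 0), "bounds")

  # noise-free, motion-free: suppressed frames are identical, so the
  # profile is flat across frames
  supp <- fr[, , 2:51]
  expect_equal(profile_total_variation(line_profile(supp, "column", 60)), 0)

  # motion raises the total variation; alignment lowers it again
  ds2 <- fixture("motion_ds", simulate_asl_dataset(
    "PCASL", "healthy", model_seed = 2, noise_seed = 2))
  cr <- crop_kidney(ds2$series, "left")
  reg <- register_groupwise(cr)
  ctr <- round(mean(which(cr$gt_masks[[1]]$kidney_left,
                          arr.ind = TRUE)[, 2]))
  tv_before <- profile_total_variation(line_profile(cr$frames, "column", ctr))
  tv_after <- profile_total_variation(line_profile(reg$aligned, "column", ctr))
  expect_lt(tv_after, tv_before)
})

test_that("evaluation report aggregates per-kidney metrics", {
  ds <- fixture("motion_ds", simulate_asl_dataset(
    "PCASL", "healthy", model_seed = 2, noise_seed = 2))
  proc <- fixture("motion_proc", process_series(ds$series, sides = "left"))
  ev <- evaluate_processing(proc)
  expect_s3_class(ev$mssim_pairs, "tbl_df")
  expect_equal(nrow(ev$mssim_pairs), 2 * 1326)
  expect_setequal(ev$dice$structure, c("whole", "cortex", "medulla"))
  expect_true(all(ev$dice$dice >= 0 & ev$dice$dice <= 1))
  expect_true(all(ev$mssim_pairs$mssim >= -1 & ev$mssim_pairs$mssim <= 1))
  agg <- ev$mssim_summary
  expect_gt(agg$mssim[agg$stage == "after"], agg$mssim[agg$stage == "before"])
  expect_lt(ev$profiles$left$tv_after, ev$profiles$left$tv_before)
})
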