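test_that("manual and automatic kidney crops behave as specified", {
  ds <- noise_free_dataset("PCASL")
  cr <- crop_kidney(ds$series, "left", box = c(10, 40, 50, 80))
  expect_equal(dim(cr$frames)[1:2], c(31, 31))
  expect_error(crop_kidney(ds$series, "left", box = c(0, 40, 50, 80)),
               "bounds")

  # auto box contains the ground-truth kidney entirely (noise-free)
  for (side in c("left", "right")) {
    cra <- crop_kidney(ds$series, side)
    gt <- cra$gt_masks[[1]][[paste0("kidney_", side)]]
    full <- ds$series$gt_masks[[1]][[paste0("kidney_", side)]]
    expect_equal(sum(gt), sum(full))   # nothing cut off by the box
  }
  bl <- crop_kidney(ds$series, "left")$box
  br <- crop_kidney(ds$series, "right")$box
  expect_true(bl[3] > br[4] || br[3] > bl[4])   # disjoint boxes

  # a zero-perfusion series has no difference signal to detect
  tab <- default_tissue_table()
  tab$perfusion[] <- 0
  scene0 <- build_phantom(1, "healthy", tissue_table = tab)
  s0 <- simulate_series(scene0, ds$series$protocol,
                        motion_trace(amplitude_mm = 0, seed = 1), snr = Inf)
  expect_error(crop_kidney(s0, "left"), "manual box")
})

test_that("PCA groupwise metric: rank-1 identity, fallback, alignment order", {
  base <- shifted_blob_stack(rep(0, 6))
  expect_equal(pca_groupwise_metric(base), 6, tolerance = 1e-8)

  expect_warning(v <- pca_groupwise_metric(array(1, c(8, 8, 5))),
                 "constant")
  expect_equal(v, 5 * 6 / 2)

  # independent oracle: metric equals the rank-weighted eigenvalue sum of
  # the inter-frame correlation matrix, whose trace is the frame count
  set.seed(4)
  noisy <- base + array(rnorm(length(base), 0, 0.05), dim(base))
  M <- matrix(noisy, ncol = 6)
  lam <- sort(eigen(cor(M), symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(sum(lam), 6, tolerance = 1e-10)
  expect_equal(pca_groupwise_metric(noisy), sum(seq_len(6) * lam),
               tolerance = 1e-8)

  # misaligned < aligned ordering
  mis <- shifted_blob_stack(c(0, 0, 0, 3, 3, 3))
  expect_gt(pca_groupwise_metric(mis), pca_groupwise_metric(base))
})

test_that("known rigid shifts are recovered within half a voxel", {
  shifts <- c(rep(0, 5), rep(2, 5))
  stack <- shifted_blob_stack(shifts)
  reg <- register_groupwise(stack)
  expect_equal(dim(reg$aligned)[3], length(shifts))
  ctr <- stack[, , 1] > 0.2
  rec <- vapply(seq_along(shifts), function(g)
    mean(reg$deformations[, , 1, g][ctr]), numeric(1))
  truth <- shifts - mean(shifts)
  expect_lt(max(abs(rec - truth)), 0.5)

  # implicit-mean constraint: per-pixel mean displacement over frames ~ 0
  expect_lt(max(abs(apply(reg$deformations, c(1, 2, 3), mean))), 0.1)

  # deformations are fold-free almost everywhere
  jac_ok <- vapply(seq_along(shifts), function(g)
    mean(jacobian_determinant(reg$deformations[, , , g]) > 0), numeric(1))
  expect_true(all(jac_ok >= 0.99))

  # aligned frame k is the raw frame k resampled through deformation k
  redo <- apply_deformation(stack[, , 6], reg$deformations[, , , 6])
  expect_equal(redo, reg$aligned[, , 6], tolerance = 1e-10)

  # stochastic descent: late metric values do not exceed early ones
  tr <- reg$metric_trace
  for (lev in seq_len(ncol(tr))) {
    v <- tr[is.finite(tr[, lev]), lev]
    n <- length(v)
    expect_lte(median(v[(n - 9):n]), median(v[1:10]) * 1.02)
  }
})

test_that("an already-aligned noise-free series is left untouched", {
  ds <- noise_free_dataset("PCASL")
  cr <- crop_kidney(ds$series, "left")
  reg <- register_groupwise(cr)
  expect_lt(max(abs(reg$deformations)), 0.25)
})

test_that("registration does not degrade similarity on corrupted series", {
  ds <- fixture("motion_ds", simulate_asl_dataset(
    "PCASL", "healthy", model_seed = 2, noise_seed = 2))
  cr <- crop_kidney(ds$series, "left")
  reg <- register_groupwise(cr)
  L <- max(cr$frames)
  before <- mean(all_pairs_mssim(cr$frames, dynamic_range = L)$mssim)
  after <- mean(all_pairs_mssim(reg$aligned, dynamic_range = L)$mssim)
  expect_gte(after, before)
})

test_that("registration settings are validated", {
  expect_error(registration_settings(nonsense = 1), "unknown")
  s <- registration_settings(iterations = 10L)
  expect_equal(s$iterations, 10L)
  expect_length(s$sigmas, 6)
})
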