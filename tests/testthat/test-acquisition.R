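test_that("motion trace selects 51 distinct phases reproducibly", {
  m <- motion_trace(amplitude_mm = 16, seed = 7)
  expect_length(m$selection, 51)
  expect_true(all(m$selection >= 0 & m$selection <= 99))
  expect_false(any(duplicated(m$selection)))
  m2 <- motion_trace(amplitude_mm = 16, seed = 7)
  expect_identical(m$selection, m2$selection)
  expect_false(identical(m$selection, motion_trace(seed = 8)$selection))

  m0 <- motion_trace(amplitude_mm = 0, seed = 1)
  expect_true(all(m0$displacement_mm == 0))
  # the reference (M0) phase is the least-displaced one
  expect_equal(m$displacement_mm[m$selection[1] + 1],
               min(m$displacement_mm))
})

test_that("series assembly: 51 frames, determinism, motion-free identity", {
  ds <- noise_free_dataset("PCASL")
  s <- ds$series
  expect_length(s$frame_order, 51)
  expect_identical(s$frame_order[1:3], c("m0", "control", "label"))
  expect_equal(dim(s$controls)[3], 25)

  # no motion, no noise: all control frames identical
  expect_equal(max(abs(sweep(s$controls, c(1, 2), s$controls[, , 1]))), 0)

  s2 <- simulate_asl_dataset("PCASL", "healthy", model_seed = 1,
                             noise_seed = 1, snr = Inf,
                             amplitude_mm = 0)$series
  expect_identical(s$m0, s2$m0)
  expect_identical(s$controls, s2$controls)

  # mean over control frames equals the suppressed M0 exactly (clean limit)
  expect_equal(apply(s$controls, c(1, 2), mean), 0.2 * s$m0,
               tolerance = 1e-12)
})

test_that("injected noise has the advertised standard deviation", {
  ds <- simulate_asl_dataset("PCASL", "healthy", model_seed = 1,
                             noise_seed = 3, snr = 20, amplitude_mm = 0)
  s <- ds$series
  resid <- as.vector(s$controls - s$clean$controls)
  expect_gt(length(resid), 1e4)
  gm <- s$gt_masks[[1]]
  sigma_expect <- mean(s$clean$m0[gm$kidney_left | gm$kidney_right]) / 20
  expect_equal(sd(resid), sigma_expect, tolerance = 0.05)
  expect_equal(s$sigma, sigma_expect)
  expect_error(simulate_series(ds$scene, s$protocol, s$motion, snr = 0),
               "positive")
})

test_that("series frames follow the interleaved acquisition order", {
  ds <- noise_free_dataset("PCASL")
  fr <- series_frames(ds$series)
  expect_equal(dim(fr)[3], 51)
  expect_identical(fr[, , 1], ds$series$m0)
  expect_identical(fr[, , 2], ds$series$controls[, , 1])
  expect_identical(fr[, , 3], ds$series$labels[, , 1])
  expect_identical(fr[, , 51], ds$series$labels[, , 25])
})
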