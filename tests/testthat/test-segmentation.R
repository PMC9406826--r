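disk_mask <- function(n = 30, r = 9) {
  outer(seq_len(n), seq_len(n), function(i, j)
    (i - n / 2)^2 + (j - n / 2)^2 <= r^2)
}

test_that("whole-kidney mask modes behave as specified", {
  m0 <- matrix(1, 30, 30)
  gt <- disk_mask()
  expect_identical(whole_kidney_mask(m0, "left", "provided",
                                     provided_mask = gt), gt)
  expect_error(whole_kidney_mask(m0, "left", "provided",
                                 provided_mask = matrix(FALSE, 30, 30)),
               "empty")
  e1 <- whole_kidney_mask(m0, "left", "emulated_manual", gt_mask = gt,
                          seed = 5)
  e2 <- whole_kidney_mask(m0, "left", "emulated_manual", gt_mask = gt,
                          seed = 5)
  expect_identical(e1, e2)
  expect_true(all(e1[gt]))                   # only adds, never removes
  expect_gte(dice(e1, gt), 0.9)
})

test_that("k-means separates a perfectly separable perfusion map", {
  whole <- disk_mask()
  rbf <- matrix(0, 30, 30)
  inner <- disk_mask(r = 5)
  rbf[whole] <- 250
  rbf[inner] <- 50
  km <- kmeans_cortex_medulla(rbf, whole)
  expect_identical(km$cortex, whole & !inner)
  expect_identical(km$medulla, inner)
  expect_equal(unname(km$cluster_means), c(250, 50))
  expect_gt(km$cluster_means["cortex"], km$cluster_means["medulla"])
})

test_that("constant perfusion falls back to the degenerate path", {
  whole <- disk_mask()
  expect_warning(km <- kmeans_cortex_medulla(matrix(100, 30, 30), whole),
                 "constant")
  expect_identical(km$cortex, whole)
  expect_false(any(km$medulla))
})

test_that("misassignment on a noisy two-Gaussian mixture stays below 1%", {
  set.seed(42)
  whole <- matrix(TRUE, 60, 60)
  truth <- matrix(rep(c(TRUE, FALSE), each = 1800), 60, 60)  # cortex half
  rbf <- matrix(0, 60, 60)
  rbf[truth] <- rnorm(sum(truth), 250, 30)
  rbf[!truth] <- rnorm(sum(!truth), 50, 15)
  km <- kmeans_cortex_medulla(rbf, whole)
  # oracle: optimal threshold at the midpoint 150
  oracle_cortex <- rbf > 150
  mis <- mean(km$cortex != oracle_cortex)
  expect_lte(mis, 0.01)
  expect_lte(mean(km$cortex != truth), 0.01)
})

test_that("erosion matches the brute-force definition with both elements", {
  set.seed(3)
  for (side in c("left", "right")) {
    se <- medulla_structuring_element(side)
    for (rep in 1:5) {
      mask <- matrix(runif(20 * 20) > 0.35, 20, 20)
      expect_identical(binary_erode(mask, se, c(2L, 3L)),
                       erode_oracle(mask, se, c(2L, 3L)))
    }
  }
  # all-ones mask: border band is lost, interior preserved
  ones <- matrix(TRUE, 20, 20)
  er <- binary_erode(ones, medulla_structuring_element("left"), c(2L, 3L))
  expect_identical(er, erode_oracle(ones, medulla_structuring_element("left"),
                                    c(2L, 3L)))
  expect_false(all(er))
  expect_true(all(er[5:15, 5:15]))
})

test_that("medulla cleanup removes rim voxels and keeps the partition", {
  whole <- disk_mask(30, 10)
  medulla <- disk_mask(30, 4)
  cortex <- whole & !medulla
  res <- erode_medulla(medulla, whole, cortex, "left")
  expect_identical(res$medulla, medulla)    # interior medulla untouched
  # medulla touching the rim loses its outer voxels, reassigned to cortex
  rim_med <- whole
  res2 <- erode_medulla(rim_med, whole, matrix(FALSE, 30, 30), "left",
                        reassign = "cortex")
  expect_lt(sum(res2$medulla), sum(rim_med))
  expect_identical(res2$cortex | res2$medulla, rim_med)
  res3 <- erode_medulla(rim_med, whole, matrix(FALSE, 30, 30), "left")
  expect_false(any(res3$cortex))
  expect_identical(res3$medulla, res2$medulla)
  # empty medulla stays empty
  res4 <- erode_medulla(matrix(FALSE, 30, 30), whole, cortex, "left")
  expect_false(any(res4$medulla))
})

test_that("segmentation output satisfies the structural invariants", {
  whole <- disk_mask()
  rbf <- matrix(NA_real_, 30, 30)
  set.seed(9)
  inner <- disk_mask(r = 5)
  rbf[whole] <- rnorm(sum(whole), 250, 25)
  rbf[inner] <- rnorm(sum(inner), 50, 10)
  map <- structure(list(rbf = rbf), class = "perfusion_map")
  seg <- segment_kidney(map, "left", whole)
  expect_false(any(seg$cortex & seg$medulla))
  expect_true(all(which(seg$cortex | seg$medulla) %in% which(whole)))
  expect_gt(seg$cluster_means["cortex"], seg$cluster_means["medulla"])
  # with reassignment the clustered voxels are fully partitioned
  seg2 <- segment_kidney(map, "left", whole, reassign = "cortex")
  expect_true(all((seg2$cortex | seg2$medulla)[whole]))
})

test_that("segmentation is side-symmetric under mirroring", {
  whole <- disk_mask()
  set.seed(11)
  rbf <- matrix(0, 30, 30)
  inner <- disk_mask(r = 5)
  rbf[whole] <- rnorm(sum(whole), 250, 20)
  rbf[inner] <- rnorm(sum(inner), 50, 10)
  map_l <- structure(list(rbf = rbf), class = "perfusion_map")
  map_r <- structure(list(rbf = rbf[, 30:1]), class = "perfusion_map")
  seg_l <- segment_kidney(map_l, "left", whole)
  seg_r <- segment_kidney(map_r, "right", whole[, 30:1])
  expect_identical(seg_r$medulla, seg_l$medulla[, 30:1])
  expect_identical(seg_r$cortex, seg_l$cortex[, 30:1])
})
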