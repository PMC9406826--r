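test_that("phantom construction is deterministic and scenario-aware", {
  s1 <- build_phantom(1, "healthy", grid_shape = small_grid)
  s2 <- build_phantom(1, "healthy", grid_shape = small_grid)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$perfusion_gt, s2$perfusion_gt)
  expect_identical(s1$texture, s2$texture)

  expect_setequal(unique(as.vector(s1$perfusion_gt)), c(0, 50, 250))
  ab <- build_phantom(1, "abnormal_right", grid_shape = small_grid)
  expect_setequal(unique(as.vector(ab$perfusion_gt)), c(0, 20, 50, 100, 250))
  expect_true(all(ab$perfusion_gt[ab$organ_masks$cortex_right] == 100))
  expect_true(all(ab$perfusion_gt[ab$organ_masks$medulla_right] == 20))
  expect_true(all(ab$perfusion_gt[ab$organ_masks$cortex_left] == 250))

  # different seeds give different anatomy
  s3 <- build_phantom(2, "healthy", grid_shape = small_grid)
  expect_false(identical(s1$labels, s3$labels))
})

test_that("perfusion ground truth equals the tissue table value voxelwise", {
  s <- build_phantom(3, "healthy", grid_shape = small_grid)
  tab <- s$tissue_table
  for (nm in c("cortex_left", "medulla_right")) {
    id <- tab$tissue_id[tab$name == nm]
    expect_true(all(s$perfusion_gt[s$labels == id] ==
                      tab$perfusion[tab$name == nm]))
    expect_true(all(s$att_gt[s$labels == id] == tab$att_ms[tab$name == nm]))
  }
})

test_that("mask algebra holds for every model seed", {
  for (seed in 1:100) {
    s <- build_phantom(seed, "healthy", grid_shape = small_grid,
                       texture_amp = 0)
    m <- s$organ_masks
    expect_identical(m$cortex_left | m$medulla_left, m$kidney_left)
    expect_identical(m$cortex_right | m$medulla_right, m$kidney_right)
    expect_false(any(m$cortex_left & m$medulla_left))
    expect_false(any(m$cortex_right & m$medulla_right))
    expect_false(any(m$kidney_left & m$kidney_right))
  }
})

test_that("too-small grids are rejected with a sizing error", {
  expect_error(build_phantom(1, "healthy", grid_shape = c(20, 20, 8)),
               "grid too small")
})

test_that("oblique slices are deterministic and label-closed", {
  s <- build_phantom(1, "healthy", grid_shape = small_grid)
  a <- extract_oblique_slice(s, 12, "labels", displacement_mm = 0)
  b <- extract_oblique_slice(s, 12, "labels", displacement_mm = 0)
  expect_identical(a$image, b$image)
  expect_true(all(unique(as.vector(a$image)) %in% s$tissue_table$tissue_id))
  expect_error(extract_oblique_slice(s, 95), "rotation_deg")
})

test_that("craniocaudal displacement shifts the slice content by d / spacing", {
  s <- build_phantom(1, "healthy", grid_shape = small_grid)
  centroid_row <- function(d) {
    sl <- extract_oblique_slice(s, 0, "labels", displacement_mm = d)
    mean(which(sl$masks$kidney_left, arr.ind = TRUE)[, 1])
  }
  shift <- centroid_row(6) - centroid_row(0)
  expect_equal(shift, 6 / 3, tolerance = 0.25)
})

test_that("a slice missing both kidneys raises an error", {
  s <- build_phantom(1, "healthy", grid_shape = small_grid)
  expect_error(extract_oblique_slice(s, 12, displacement_mm = 500),
               "misses both kidneys")
})

test_that("tissue table invariants are enforced", {
  tab <- default_tissue_table()
  expect_true(all(tab$rho >= 0 & tab$rho <= 1))
  perfused <- tab$name[tab$perfusion > 0]
  expect_true(all(grepl("^(cortex|medulla)_", perfused)))
  bad <- tab
  bad$perfusion[bad$name == "liver"] <- 10
  expect_error(validate_tissue_table(bad), "cortex/medulla")
})
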