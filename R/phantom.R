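#' Build a procedural abdominal label phantom with paired kidneys
#'
#' Constructs a 3-D tissue-label volume containing a soft-tissue torso, two
#' bean-shaped kidneys (a cortical shell of at least two voxels around a
#' medullary interior, with a hilar notch filled by fluid-like pelvis
#' tissue), a liver adjacent to the right kidney and a spleen adjacent to
#' the left kidney, plus voxelwise ground-truth perfusion and arterial
#' transit time maps. The phantom axes are: first index left-right (index 1
#' = subject's right), second anterior-posterior, third craniocaudal.
#'
#' `model_seed` deterministically jitters kidney size (within +/-15
#' percent), position (within +/-10 mm) and long-axis orientation, so seeds
#' 1-5 play the role of five distinct body models with different organ
#' sizes and shapes.
#'
#' @param model_seed integer seed selecting the anatomy variant.
#' @param scenario `"healthy"` (cortex 250 / medulla 50 mL/100 g/min
#'   bilaterally) or `"abnormal_right"` (right kidney 100 / 20).
#' @param grid_shape integer 3-vector of voxel counts, default
#'   `c(96, 96, 32)`.
#' @param voxel_size_mm numeric 3-vector of voxel spacings in mm, default
#'   `c(3, 3, 5)`.
#' @param tissue_table optional tissue property table; defaults to
#'   [default_tissue_table()] for the scenario.
#' @param texture_amp relative standard deviation of the smooth
#'   multiplicative intra-tissue signal heterogeneity field (default 0.25,
#'   i.e. 25 percent). Real parenchyma is not uniform; this static field
#'   travels with the phantom, giving image-similarity metrics and the
#'   registration the kind of structure in-vivo images provide. Set to 0
#'   for perfectly uniform tissue.
#' @param texture_sigma_vox Gaussian correlation length of the texture
#'   field in voxels per axis.
#' @return An object of class `phantom_scene` with elements `labels`
#'   (integer 3-D array), `voxel_size_mm`, `tissue_table`, `organ_masks`
#'   (logical 3-D arrays: `kidney_left`, `kidney_right`, `cortex_left`,
#'   `cortex_right`, `medulla_left`, `medulla_right`), `perfusion_gt`,
#'   `att_gt`, `kidney_centers_mm`, `model_seed`, `scenario`.
#' @export
#' @examples
#' scene <- build_phantom(1, "healthy", grid_shape = c(64, 64, 24))
#' table(scene$perfusion_gt[scene$organ_masks$kidney_left])
build_phantom <- function(model_seed = 1L,
                          scenario = c("healthy", "abnormal_right"),
                          grid_shape = c(96L, 96L, 32L),
                          voxel_size_mm = c(3, 3, 5),
                          tissue_table = NULL,
                          texture_amp = 0.25,
                          texture_sigma_vox = c(1, 1, 1)) {
  scenario <- match.arg(scenario)
  stopifnot(length(grid_shape) == 3, length(voxel_size_mm) == 3)
  grid_shape <- as.integer(grid_shape)
  tissue_table <- tissue_table %||% default_tissue_table(scenario)
  validate_tissue_table(tissue_table)

  # anatomy jitter: five seeds emulate five body models
  jit <- withr::with_seed(model_seed, list(
    size_l = stats::runif(1, 0.85, 1.15),
    size_r = stats::runif(1, 0.85, 1.15),
    pos_l = stats::runif(3, -10, 10),
    pos_r = stats::runif(3, -10, 10),
    tilt_l = stats::runif(1, -10, 10),
    tilt_r = stats::runif(1, -10, 10),
    texture_raw = array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  ))
  texture <- array(1, dim = grid_shape)
  if (texture_amp > 0) {
    f <- smooth3d(jit$texture_raw, texture_sigma_vox)
    texture <- pmax(1 + texture_amp * f / stats::sd(f), 0.2)
  }

  ext <- grid_shape * voxel_size_mm
  # voxel-centre coordinates in mm, origin at the volume centre
  cx <- (seq_len(grid_shape[1]) - (grid_shape[1] + 1) / 2) * voxel_size_mm[1]
  cy <- (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * voxel_size_mm[2]
  cz <- (seq_len(grid_shape[3]) - (grid_shape[3] + 1) / 2) * voxel_size_mm[3]
  X <- array(rep(cx, times = grid_shape[2] * grid_shape[3]), dim = grid_shape)
  Y <- array(rep(rep(cy, each = grid_shape[1]), times = grid_shape[3]),
             dim = grid_shape)
  Z <- array(rep(cz, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)

  labels <- array(0L, dim = grid_shape)
  body <- (X / (0.47 * ext[1]))^2 + (Y / (0.40 * ext[2]))^2 <= 1
  labels[body] <- 1L

  id <- function(nm) tissue_table$tissue_id[tissue_table$name == nm]

  # liver on the subject's right (low x), superior; spleen on the left
  liver <- ellipsoid_mask(X, Y, Z, c(-0.22 * ext[1], -8, 0.28 * ext[3]),
                          c(55, 42, 48))
  spleen <- ellipsoid_mask(X, Y, Z, c(0.24 * ext[1], -6, 0.24 * ext[3]),
                           c(28, 24, 34))
  labels[liver & body] <- id("liver")
  labels[spleen & body] <- id("spleen")

  base_semi <- c(24, 19, 54)   # ~5 x 4 x 11 cm kidney
  kid <- list(
    left = kidney_compartments(X, Y, Z,
      center = c(0.19 * ext[1], 8, 0) + jit$pos_l,
      semi = base_semi * jit$size_l, tilt_deg = jit$tilt_l, side = "left"),
    right = kidney_compartments(X, Y, Z,
      center = c(-0.19 * ext[1], 8, 0) + jit$pos_r,
      semi = base_semi * jit$size_r, tilt_deg = jit$tilt_r, side = "right")
  )
  check_kidney_fit(kid, grid_shape)

  for (side in c("left", "right")) {
    k <- kid[[side]]
    labels[k$pelvis] <- id("pelvis")
    labels[k$cortex] <- id(paste0("cortex_", side))
    labels[k$medulla] <- id(paste0("medulla_", side))
  }

  organ_masks <- list(
    kidney_left = kid$left$whole, kidney_right = kid$right$whole,
    cortex_left = kid$left$cortex, cortex_right = kid$right$cortex,
    medulla_left = kid$left$medulla, medulla_right = kid$right$medulla
  )

  structure(list(
    labels = labels,
    texture = texture,
    voxel_size_mm = voxel_size_mm,
    tissue_table = tissue_table,
    organ_masks = organ_masks,
    perfusion_gt = lookup_tissue(labels, tissue_table, "perfusion"),
    att_gt = lookup_tissue(labels, tissue_table, "att_ms"),
    kidney_centers_mm = rbind(left = kid$left$center, right = kid$right$center),
    model_seed = model_seed,
    scenario = scenario
  ), class = "phantom_scene")
}

ellipsoid_mask <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

# bean = ellipsoid minus a medial notch ellipsoid; medulla is the same bean
# shrunk so the cortex shell is >= 2 voxels thick everywhere; the carved
# notch within the outer ellipsoid becomes fluid-like pelvis tissue
kidney_compartments <- function(X, Y, Z, center, semi, tilt_deg, side) {
  th <- tilt_deg * pi / 180
  # rotate about the anterior-posterior axis (y): tilts the long axis in the
  # coronal plane
  xr <- (X - center[1]) * cos(th) - (Z - center[3]) * sin(th)
  yr <- Y - center[2]
  zr <- (X - center[1]) * sin(th) + (Z - center[3]) * cos(th)
  medial <- if (side == "left") -1 else 1   # toward the body midline
  notch_c <- c(medial * semi[1], 0, 0)
  notch_semi <- c(0.65, 0.85, 0.45) * semi

  inside <- function(s, nc, ns) {
    ((xr / s[1])^2 + (yr / s[2])^2 + (zr / s[3])^2 <= 1) &
      !(((xr - nc[1]) / ns[1])^2 + ((yr - nc[2]) / ns[2])^2 +
          ((zr - nc[3]) / ns[3])^2 <= 1)
  }
  # cortical thickness ~9 mm (incl. columns) at the base kidney size,
  # scaled with the organ so jittered models keep their medulla fraction
  shrink <- semi * c(9 / 24, 9 / 19, 12 / 54)
  whole <- inside(semi, notch_c, notch_semi)
  medulla <- inside(pmax(semi - shrink, 1), notch_c, notch_semi + shrink / 2)
  medulla <- medulla & whole
  outer_ell <- (xr / semi[1])^2 + (yr / semi[2])^2 + (zr / semi[3])^2 <= 1
  pelvis <- outer_ell & !whole
  list(whole = whole, cortex = whole & !medulla, medulla = medulla,
       pelvis = pelvis, center = center)
}

check_kidney_fit <- function(kid, grid_shape) {
  for (side in c("left", "right")) {
    m <- kid[[side]]$whole
    if (!any(m))
      stop_renasl("grid too small: the ", side, " kidney does not fit; ",
                  "increase grid_shape (>= 64 x 64 x 24 recommended)")
    w <- which(m, arr.ind = TRUE)
    if (any(w == 1) || any(t(t(w) - grid_shape) == 0))
      stop_renasl("grid too small: the ", side, " kidney touches the volume ",
                  "border; increase grid_shape (>= 64 x 64 x 24 recommended)")
  }
  if (any(kid$left$whole & kid$right$whole))
    stop_renasl("left and right kidneys overlap; increase grid_shape")
  invisible(TRUE)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene seed=%d scenario=%s grid=%s voxel=%s mm>\n",
              x$model_seed, x$scenario,
              paste(dim(x$labels), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  nv <- vapply(x$organ_masks, sum, numeric(1))
  cat("  organ voxels:", paste(names(nv), nv, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Extract a coronal-oblique 2-D slice through the kidneys
#'
#' Samples a single slice from a phantom volume on an in-plane grid whose
#' columns run along the left-right axis and whose rows run along the
#' craniocaudal axis tilted by `rotation_deg` about the left-right axis
#' (rows increase toward the head). A craniocaudal `displacement_mm` is
#' applied to the phantom *before* slicing, so through-plane motion changes
#' the in-plane organ cross-section, as it does for an oblique slice of a
#' moving abdomen. Label fields and masks are resampled nearest-neighbour;
#' continuous maps trilinearly.
#'
#' @param scene a [build_phantom()] result.
#' @param rotation_deg slice tilt about the left-right axis in degrees
#'   (|angle| < 90), default 12.
#' @param field `"labels"`, `"perfusion_gt"` or `"att_gt"`.
#' @param displacement_mm craniocaudal shift of the phantom in mm.
#' @param in_plane_mm in-plane pixel spacing (row, column) in mm.
#' @return list with `image` (2-D matrix; integer labels or map values),
#'   `masks` (list of 2-D logical organ masks), `spacing_mm`, `rotation_deg`,
#'   `displacement_mm`.
#' @export
extract_oblique_slice <- function(scene, rotation_deg = 12,
                                  field = c("labels", "perfusion_gt", "att_gt"),
                                  displacement_mm = 0,
                                  in_plane_mm = c(3, 3)) {
  stopifnot(inherits(scene, "phantom_scene"))
  field <- match.arg(field)
  if (abs(rotation_deg) >= 90)
    stop_renasl("|rotation_deg| must be < 90")
  g <- slice_grid(scene, rotation_deg, in_plane_mm)
  pts <- slice_points(scene, g, displacement_mm)
  arr <- scene[[field]]
  method <- if (field == "labels") "nearest" else "linear"
  img <- matrix(interp3(arr, pts, method = method, fill = 0),
                nrow = g$nrow, ncol = g$ncol)
  masks <- lapply(scene$organ_masks, function(m) {
    matrix(interp3(m + 0, pts, method = "nearest", fill = 0) > 0.5,
           nrow = g$nrow, ncol = g$ncol)
  })
  if (!any(masks$kidney_left) && !any(masks$kidney_right))
    stop_renasl("the requested slice misses both kidneys")
  list(image = img, masks = masks, spacing_mm = in_plane_mm,
       rotation_deg = rotation_deg, displacement_mm = displacement_mm)
}

# fixed slice grid for a scene: centred on the mid-point between the two
# kidney centres, covering the full left-right and craniocaudal extent
slice_grid <- function(scene, rotation_deg, in_plane_mm) {
  ext <- dim(scene$labels) * scene$voxel_size_mm
  ncol <- floor(ext[1] / in_plane_mm[2])
  nrow <- floor(ext[3] / in_plane_mm[1])
  c0 <- colMeans(scene$kidney_centers_mm)
  th <- rotation_deg * pi / 180
  list(nrow = nrow, ncol = ncol,
       c0 = c(0, c0[2], 0),                     # centre in mm coordinates
       e_col = c(1, 0, 0),
       e_row = c(0, -sin(th), cos(th)),
       in_plane_mm = in_plane_mm)
}

slice_points <- function(scene, g, displacement_mm) {
  u <- (seq_len(g$ncol) - (g$ncol + 1) / 2) * g$in_plane_mm[2]
  v <- (seq_len(g$nrow) - (g$nrow + 1) / 2) * g$in_plane_mm[1]
  U <- rep(u, each = g$nrow)
  V <- rep(v, times = g$ncol)
  p <- cbind(g$c0[1] + U * g$e_col[1] + V * g$e_row[1],
             g$c0[2] + U * g$e_col[2] + V * g$e_row[2],
             g$c0[3] + U * g$e_col[3] + V * g$e_row[3])
  p[, 3] <- p[, 3] - displacement_mm   # phantom shifted +z => sample at z - d
  idx <- mm_to_index(scene, p)
  # the abdomen continues beyond the simulated volume: clamp the
  # craniocaudal coordinate so motion does not flow "air" into the slice
  idx[, 3] <- pmin(pmax(idx[, 3], 1), dim(scene$labels)[3])
  idx
}

mm_to_index <- function(scene, p) {
  d <- dim(scene$labels)
  sweep(sweep(p, 2, scene$voxel_size_mm, "/"), 2, (d + 1) / 2, "+")
}
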