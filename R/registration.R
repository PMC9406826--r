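#' Crop an ASL series around one kidney
#'
#' Registration is run separately per kidney on a rectangular crop. With
#' `box = "auto"` the crop is derived from the temporal-mean image: light
#' smoothing, thresholding at 90 percent of the (robust) maximum — the
#' kidney parenchyma is the brightest large structure on the spin-echo
#' images — connected components, selection of the largest component on
#' the requested side, and padding by `pad` voxels. A manual
#' `box = c(row_min, row_max, col_min, col_max)` passes through unchanged.
#'
#' Side convention: image columns run along the left-right axis with the
#' subject's right on low column indices, so the right kidney occupies the
#' left half of the image.
#'
#' @param series an [simulate_series()] result.
#' @param side `"left"` or `"right"`.
#' @param box `"auto"` or an integer 4-vector `c(r0, r1, c0, c1)`.
#' @param pad padding in voxels for the auto box, default 5.
#' @return object of class `asl_crop`: `frames` (raw frames, cropped, in
#'   acquisition order), `box`, `side`, `frame_order`, `gt_masks`
#'   (per-frame organ masks cropped to the box), `spacing_mm`, `protocol`.
#' @export
crop_kidney <- function(series, side = c("left", "right"), box = "auto",
                        pad = 5L) {
  side <- match.arg(side)
  frames <- series_frames(series)
  d <- dim(frames)
  if (identical(box, "auto")) {
    # the kidneys are the only perfused structures: the temporal mean
    # control-minus-label image lights them up regardless of the
    # anatomical background, noise or intra-tissue texture
    md <- mean_difference(frames)
    # strong smoothing kills thin residual-motion edge artifacts while the
    # broad kidney blob survives
    sm <- smooth2d(md$delta_m, 3)
    half <- if (side == "left") col(sm) > d[2] / 2 else col(sm) <= d[2] / 2
    mask <- sm > 0.4 * max(sm[half]) & half
    lab <- label_components(mask)
    n_comp <- max(lab)
    sizes <- tabulate(lab[lab > 0])
    if (!n_comp || max(sizes) < 10)
      stop_renasl("auto crop found no kidney-sized component on the ", side,
                  " side; pass a manual box")
    # the kidney is the component with the most integrated difference signal
    totals <- vapply(seq_len(n_comp), function(k) sum(sm[lab == k]),
                     numeric(1))
    comp <- lab == which.max(totals)
    if (sum(comp) < 10)
      stop_renasl("auto crop found no kidney-sized component on the ", side,
                  " side; pass a manual box")
    w <- which(comp, arr.ind = TRUE)
    box <- c(max(1L, min(w[, 1]) - pad), min(d[1], max(w[, 1]) + pad),
             max(1L, min(w[, 2]) - pad), min(d[2], max(w[, 2]) + pad))
    # never smaller than the SSIM window used downstream
    box <- widen_box(box, 16L, d)
  } else {
    box <- as.integer(box)
    if (length(box) != 4 || box[1] < 1 || box[3] < 1 ||
        box[2] > d[1] || box[4] > d[2] || box[1] > box[2] || box[3] > box[4])
      stop_renasl("box must be c(r0, r1, c0, c1) within the image bounds")
  }
  rows <- box[1]:box[2]; cols <- box[3]:box[4]
  structure(list(
    frames = frames[rows, cols, , drop = FALSE],
    box = box, side = side,
    frame_order = series$frame_order,
    gt_masks = lapply(series$gt_masks, function(ms)
      lapply(ms, function(m) m[rows, cols, drop = FALSE])),
    spacing_mm = series$protocol$voxel_mm[1:2],
    protocol = series$protocol
  ), class = "asl_crop")
}

#' PCA-based groupwise dissimilarity (PCAMetric2)
#'
#' The groupwise alignment criterion: the G x G correlation matrix of the
#' frame intensities is eigendecomposed and the metric is the
#' rank-weighted eigenvalue sum `sum_j j * lambda_j` with eigenvalues
#' sorted in descending order. Well-aligned stacks concentrate variance in
#' the leading components (low weights), so lower is better; the trace
#' constraint `sum_j lambda_j = G` always holds. Constant (zero-variance)
#' frames make the correlation undefined: an all-constant stack returns
#' the uniform-eigenvalue fallback `G * (G + 1) / 2` with a warning.
#'
#' @param frames 3-D array `rows x cols x G` (G >= 2) or an `N x G` matrix
#'   of intensities.
#' @return scalar dissimilarity.
#' @export
#' @examples
#' x <- array(rep(matrix(runif(100), 10), 4), c(10, 10, 4))
#' pca_groupwise_metric(x)   # identical frames: metric = G = 4
pca_groupwise_metric <- function(frames) {
  M <- if (length(dim(frames)) == 3) {
    matrix(frames, ncol = dim(frames)[3])
  } else as.matrix(frames)
  G <- ncol(M)
  if (G < 2) stop_renasl("need at least 2 frames")
  sds <- apply(M, 2, stats::sd)
  if (all(sds < 1e-12)) {
    warning("all frames are constant; returning the uniform-eigenvalue fallback")
    return(G * (G + 1) / 2)
  }
  res <- pca_metric_cpp(M)
  if (res$degenerate)
    warning("constant frame(s) in the stack; their correlations were treated as zero")
  res$metric
}

#' Default groupwise registration settings
#'
#' Six multi-resolution levels defined by Gaussian pre-smoothing sigmas
#' (10, 8, 2, 4, 2, 1 voxels), cubic B-spline free-form deformations with
#' a control-point spacing of 8 voxels at the finest level (doubled per
#' coarser level), and an adaptive stochastic gradient descent with 800
#' iterations per level sampling 50 percent of the crop voxels per
#' iteration.
#'
#' @param ... overrides (`sigmas`, `grid_spacing`, `iterations`,
#'   `subsample`, `step0`, `decay_A`, `decay_alpha`, `max_update`, `seed`).
#' @return named list of settings.
#' @export
registration_settings <- function(...) {
  s <- list(sigmas = c(10, 8, 2, 4, 2, 1), grid_spacing = 8L,
            iterations = 800L, subsample = 0.5, step0 = 1.0,
            decay_A = 20, decay_alpha = 0.602, max_update = 0.5,
            bend_weight = 0.005, split_weight = 1.0, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(s))
  if (length(unknown))
    stop_renasl("unknown registration setting(s): ",
                paste(unknown, collapse = ", "))
  s[names(dots)] <- dots
  s
}

#' Groupwise motion correction of an ASL frame stack
#'
#' Jointly optimises one free-form B-spline deformation per frame against
#' the [pca_groupwise_metric()] with a zero-mean-displacement constraint
#' over frames, so the stack converges to an implicit mean image rather
#' than to any single reference frame. Multi-resolution is realised by
#' Gaussian pre-smoothing of the frames with the per-level sigmas;
#' intensities are interpolated with cubic B-splines. The optimisation is
#' a seeded adaptive stochastic gradient descent on a random voxel subset
#' per iteration, hence deterministic for a fixed seed.
#'
#' @param cropped an [crop_kidney()] result, or a plain 3-D frame array.
#' @param settings a [registration_settings()] list.
#' @return object of class `registration_result`: `aligned` (frames after
#'   correction), `deformations` (`rows x cols x 2 x G` voxel displacement
#'   field, components row/col; multiply by `spacing_mm` for mm),
#'   `metric_trace` (iterations x levels), `crop_box`, `settings`,
#'   `frame_order`, `spacing_mm`.
#' @export
register_groupwise <- function(cropped, settings = registration_settings()) {
  if (inherits(cropped, "asl_crop")) {
    frames <- cropped$frames
    box <- cropped$box
    frame_order <- cropped$frame_order
    spacing <- cropped$spacing_mm
  } else {
    frames <- cropped
    box <- c(1L, dim(frames)[1], 1L, dim(frames)[2])
    frame_order <- NULL
    spacing <- c(1, 1)
  }
  d <- dim(frames)
  if (length(d) != 3 || d[3] < 2) stop_renasl("need a stack of >= 2 frames")
  n_levels <- length(settings$sigmas)
  spacings <- settings$grid_spacing * 2^(rev(seq_len(n_levels)) - 1)
  smoothed <- lapply(settings$sigmas, function(sg) {
    out <- frames
    for (g in seq_len(d[3])) out[, , g] <- smooth2d(frames[, , g], sg)
    out
  })
  res <- gw_register_cpp(frames, smoothed, as.integer(spacings),
                         as.integer(settings$iterations),
                         settings$subsample, as.integer(settings$seed),
                         settings$step0, settings$decay_A,
                         settings$decay_alpha, settings$max_update,
                         settings$bend_weight,
                         frame_type_codes(frame_order, d[3]),
                         settings$split_weight)
  trace <- res$metric_trace
  check_descent(trace)
  defo <- array(0, c(d[1], d[2], 2, d[3]))
  defo[, , 1, ] <- res$u_row
  defo[, , 2, ] <- res$u_col
  structure(list(
    aligned = res$aligned,
    deformations = defo,
    metric_trace = trace,
    crop_box = box,
    settings = settings,
    frame_order = frame_order,
    spacing_mm = spacing
  ), class = "registration_result")
}

widen_box <- function(box, min_size, d) {
  for (k in c(1L, 3L)) {
    lo <- box[k]; hi <- box[k + 1L]; n <- d[(k + 1L) %/% 2L]
    while (hi - lo + 1L < min_size) {
      if (lo > 1L) lo <- lo - 1L
      if (hi < n) hi <- hi + 1L
      if (lo == 1L && hi == n) break
    }
    box[k] <- lo; box[k + 1L] <- hi
  }
  box
}

frame_type_codes <- function(frame_order, n) {
  if (is.null(frame_order)) return(integer(n))
  match(frame_order, c("m0", "control", "label")) - 1L
}

check_descent <- function(trace) {
  for (lev in seq_len(ncol(trace))) {
    tr <- trace[, lev]
    tr <- tr[is.finite(tr)]
    if (length(tr) < 10) next
    n <- length(tr)
    first <- stats::median(tr[seq_len(max(5, n %/% 5))])
    last <- stats::median(tr[(n - max(5, n %/% 5) + 1):n])
    if (last > 1.10 * first)
      stop_renasl(sprintf(
        "registration diverged at level %d (metric %.3f -> %.3f); trace: %s",
        lev, first, last, paste(round(tr, 2), collapse = " ")))
  }
  invisible(TRUE)
}

#' Apply a per-frame deformation to an image
#'
#' Pull-back warp `out(x) = img(x + u(x))` with cubic B-spline (default)
#' or bilinear interpolation. Applying frame k's deformation to raw frame
#' k reproduces the aligned frame k.
#'
#' @param img 2-D image.
#' @param deformation `rows x cols x 2` voxel displacement field.
#' @param interp `"cubic"` or `"linear"`.
#' @return warped 2-D image.
#' @export
apply_deformation <- function(img, deformation, interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  if (!all(dim(img) == dim(deformation)[1:2]))
    stop_renasl("deformation grid does not match the image")
  if (interp == "cubic") {
    bspline_warp_cpp(img, deformation[, , 1], deformation[, , 2])
  } else {
    warp_image_linear(img, deformation)
  }
}

#' Jacobian determinant of a deformation field
#'
#' Determinant of the spatial Jacobian of `x + u(x)` by central finite
#' differences; values > 0 indicate a locally invertible (fold-free)
#' deformation.
#'
#' @param deformation `rows x cols x 2` voxel displacement field.
#' @return 2-D matrix of determinants.
#' @export
jacobian_determinant <- function(deformation) {
  ur <- deformation[, , 1]; uc <- deformation[, , 2]
  d1 <- function(m, along) {
    n <- dim(m)[along]
    idx_p <- pmin(seq_len(n) + 1, n)
    idx_m <- pmax(seq_len(n) - 1, 1)
    den <- idx_p - idx_m
    if (along == 1) (m[idx_p, ] - m[idx_m, ]) / den
    else t(t(m[, idx_p] - m[, idx_m]) / den)
  }
  (1 + d1(ur, 1)) * (1 + d1(uc, 2)) - d1(ur, 2) * d1(uc, 1)
}

#' @export
print.registration_result <- function(x, ...) {
  tr <- x$metric_trace
  cat(sprintf(
    "<registration_result %d frames, crop %s, metric %.2f -> %.2f>\n",
    dim(x$aligned)[3], paste(x$crop_box, collapse = ":"),
    tr[1, 1], tr[nrow(tr), ncol(tr)]))
  invisible(x)
}
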