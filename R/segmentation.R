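#' Whole-kidney mask on the M0 image
#'
#' The pipeline takes the whole-kidney outline as an input: either a mask
#' drawn by an operator (`mode = "provided"`) or, for fully synthetic
#' benchmarking, an emulation of manual drawing (`mode = "emulated_manual"`)
#' that perturbs the ground-truth mask by adding each boundary voxel of the
#' one-voxel dilation ring with probability 0.5 (seeded), mimicking the
#' over-inclusion of a hand-drawn contour.
#'
#' @param m0 M0 image (used for grid checking only).
#' @param side `"left"` or `"right"` (bookkeeping).
#' @param mode `"provided"` or `"emulated_manual"`.
#' @param provided_mask 2-D logical mask when `mode = "provided"`.
#' @param gt_mask ground-truth 2-D logical mask when
#'   `mode = "emulated_manual"`.
#' @param seed seed for the boundary perturbation.
#' @return 2-D logical mask.
#' @export
whole_kidney_mask <- function(m0, side = c("left", "right"),
                              mode = c("provided", "emulated_manual"),
                              provided_mask = NULL, gt_mask = NULL,
                              seed = 1L) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  if (mode == "provided") {
    if (is.null(provided_mask)) stop_renasl("provided_mask is required")
    if (!all(dim(provided_mask) == dim(m0)))
      stop_renasl("provided_mask does not match the image grid")
    if (!any(provided_mask)) stop_renasl("provided whole-kidney mask is empty")
    return(provided_mask)
  }
  if (is.null(gt_mask)) stop_renasl("gt_mask is required for emulated_manual")
  if (!any(gt_mask)) stop_renasl("ground-truth whole-kidney mask is empty")
  ring <- binary_dilate(gt_mask, se_disk1(), c(2L, 2L)) & !gt_mask
  add <- withr::with_seed(seed, stats::runif(sum(ring)) < 0.5)
  out <- gt_mask
  out[which(ring)[add]] <- TRUE
  out
}

se_disk1 <- function() matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3) > 0

# binary morphology with an explicit structuring-element origin
se_offsets <- function(se, origin) {
  w <- which(se > 0, arr.ind = TRUE)
  cbind(w[, 1] - origin[1], w[, 2] - origin[2])
}

#' Binary erosion/dilation with an explicit origin
#'
#' Direct set-definition morphology: erosion keeps a pixel when the
#' structuring element, centred at its origin on that pixel, lies entirely
#' inside the mask (pixels outside the image count as background);
#' dilation marks every pixel reached by the reflected element.
#'
#' @param mask 2-D logical matrix.
#' @param se structuring element (logical/0-1 matrix).
#' @param origin 1-based (row, col) of the element origin.
#' @return 2-D logical matrix.
#' @export
binary_erode <- function(mask, se, origin) {
  off <- se_offsets(se, origin)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  idx <- which(mask | !mask, arr.ind = TRUE)
  for (k in seq_len(nrow(off))) {
    i <- idx[, 1] + off[k, 1]
    j <- idx[, 2] + off[k, 2]
    inside <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
    v <- rep(FALSE, nrow(idx))
    v[inside] <- mask[cbind(i[inside], j[inside])]
    out <- out & matrix(v, nrow(mask), ncol(mask))
  }
  out
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask, se, origin) {
  off <- -se_offsets(se, origin)   # reflected element
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  for (k in seq_len(nrow(off))) {
    i <- idx[, 1] + off[k, 1]
    j <- idx[, 2] + off[k, 2]
    inside <- i >= 1 & i <= nrow(mask) & j >= 1 & j <= ncol(mask)
    out[cbind(i[inside], j[inside])] <- TRUE
  }
  out
}

#' Cortex/medulla separation by two-cluster k-means on the perfusion map
#'
#' Runs 1-D k-means (k = 2, Lloyd iterations) on the quantified perfusion
#' values inside the whole-kidney mask. Initial centres are placed
#' deterministically at the 10th and 90th percentiles of the masked values;
#' the cluster with the higher mean perfusion becomes the cortex. If all
#' masked values are identical the clustering is degenerate: the whole mask
#' is returned as cortex with an empty medulla and a warning.
#'
#' Voxels whose quantified perfusion falls outside `rbf_range` are
#' physiologically implausible (residual-motion artifacts at strong edges)
#' and are excluded from the clustering; they belong to neither output
#' mask. Set `rbf_range = NULL` to cluster every finite voxel.
#'
#' @param rbf a [quantify()] result or a 2-D perfusion matrix.
#' @param whole 2-D logical whole-kidney mask (>= 4 voxels).
#' @param iter_max maximum Lloyd iterations, default 300.
#' @param rbf_range plausible perfusion interval in mL/100 g/min, default
#'   `c(-100, 600)`.
#' @return list with `cortex`, `medulla` (2-D logical masks) and
#'   `cluster_means` (named numeric: cortex, medulla).
#' @export
kmeans_cortex_medulla <- function(rbf, whole, iter_max = 300L,
                                  rbf_range = c(-100, 600)) {
  if (inherits(rbf, "perfusion_map")) rbf <- rbf$rbf
  if (!all(dim(rbf) == dim(whole)))
    stop_renasl("perfusion map and whole-kidney mask must share a grid")
  sel <- whole & is.finite(rbf)
  if (!is.null(rbf_range))
    sel <- sel & rbf >= rbf_range[1] & rbf <= rbf_range[2]
  if (sum(sel) < 4L) stop_renasl("whole-kidney mask has fewer than 4 usable voxels")
  x <- rbf[sel]
  if (diff(range(x)) == 0) {
    warning("constant perfusion inside the kidney mask; ",
            "returning whole mask as cortex and empty medulla")
    empty <- matrix(FALSE, nrow(whole), ncol(whole))
    return(list(cortex = whole, medulla = empty,
                cluster_means = c(cortex = x[1], medulla = NA_real_)))
  }
  centers <- stats::quantile(x, c(0.9, 0.1), names = FALSE)
  if (diff(centers) == 0) centers <- range(x)[2:1]
  km <- suppressWarnings(
    stats::kmeans(x, centers = matrix(centers, ncol = 1),
                  iter.max = iter_max, algorithm = "Lloyd"))
  hi <- which.max(km$centers)
  cortex <- medulla <- matrix(FALSE, nrow(whole), ncol(whole))
  cortex[sel] <- km$cluster == hi
  medulla[sel] <- km$cluster != hi
  list(cortex = cortex, medulla = medulla,
       cluster_means = c(cortex = km$centers[hi],
                         medulla = km$centers[-hi][1]))
}

#' Side-specific structuring elements for the medulla cleanup
#'
#' The 4 x 5 diagonal elements used to erode the whole-kidney mask before
#' cleaning the medulla mask; the diagonal runs opposite ways for the left
#' and right kidney to follow the organs' oblique lower borders. The
#' element origin sits at row 2, column 3.
#'
#' @param side `"left"` or `"right"`.
#' @return 4 x 5 0/1 matrix.
#' @export
medulla_structuring_element <- function(side = c("left", "right")) {
  side <- match.arg(side)
  left <- rbind(c(0, 0, 0, 1, 1),
                c(0, 0, 1, 0, 0),
                c(0, 1, 1, 0, 0),
                c(1, 1, 0, 0, 0))
  right <- rbind(c(1, 1, 0, 0, 0),
                 c(0, 0, 1, 0, 0),
                 c(0, 0, 1, 1, 0),
                 c(0, 0, 0, 1, 1))
  if (side == "left") left else right
}

#' Clean the medulla mask by erosion of the whole-kidney mask
#'
#' Erodes the whole-kidney mask with the side-specific structuring element
#' and keeps only medulla voxels inside the eroded mask, removing spurious
#' medulla assignments on the outer kidney rim. Removed voxels are
#' dropped by default; `reassign = "cortex"` adds them to the cortex so
#' that cortex and medulla still partition the clustered voxels.
#'
#' @param medulla,whole,cortex 2-D logical masks on one grid.
#' @param side `"left"` or `"right"`.
#' @param reassign `"cortex"` or `"discard"`.
#' @return list with updated `cortex` and `medulla` masks.
#' @export
erode_medulla <- function(medulla, whole, cortex, side = c("left", "right"),
                          reassign = c("discard", "cortex")) {
  side <- match.arg(side)
  reassign <- match.arg(reassign)
  stopifnot(all(dim(medulla) == dim(whole)), all(dim(cortex) == dim(whole)))
  eroded <- binary_erode(whole, medulla_structuring_element(side),
                         origin = c(2L, 3L))
  kept <- medulla & eroded
  removed <- medulla & !eroded
  if (reassign == "cortex") cortex <- cortex | removed
  list(cortex = cortex, medulla = kept)
}

#' Segment one kidney into cortex and medulla
#'
#' Full semi-automatic segmentation of one side: whole-kidney mask
#' (provided or emulated-manual), two-cluster k-means on the perfusion map,
#' and erosion cleanup of the medulla.
#'
#' Voxels the erosion removes from the medulla mask are dropped by
#' default, following the rule that the clustered medulla mask is simply
#' multiplied by the eroded whole-kidney mask; `reassign = "cortex"` adds
#' them to the cortex instead, preserving the cluster partition.
#'
#' @param map a [quantify()] result.
#' @param side `"left"` or `"right"`.
#' @param whole 2-D logical whole-kidney mask for this side.
#' @param reassign see [erode_medulla()].
#' @return object of class `segmentation_result`: `whole`, `cortex`,
#'   `medulla`, `cluster_means`, `side`.
#' @export
segment_kidney <- function(map, side, whole, reassign = "discard") {
  km <- kmeans_cortex_medulla(map, whole)
  cleaned <- erode_medulla(km$medulla, whole, km$cortex, side = side,
                           reassign = reassign)
  structure(list(whole = whole, cortex = cleaned$cortex,
                 medulla = cleaned$medulla,
                 cluster_means = km$cluster_means, side = side),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result %s: whole=%d cortex=%d medulla=%d voxels, means %.0f/%.0f>\n",
    x$side, sum(x$whole), sum(x$cortex), sum(x$medulla),
    x$cluster_means[1], x$cluster_means[2]))
  invisible(x)
}
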