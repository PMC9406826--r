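#' Mean structural similarity index of two images
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5), stability
#' constants `k1 = 0.01`, `k2 = 0.03`, averaged over the valid interior of
#' the SSIM map (the border where the window does not fit is excluded).
#' The dynamic range should be the maximum intensity over the whole data
#' set being compared, not the per-pair range, so that comparisons against
#' the bright M0 frame are penalised consistently.
#'
#' @param a,b 2-D images of identical shape.
#' @param dynamic_range intensity range L; default `max(a, b)`.
#' @param win odd window width, default 11.
#' @param sigma Gaussian window sigma, default 1.5.
#' @param k1,k2 stability constants.
#' @return scalar in `[-1, 1]`.
#' @export
#' @examples
#' x <- matrix(runif(400), 20, 20)
#' mssim(x, x)   # 1
mssim <- function(a, b, dynamic_range = NULL, win = 11L, sigma = 1.5,
                  k1 = 0.01, k2 = 0.03) {
  if (!all(dim(a) == dim(b))) stop_renasl("images must share a grid")
  L <- dynamic_range %||% max(a, b)
  if (L <= 0) L <- 1
  r <- (win - 1L) %/% 2L
  if (nrow(a) < win || ncol(a) < win)
    stop_renasl("images smaller than the SSIM window")
  f <- valid_gauss_filter(nrow(a), ncol(a), r, sigma)
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  cab <- f(a * b) - mu_a * mu_b
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(ssim_map)
}

# separable 'valid' Gaussian filtering as two matrix products
valid_gauss_filter <- function(nr, nc, r, sigma) {
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  band <- function(n) {
    K <- matrix(0, n - 2 * r, n)
    for (i in seq_len(n - 2 * r)) K[i, i:(i + 2 * r)] <- k
    K
  }
  Kr <- band(nr); Kct <- t(band(nc))
  function(x) Kr %*% x %*% Kct
}

#' All-pairs MSSIM over a frame stack
#'
#' Computes the MSSIM for every unordered pair of frames, including
#' self-pairs by default (which contribute values of exactly 1); a 51-frame
#' series therefore yields `51 * 52 / 2 = 1326` values. The dynamic range
#' is fixed to the maximum over the whole stack.
#'
#' @param frames 3-D array `rows x cols x n`.
#' @param include_self include the `i == j` pairs (default TRUE).
#' @param dynamic_range override the dynamic range.
#' @return tibble with columns `i`, `j`, `mssim`.
#' @export
all_pairs_mssim <- function(frames, include_self = TRUE,
                            dynamic_range = NULL) {
  n <- dim(frames)[3]
  if (n < 2L) stop_renasl("need at least 2 frames")
  L <- dynamic_range %||% max(frames)
  if (L <= 0) L <- 1
  r <- 5L; sigma <- 1.5; k1 <- 0.01; k2 <- 0.03
  if (dim(frames)[1] < 11L || dim(frames)[2] < 11L)
    stop_renasl("frames smaller than the SSIM window")
  f <- valid_gauss_filter(dim(frames)[1], dim(frames)[2], r, sigma)
  mu <- lapply(seq_len(n), function(i) f(frames[, , i]))
  m2 <- lapply(seq_len(n), function(i) f(frames[, , i]^2))
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  pairs <- which(upper.tri(diag(n), diag = include_self), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  vals <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (i == j) return(1)
    cab <- f(frames[, , i] * frames[, , j]) - mu[[i]] * mu[[j]]
    va <- m2[[i]] - mu[[i]]^2
    vb <- m2[[j]] - mu[[j]]^2
    mean(((2 * mu[[i]] * mu[[j]] + c1) * (2 * cab + c2)) /
           ((mu[[i]]^2 + mu[[j]]^2 + c1) * (va + vb + c2)))
  }, numeric(1))
  tibble::tibble(i = pairs[, 1], j = pairs[, 2], mssim = vals)
}

#' Dice overlap of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; two empty masks are defined to agree
#' perfectly (returns 1 with a warning).
#'
#' @param a,b 2-D logical masks of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_renasl("masks must share a grid")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("both masks are empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Warp a binary mask through a deformation field and rebinarize
#'
#' Transforms a ground-truth mask with the (pull-back) displacement field
#' of a registered frame — typically the M0 frame's deformation — using
#' linear interpolation, then rebinarizes at 0.5 so it can be compared to
#' masks drawn in the registered (implicit mean) space.
#'
#' @param mask 2-D logical mask.
#' @param deformation `rows x cols x 2` displacement field in voxels
#'   (row, col components), as produced by [register_groupwise()].
#' @return 2-D logical mask.
#' @export
transform_gt_mask <- function(mask, deformation) {
  if (!all(dim(mask) == dim(deformation)[1:2]))
    stop_renasl("deformation is not defined on the mask grid")
  w <- warp_image_linear(mask + 0, deformation)
  w >= 0.5
}

# pull-back bilinear warp: out(x) = img(x + u(x)), edge-clamped
warp_image_linear <- function(img, deformation) {
  nr <- nrow(img); nc <- ncol(img)
  i <- rep(seq_len(nr), times = nc) + as.vector(deformation[, , 1])
  j <- rep(seq_len(nc), each = nr) + as.vector(deformation[, , 2])
  i <- pmin(pmax(i, 1), nr); j <- pmin(pmax(j, 1), nc)
  i0 <- pmin(floor(i), nr - 1); j0 <- pmin(floor(j), nc - 1)
  fi <- i - i0; fj <- j - j0
  v <- (1 - fi) * (1 - fj) * img[cbind(i0, j0)] +
    fi * (1 - fj) * img[cbind(i0 + 1, j0)] +
    (1 - fi) * fj * img[cbind(i0, j0 + 1)] +
    fi * fj * img[cbind(i0 + 1, j0 + 1)]
  matrix(v, nr, nc)
}

#' Time-line profile through an ASL series
#'
#' Extracts a fixed row or column from every frame in acquisition order;
#' residual motion shows up as jagged structures along the frame axis. The
#' companion smoothness statistic is the total variation along the frame
#' axis, summed over positions (computed by [profile_total_variation()]).
#'
#' @param frames 3-D array `rows x cols x n`.
#' @param axis `"row"` or `"column"`: the fixed line to extract.
#' @param index 1-based row/column index.
#' @return matrix `position x frame`.
#' @export
line_profile <- function(frames, axis = c("row", "column"), index) {
  axis <- match.arg(axis)
  d <- dim(frames)
  if (axis == "row") {
    if (index < 1 || index > d[1]) stop_renasl("row index out of bounds")
    out <- frames[index, , ]
  } else {
    if (index < 1 || index > d[2]) stop_renasl("column index out of bounds")
    out <- frames[, index, ]
  }
  out
}

#' @rdname line_profile
#' @param profile a [line_profile()] matrix.
#' @export
profile_total_variation <- function(profile) {
  sum(abs(profile[, -1, drop = FALSE] - profile[, -ncol(profile), drop = FALSE]))
}
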