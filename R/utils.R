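#' @keywords internal
"_PACKAGE"

#' @useDynLib renasl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm quantile kmeans sd median
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_renasl <- function(...) stop(..., call. = FALSE)

#' Trilinear / nearest-neighbour sampling of a 3-D array
#'
#' Samples `arr` at fractional voxel coordinates (1-based). Points outside
#' the array are filled with `fill`.
#'
#' @param arr numeric 3-D array.
#' @param idx n x 3 matrix of fractional 1-based voxel indices.
#' @param method "linear" or "nearest".
#' @param fill value used outside the array extent.
#' @return numeric vector of length `nrow(idx)`.
#' @keywords internal
interp3 <- function(arr, idx, method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(arr)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  out <- rep(fill, nrow(idx))
  if (method == "nearest") {
    xi <- round(x); yi <- round(y); zi <- round(z)
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    out[ok] <- arr[cbind(xi[ok], yi[ok], zi[ok])]
    return(out)
  }
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    v <- v + w * arr[cbind(x0 + dx, y0 + dy, z0 + dz)]
  }
  out[ok] <- v
  out
}

# 1-D Gaussian filter matrix (rows renormalised at the borders) so that
# separable smoothing of image X is G_r %*% X %*% t(G_c).
gauss_filter_matrix <- function(n, sigma, radius = NULL) {
  if (sigma <= 0) return(diag(n))
  r <- radius %||% max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= n
    G[i, j[keep]] <- k[keep] / sum(k[keep])
  }
  G
}

smooth2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Gr <- gauss_filter_matrix(nrow(img), sigma)
  Gc <- gauss_filter_matrix(ncol(img), sigma)
  Gr %*% img %*% t(Gc)
}

# separable 3-D Gaussian smoothing (sigma per axis, in voxels)
smooth3d <- function(arr, sigma) {
  d <- dim(arr)
  G1 <- gauss_filter_matrix(d[1], sigma[1])
  G2 <- gauss_filter_matrix(d[2], sigma[2])
  G3 <- gauss_filter_matrix(d[3], sigma[3])
  x <- G1 %*% matrix(arr, d[1], d[2] * d[3])
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- G2 %*% matrix(x, d[2], d[1] * d[3])
  x <- aperm(array(x, c(d[2], d[1], d[3])), c(2, 1, 3))
  x <- aperm(x, c(3, 1, 2))
  x <- G3 %*% matrix(x, d[3], d[1] * d[2])
  aperm(array(x, c(d[3], d[1], d[2])), c(2, 3, 1))
}

# connected components of a logical matrix (8-connectivity); returns an
# integer matrix of component ids (0 = background)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}
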