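#' Respiratory motion trace
#'
#' Models free-breathing craniocaudal motion as a smooth sinusoid-derived
#' displacement over one breathing cycle sampled at `n_phases` equally
#' spaced time points centred on the exhalation plateau:
#' `d(phi) = amplitude * sin(pi * phi)^4` with the cycle fraction
#' `phi in [-1/2, 1/2]`, so most phases sit near the exhaled (zero
#' displacement) position and the extremes reach the full inhalation
#' amplitude. A seeded random subset of `n_select` phases (without
#' replacement) provides the acquisition time points; the phase closest to
#' zero displacement is reserved as the reference phase for the M0 frame.
#'
#' @param amplitude_mm peak craniocaudal displacement (mm), default 8.
#' @param period_s breathing period (s), default 4 (bookkeeping only).
#' @param n_phases number of simulated breathing phases, default 100.
#' @param n_select number of acquired frames, default 51.
#' @param seed integer seed for the phase selection.
#' @return object of class `motion_trace`: `displacement_mm` (length
#'   `n_phases`), `phase_times_s`, `selection` (0-based phase indices, first
#'   entry = reference/M0 phase), `amplitude_mm`, `period_s`, `seed`.
#' @export
#' @examples
#' motion_trace(amplitude_mm = 8, seed = 1)
motion_trace <- function(amplitude_mm = 8, period_s = 4, n_phases = 100L,
                         n_select = 51L, seed = 1L) {
  stopifnot(n_select <= n_phases, amplitude_mm >= 0, period_s > 0)
  phi <- seq(-0.5, 0.5, length.out = n_phases)
  disp <- amplitude_mm * sin(pi * phi)^4
  ref <- which.min(abs(disp))
  others <- withr::with_seed(seed,
    sample(setdiff(seq_len(n_phases), ref), n_select - 1L))
  structure(list(
    displacement_mm = disp,
    phase_times_s = phi * period_s,
    selection = c(ref, others) - 1L,
    n_phases = n_phases,
    amplitude_mm = amplitude_mm,
    period_s = period_s,
    seed = seed
  ), class = "motion_trace")
}

#' Simulate a full ASL time series
#'
#' Produces one M0 image and `n_pairs` control-label pairs (51 frames by
#' default). For every selected breathing phase the phantom is displaced
#' craniocaudally, the coronal-oblique slice is extracted, and the slice is
#' converted to M0/control/label magnitudes with [make_control_label_m0()].
#' The M0 frame is acquired at the reference (zero-displacement) phase.
#' Additive white Gaussian noise with standard deviation
#' `mean kidney M0 / snr` is injected independently into every frame;
#' `snr = Inf` gives the noise-free series. Per-frame ground-truth organ
#' masks (the displaced phantom's slice masks) are retained for evaluation.
#'
#' @param scene a [build_phantom()] result.
#' @param protocol an [asl_protocol()].
#' @param motion a [motion_trace()].
#' @param snr M0 signal-to-noise ratio (> 0, or `Inf` for noise-free).
#' @param noise_seed integer seed for the noise fields.
#' @return object of class `asl_series`: `m0`, `controls`, `labels`
#'   (2-D matrix / 3-D arrays), clean (noise-free) counterparts under
#'   `clean`, `frame_order` (frame type sequence), `frame_phase` (0-based
#'   phase per frame in acquisition order), `gt_masks` (per-frame organ mask
#'   lists), `sigma`, `protocol`, `motion`, `scene_meta`.
#' @export
simulate_series <- function(scene, protocol, motion, snr = Inf,
                            noise_seed = 1L) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(protocol, "asl_protocol"),
            inherits(motion, "motion_trace"))
  if (!(snr > 0)) stop_renasl("snr must be positive (Inf for noise-free)")
  n_pairs <- protocol$n_pairs
  n_frames <- 2L * n_pairs + 1L
  if (length(motion$selection) != n_frames)
    stop_renasl("motion trace selects ", length(motion$selection),
                " phases but the protocol needs ", n_frames, " frames")

  sel <- motion$selection + 1L
  disp <- motion$displacement_mm[sel]

  grid <- slice_grid(scene, protocol$rotation_deg, protocol$voxel_mm[1:2])
  slices <- lapply(seq_len(n_frames), function(i) {
    pts <- slice_points(scene, grid, disp[i])
    shp <- c(grid$nrow, grid$ncol)
    lab <- matrix(interp3(scene$labels, pts, "nearest"), shp[1], shp[2])
    # perfusion and transit time are tissue properties: assign them from the
    # (nearest-neighbour) labels so every voxel carries its tissue's value
    perf <- lookup_tissue(lab, scene$tissue_table, "perfusion")
    att <- lookup_tissue(lab, scene$tissue_table, "att_ms")
    tex <- matrix(interp3(scene$texture, pts, "linear", fill = 1),
                  shp[1], shp[2])
    masks <- lapply(scene$organ_masks, function(m)
      matrix(interp3(m + 0, pts, "nearest") > 0.5, shp[1], shp[2]))
    img <- make_control_label_m0(lab, scene$tissue_table, protocol, perf, att,
                                 texture_slice = tex)
    list(img = img, masks = masks)
  })

  shp <- dim(slices[[1]]$img$m0)
  m0_clean <- slices[[1]]$img$m0
  controls_clean <- array(0, c(shp, n_pairs))
  labels_clean <- array(0, c(shp, n_pairs))
  for (k in seq_len(n_pairs)) {
    controls_clean[, , k] <- slices[[2 * k]]$img$control
    labels_clean[, , k] <- slices[[2 * k + 1]]$img$label
  }

  kid_ref <- slices[[1]]$masks$kidney_left | slices[[1]]$masks$kidney_right
  sigma <- if (is.finite(snr)) mean(m0_clean[kid_ref]) / snr else 0

  noise <- function() {
    if (sigma == 0) return(matrix(0, shp[1], shp[2]))
    matrix(rnorm(prod(shp), 0, sigma), shp[1], shp[2])
  }
  noisy <- withr::with_seed(noise_seed, {
    m0 <- m0_clean + noise()
    co <- controls_clean
    la <- labels_clean
    for (k in seq_len(n_pairs)) {
      co[, , k] <- co[, , k] + noise()
      la[, , k] <- la[, , k] + noise()
    }
    list(m0 = m0, controls = co, labels = la)
  })

  frame_order <- c("m0", rep(c("control", "label"), n_pairs))
  structure(list(
    m0 = noisy$m0, controls = noisy$controls, labels = noisy$labels,
    clean = list(m0 = m0_clean, controls = controls_clean,
                 labels = labels_clean),
    frame_order = frame_order,
    frame_phase = motion$selection,
    frame_displacement_mm = disp,
    gt_masks = lapply(slices, `[[`, "masks"),
    sigma = sigma, snr = snr, noise_seed = noise_seed,
    protocol = protocol, motion = motion,
    scene_meta = list(model_seed = scene$model_seed,
                      scenario = scene$scenario,
                      voxel_size_mm = scene$voxel_size_mm)
  ), class = "asl_series")
}

#' Stack the frames of a series in acquisition order
#'
#' @param series an [simulate_series()] result.
#' @param clean use the noise-free images.
#' @return 3-D array `rows x cols x frames` ordered
#'   `(m0, c1, l1, ..., c25, l25)`.
#' @export
series_frames <- function(series, clean = FALSE) {
  src <- if (clean) series$clean else series
  n_pairs <- dim(src$controls)[3]
  shp <- dim(src$m0)
  out <- array(0, c(shp, 2L * n_pairs + 1L))
  out[, , 1] <- src$m0
  for (k in seq_len(n_pairs)) {
    out[, , 2 * k] <- src$controls[, , k]
    out[, , 2 * k + 1] <- src$labels[, , k]
  }
  out
}

#' @export
print.asl_series <- function(x, ...) {
  cat(sprintf(
    "<asl_series %s: %d frames (%s), grid %s, snr=%s, motion %.1f mm>\n",
    x$protocol$scheme, length(x$frame_order),
    "m0 + control/label pairs",
    paste(dim(x$m0), collapse = "x"),
    format(x$snr), x$motion$amplitude_mm))
  invisible(x)
}
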