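# lazily built, cached fixtures shared across test files

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

small_grid <- c(64L, 64L, 32L)

noise_free_dataset <- function(scheme, scenario = "healthy", seed = 1,
                               att_mode = "literature") {
  fixture(paste("nf", scheme, scenario, seed, att_mode, sep = "_"), {
    simulate_asl_dataset(scheme, scenario, model_seed = seed,
                         noise_seed = seed, snr = Inf, amplitude_mm = 0,
                         att_mode = att_mode)
  })
}

# mean rbf per region from an unregistered noise-free series, over the
# reference-phase ground-truth masks
quantify_noise_free <- function(ds) {
  s <- ds$series
  md <- mean_difference(series_frames(s))
  map <- quantify(md$delta_m, md$m0, s$protocol)
  gm <- s$gt_masks[[1]]
  list(map = map, gm = gm,
       cortex = mean(map$rbf[gm$cortex_left | gm$cortex_right]),
       medulla = mean(map$rbf[gm$medulla_left | gm$medulla_right]))
}

# full pipeline over the benchmark conditions: 5 anatomy seeds x 2 schemes,
# default motion and noise; summaries only (objects are large)
pipeline_runs <- function() {
  fixture("pipeline_runs", {
    runs <- list()
    for (scheme in c("PCASL", "PASL")) {
      for (seed in 1:5) {
        ds <- simulate_asl_dataset(
          scheme, "healthy", model_seed = seed, noise_seed = seed,
          att_mode = if (scheme == "PASL") "zero" else "literature")
        sides <- list()
        for (side in c("left", "right")) {
          k <- process_kidney(ds$series, side, mask_seed = seed)
          L <- max(k$crop$frames)
          before <- mean(all_pairs_mssim(k$crop$frames,
                                         dynamic_range = L)$mssim)
          after <- mean(all_pairs_mssim(k$registration$aligned,
                                        dynamic_range = L)$mssim)
          ps <- perfusion_stats(k$map, list(
            cortex = k$segmentation$cortex,
            medulla = k$segmentation$medulla))
          sides[[side]] <- list(
            mssim_before = before, mssim_after = after,
            dice_whole = dice(k$segmentation$whole, k$gt_masks$whole),
            dice_cortex = dice(k$segmentation$cortex, k$gt_masks$cortex),
            dice_medulla = dice(k$segmentation$medulla, k$gt_masks$medulla),
            cortex_mean = ps$mean[ps$region == "cortex"],
            medulla_mean = ps$mean[ps$region == "medulla"],
            n_cortex = ps$n_voxels[ps$region == "cortex"],
            n_medulla = ps$n_voxels[ps$region == "medulla"])
        }
        runs[[paste(scheme, seed, sep = "_")]] <-
          list(scheme = scheme, seed = seed, sides = sides)
      }
    }
    runs
  })
}

run_field <- function(runs, field, scheme = NULL) {
  unlist(lapply(runs, function(r) {
    if (!is.null(scheme) && r$scheme != scheme) return(NULL)
    vapply(r$sides, `[[`, numeric(1), field)
  }))
}

# independent numerical oracle for the general kinetic model: direct
# integration of the delivery-decay convolution
gkm_convolution_oracle <- function(f, m0, protocol, att_ms) {
  t1b <- protocol$t1_blood_ms / 1000
  dt <- att_ms / 1000
  f_per_s <- f / 6000
  m0b <- m0 / protocol$lambda_ml_per_g
  amp <- 2 * m0b * f_per_s * protocol$alpha * protocol$bs_correction
  if (protocol$scheme == "PASL") {
    t_meas <- protocol$ti_ms / 1000
    hi <- min(t_meas, dt + protocol$ti1_ms / 1000)
    if (hi <= dt) return(0)
    # bolus decays since inversion: c(s) = exp(-s/T1b) on [dt, dt+TI1]
    ig <- stats::integrate(function(s) exp(-s / t1b) *
                             exp(-(t_meas - s) / t1b),
                           dt, hi, rel.tol = 1e-13, abs.tol = 1e-15)
  } else {
    t_meas <- (protocol$tau_ms + protocol$pld_ms) / 1000
    hi <- min(t_meas, dt + protocol$tau_ms / 1000)
    if (hi <= dt) return(0)
    # labeled at the plane, decayed over the transit: c(s) = exp(-dt/T1b)
    ig <- stats::integrate(function(s) exp(-dt / t1b) *
                             exp(-(t_meas - s) / t1b),
                           dt, hi, rel.tol = 1e-13, abs.tol = 1e-15)
  }
  amp * ig$value
}

# slow direct-definition binary erosion used as the oracle for the
# morphology code
erode_oracle <- function(mask, se, origin) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  off <- which(se > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      ii <- i + off[k, 1] - origin[1]
      jj <- j + off[k, 2] - origin[2]
      if (ii < 1 || ii > nrow(mask) || jj < 1 || jj > ncol(mask) ||
          !mask[ii, jj]) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

# small synthetic blob stack with known per-frame integer row shifts
shifted_blob_stack <- function(shifts, nr = 40, nc = 30) {
  base <- outer(seq_len(nr), seq_len(nc), function(i, j)
    exp(-((i - 20)^2 / 60 + (j - 15)^2 / 40)) +
      0.3 * exp(-((i - 28)^2 / 30 + (j - 20)^2 / 25)))
  stack <- array(0, c(nr, nc, length(shifts)))
  for (g in seq_along(shifts)) {
    img <- base
    s <- shifts[g]
    if (s > 0) img <- rbind(matrix(0, s, nc), base[seq_len(nr - s), ])
    stack[, , g] <- img
  }
  stack
}
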