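#' Run configuration
#'
#' All knobs of a simulation + processing run in one serialisable list, so
#' a run is reproducible from its echoed configuration alone.
#'
#' @param ... overrides of any default field.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    scheme = "PCASL", scenario = "healthy",
    model_seed = 1L, noise_seed = 1L,
    snr = 40, amplitude_mm = 16, period_s = 4,
    grid_shape = c(96L, 96L, 32L),
    registration = registration_settings(),
    seg_mode = "emulated_manual", mask_seed = 1L,
    protocol_overrides = list()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_renasl("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

write_nifti_arr <- function(arr, path, pixdim = NULL) {
  img <- RNifti::asNifti(arr)
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated ASL dataset to a directory
#'
#' Layout: `series.nii.gz` (4-D, frames in acquisition order
#' m0, c1, l1, ...), `sidecar.json` with the protocol, frame bookkeeping
#' and seeds, per-frame ground-truth masks `gt_<structure>.nii.gz` (4-D),
#' ground-truth perfusion/transit-time slices at the reference phase, and
#' the echoed `config.json`.
#'
#' @param dataset a [simulate_asl_dataset()] result.
#' @param dir output directory (created if needed).
#' @param config optional [run_config()] to echo.
#' @return `dir`, invisibly.
#' @export
write_asl_dataset <- function(dataset, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- dataset$series
  frames <- series_frames(series)
  d <- dim(frames)
  vox <- series$protocol$voxel_mm
  write_nifti_arr(array(frames, c(d[1], d[2], 1, d[3])),
                  file.path(dir, "series.nii.gz"),
                  pixdim = c(vox[1], vox[2], vox[3], 1))
  structures <- names(series$gt_masks[[1]])
  for (st in structures) {
    stack <- vapply(series$gt_masks, function(ms) ms[[st]] + 0,
                    matrix(0, d[1], d[2]))
    write_nifti_arr(array(stack, c(d[1], d[2], 1, d[3])),
                    file.path(dir, paste0("gt_", st, ".nii.gz")),
                    pixdim = c(vox[1], vox[2], vox[3], 1))
  }
  ref_slice <- extract_oblique_slice(dataset$scene,
                                     series$protocol$rotation_deg,
                                     "perfusion_gt", displacement_mm = 0,
                                     in_plane_mm = vox[1:2])
  write_nifti_arr(ref_slice$image, file.path(dir, "perfusion_gt.nii.gz"),
                  pixdim = vox[1:2])
  att_slice <- extract_oblique_slice(dataset$scene,
                                     series$protocol$rotation_deg,
                                     "att_gt", displacement_mm = 0,
                                     in_plane_mm = vox[1:2])
  write_nifti_arr(att_slice$image, file.path(dir, "att_gt.nii.gz"),
                  pixdim = vox[1:2])
  sidecar <- c(
    series$protocol[setdiff(names(series$protocol), NULL)],
    list(frame_order = series$frame_order,
         frame_phase = series$frame_phase,
         frame_displacement_mm = series$frame_displacement_mm,
         snr = if (is.finite(series$snr)) series$snr else "Inf",
         sigma = series$sigma,
         seeds = list(model_seed = series$scene_meta$model_seed,
                      noise_seed = series$noise_seed,
                      motion_seed = series$motion$seed),
         scenario = series$scene_meta$scenario,
         motion = list(amplitude_mm = series$motion$amplitude_mm,
                       period_s = series$motion$period_s,
                       n_phases = series$motion$n_phases),
         gt_structures = structures,
         package_version = as.character(utils::packageVersion("renasl"))))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

sidecar_required <- function(scheme) {
  c("scheme", "tr_ms", "te_ms", "alpha", "bs_correction", "bs_factor",
    "t1_blood_ms", "lambda_ml_per_g", "n_pairs", "voxel_mm", "rotation_deg",
    if (scheme == "PASL") c("ti_ms", "ti1_ms") else c("pld_ms", "tau_ms"),
    "frame_order", "frame_phase", "snr")
}

#' Read an ASL dataset directory back into a series object
#'
#' Accepts any directory with a conforming `series.nii.gz` + `sidecar.json`
#' pair (ground-truth masks are attached when present). Errors name any
#' missing sidecar field.
#'
#' @param dir dataset directory.
#' @return an `asl_series` object.
#' @export
read_asl_dataset <- function(dir) {
  sc_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sc_path)) stop_renasl("no sidecar.json in ", dir)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  need <- sidecar_required(sc$scheme %||% "PCASL")
  missing <- setdiff(need, names(sc))
  if (length(missing))
    stop_renasl("sidecar is missing required field(s): ",
                paste(missing, collapse = ", "))
  arr <- as.array(RNifti::readNifti(file.path(dir, "series.nii.gz")))
  frames <- array(arr, c(dim(arr)[1], dim(arr)[2], dim(arr)[4]))
  timing <- if (sc$scheme == "PASL") {
    list(ti_ms = sc$ti_ms, ti1_ms = sc$ti1_ms)
  } else {
    list(pld_ms = sc$pld_ms, tau_ms = sc$tau_ms)
  }
  protocol <- do.call(asl_protocol, c(
    list(scheme = sc$scheme, tr_ms = sc$tr_ms, te_ms = sc$te_ms,
         alpha = sc$alpha, bs_correction = sc$bs_correction,
         bs_factor = sc$bs_factor, t1_blood_ms = sc$t1_blood_ms,
         lambda_ml_per_g = sc$lambda_ml_per_g,
         n_pairs = as.integer(sc$n_pairs),
         voxel_mm = as.numeric(sc$voxel_mm),
         rotation_deg = sc$rotation_deg),
    timing))
  n <- dim(frames)[3]
  n_pairs <- protocol$n_pairs
  m0 <- frames[, , 1]
  controls <- frames[, , seq(2, n, by = 2), drop = FALSE]
  labels <- frames[, , seq(3, n, by = 2), drop = FALSE]
  gt_masks <- NULL
  sts <- sc$gt_structures
  if (!is.null(sts) &&
      all(file.exists(file.path(dir, paste0("gt_", sts, ".nii.gz"))))) {
    stacks <- lapply(sts, function(st) {
      a <- as.array(RNifti::readNifti(file.path(dir,
                                                paste0("gt_", st, ".nii.gz"))))
      array(a, c(dim(a)[1], dim(a)[2], dim(a)[4])) > 0.5
    })
    names(stacks) <- sts
    gt_masks <- lapply(seq_len(n), function(i)
      lapply(stacks, function(s) s[, , i]))
  }
  structure(list(
    m0 = m0, controls = controls, labels = labels,
    clean = NULL,
    frame_order = sc$frame_order,
    frame_phase = sc$frame_phase,
    frame_displacement_mm = sc$frame_displacement_mm,
    gt_masks = gt_masks,
    sigma = sc$sigma %||% NA_real_,
    snr = if (identical(sc$snr, "Inf")) Inf else sc$snr,
    noise_seed = sc$seeds$noise_seed %||% NA_integer_,
    protocol = protocol,
    motion = sc$motion,
    scene_meta = list(model_seed = sc$seeds$model_seed %||% NA_integer_,
                      scenario = sc$scenario %||% NA_character_,
                      voxel_size_mm = as.numeric(sc$voxel_mm))
  ), class = "asl_series")
}

#' Write processing results for both kidneys
#'
#' Per side: the perfusion map, segmentation masks, deformation fields
#' (4-D NIfTI, components row/col in voxels), the per-level metric trace
#' (CSV) and the settings echo (JSON); regional statistics to
#' `perfusion_stats.csv`.
#'
#' @param processed a [process_series()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_processing_results <- function(processed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  perf_all <- list()
  for (side in names(processed)) {
    k <- processed[[side]]
    pfx <- file.path(dir, side)
    dir.create(pfx, showWarnings = FALSE)
    write_nifti_arr(k$map$rbf, file.path(pfx, "rbf.nii.gz"))
    write_nifti_arr(k$map$delta_m, file.path(pfx, "delta_m.nii.gz"))
    for (st in c("whole", "cortex", "medulla"))
      write_nifti_arr(k$segmentation[[st]] + 0,
                      file.path(pfx, paste0("mask_", st, ".nii.gz")))
    write_nifti_arr(k$registration$deformations,
                    file.path(pfx, "deformations.nii.gz"))
    utils::write.csv(as.data.frame(k$registration$metric_trace),
                     file.path(pfx, "metric_trace.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(k$registration$settings, list(crop_box = k$registration$crop_box)),
      file.path(pfx, "settings.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    perf_all[[side]] <- tibble::tibble(
      side = side,
      perfusion_stats(k$map, list(whole = k$segmentation$whole,
                                  cortex = k$segmentation$cortex,
                                  medulla = k$segmentation$medulla)))
  }
  utils::write.csv(do.call(rbind, perf_all),
                   file.path(dir, "perfusion_stats.csv"), row.names = FALSE)
  saveRDS(processed, file.path(dir, "processed.rds"))
  invisible(dir)
}

#' Write an evaluation report to a directory
#'
#' `report.json` (summaries), `mssim_pairs.csv`, `dice.csv`,
#' `perfusion_stats.csv` and the line-profile matrices as CSV.
#'
#' @param evaluation an [evaluate_processing()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(evaluation$mssim_pairs, file.path(dir, "mssim_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(evaluation$dice, file.path(dir, "dice.csv"),
                   row.names = FALSE)
  utils::write.csv(evaluation$perfusion,
                   file.path(dir, "perfusion_stats.csv"), row.names = FALSE)
  for (side in names(evaluation$profiles)) {
    p <- evaluation$profiles[[side]]
    utils::write.csv(p$before,
                     file.path(dir, paste0("profile_", side, "_before.csv")),
                     row.names = FALSE)
    utils::write.csv(p$after,
                     file.path(dir, paste0("profile_", side, "_after.csv")),
                     row.names = FALSE)
  }
  report <- list(
    mssim_summary = evaluation$mssim_summary,
    dice = evaluation$dice,
    perfusion = evaluation$perfusion,
    profile_total_variation = lapply(evaluation$profiles, function(p)
      list(before = p$tv_before, after = p$tv_after)))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Directory-level pipeline commands
#'
#' The three stages of the workflow as directory-to-directory operations,
#' used by the `renasl` command-line script: `asl_simulate_dataset`
#' simulates and writes a dataset, `asl_process_dataset` reads a dataset
#' directory, runs crop/registration/quantification/segmentation and
#' writes the results, `asl_evaluate_dataset` compares results with the
#' dataset's ground truth and writes the report.
#'
#' @param config a [run_config()].
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @param results_dir processing-results directory.
#' @return the output directory, invisibly.
#' @export
asl_simulate_dataset <- function(config, out_dir) {
  ds <- simulate_asl_dataset(
    scheme = config$scheme, scenario = config$scenario,
    model_seed = config$model_seed, noise_seed = config$noise_seed,
    snr = config$snr, amplitude_mm = config$amplitude_mm,
    period_s = config$period_s, grid_shape = config$grid_shape)
  write_asl_dataset(ds, out_dir, config = config)
}

#' @rdname asl_simulate_dataset
#' @export
asl_process_dataset <- function(data_dir, out_dir,
                                config = run_config()) {
  series <- read_asl_dataset(data_dir)
  processed <- process_series(series, settings = config$registration,
                              seg_mode = config$seg_mode,
                              mask_seed = config$mask_seed)
  write_processing_results(processed, out_dir)
}

#' @rdname asl_simulate_dataset
#' @export
asl_evaluate_dataset <- function(data_dir, results_dir, out_dir) {
  processed <- readRDS(file.path(results_dir, "processed.rds"))
  ev <- evaluate_processing(processed)
  write_evaluation(ev, out_dir)
}
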