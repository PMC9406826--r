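#' Spin-echo signal magnitude
#'
#' Converts tissue properties into an MR magnitude value with the spin-echo
#' signal equation `S = rho * (1 - exp(-TR/T1)) * exp(-TE/T2)`. Vectorised
#' over all arguments.
#'
#' @param rho relative proton density (dimensionless).
#' @param t1_ms,t2_ms longitudinal/transverse relaxation times (ms), > 0.
#' @param tr_ms,te_ms repetition and echo time (ms), > 0.
#' @return signal magnitude in arbitrary units.
#' @export
#' @examples
#' spin_echo_signal(1, 1000, 100, 5000, 23)
spin_echo_signal <- function(rho, t1_ms, t2_ms, tr_ms, te_ms) {
  if (any(t1_ms <= 0) || any(t2_ms <= 0))
    stop_renasl("relaxation times must be positive")
  if (any(tr_ms <= 0) || any(te_ms < 0))
    stop_renasl("TR must be positive and TE non-negative")
  rho * (1 - exp(-tr_ms / t1_ms)) * exp(-te_ms / t2_ms)
}

# spin-echo magnitude image from a tissue label image
signal_from_labels <- function(labels, tissue_table, protocol) {
  s <- spin_echo_signal(tissue_table$rho,
                        pmax(tissue_table$t1_ms, 1e-9),
                        pmax(tissue_table$t2_ms, 1e-9),
                        protocol$tr_ms, protocol$te_ms)
  s[tissue_table$rho <= 0] <- 0
  vals <- numeric(max(tissue_table$tissue_id) + 1L)
  vals[tissue_table$tissue_id + 1L] <- s
  out <- vals[as.integer(labels) + 1L]
  dim(out) <- dim(labels)
  out
}

#' Perfusion-weighted signal difference from the general kinetic model
#'
#' Computes the ASL difference signal `dM = control - label` predicted by
#' the single-compartment general kinetic model under the assumption that
#' the apparent tissue T1 equals the T1 of arterial blood. The labeled
#' bolus arrives after the arterial transit time `att_ms`; PASL is read out
#' at TI, PCASL at `tau + PLD`. Labeling efficiency and the background
#' suppression attenuation (`bs_correction` = 0.93^2 for two suppression
#' pulses) are applied in the forward direction so that the consensus
#' quantification equations invert the model exactly.
#'
#' With the blood-equals-tissue T1 assumption the PCASL difference signal is
#' independent of the transit time whenever `att_ms <= PLD` (fully
#' delivered bolus). PASL with `TI >= att + TI1` is likewise fully
#' delivered; for larger transit times only the delivered fraction of the
#' bolus contributes.
#'
#' @param f perfusion in mL/100 g/min (>= 0); vectorised.
#' @param m0_tissue equilibrium tissue magnetisation (same grid as `f`).
#' @param protocol an [asl_protocol()].
#' @param att_ms arterial transit time in ms (>= 0).
#' @return difference signal dM in the units of `m0_tissue`.
#' @export
#' @examples
#' p <- asl_protocol("PCASL")
#' gkm_delta_m(250, 1, p, att_ms = 1141)
gkm_delta_m <- function(f, m0_tissue, protocol, att_ms) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (any(f < 0)) stop_renasl("perfusion f must be >= 0")
  if (any(att_ms < 0)) stop_renasl("arterial transit time must be >= 0")
  t1b <- protocol$t1_blood_ms / 1000      # s
  dt <- att_ms / 1000
  f_per_s <- f / 6000                     # mL/100g/min -> mL/g/s
  m0b <- m0_tissue / protocol$lambda_ml_per_g
  scale <- 2 * m0b * f_per_s * protocol$alpha * protocol$bs_correction
  if (protocol$scheme == "PASL") {
    ti <- protocol$ti_ms / 1000
    ti1 <- protocol$ti1_ms / 1000
    width <- pmax(pmin(ti, dt + ti1) - dt, 0)
    dm <- scale * exp(-ti / t1b) * width
  } else {
    t <- (protocol$tau_ms + protocol$pld_ms) / 1000
    tau <- protocol$tau_ms / 1000
    lo <- pmin(t, dt + tau)
    dm <- scale * exp(-dt / t1b) * t1b *
      (exp(-(t - lo) / t1b) - exp(-(t - dt) / t1b))
    dm[dt >= t] <- 0
  }
  dm
}

#' Generate M0, control and label images from a label slice
#'
#' Builds the three ASL image types on a common 2-D grid: the M0 image is
#' the spin-echo magnitude of the tissue labels; control images are the M0
#' reduced to `bs_factor` (20 percent) by background suppression; label
#' images are the control minus the kinetic-model difference signal.
#'
#' @param slice_labels 2-D integer label image.
#' @param tissue_table tissue property table.
#' @param protocol an [asl_protocol()].
#' @param perfusion_slice 2-D perfusion map (mL/100 g/min).
#' @param att_slice 2-D arterial transit time map (ms).
#' @param texture_slice optional 2-D multiplicative signal heterogeneity
#'   field (default uniform 1).
#' @return list with `m0`, `control`, `label` (2-D matrices).
#' @export
make_control_label_m0 <- function(slice_labels, tissue_table, protocol,
                                  perfusion_slice, att_slice,
                                  texture_slice = NULL) {
  if (!all(dim(slice_labels) == dim(perfusion_slice)) ||
      !all(dim(slice_labels) == dim(att_slice)))
    stop_renasl("slice_labels, perfusion_slice and att_slice must share a grid")
  m0 <- signal_from_labels(slice_labels, tissue_table, protocol)
  if (!is.null(texture_slice)) {
    if (!all(dim(texture_slice) == dim(slice_labels)))
      stop_renasl("texture_slice must share the slice grid")
    m0 <- m0 * texture_slice
  }
  control <- protocol$bs_factor * m0
  dm <- gkm_delta_m(perfusion_slice, m0, protocol, att_slice)
  label <- control - dm
  if (any(label < 0)) {
    warning("negative label intensities clipped to zero")
    label[label < 0] <- 0
  }
  list(m0 = m0, control = control, label = label)
}
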