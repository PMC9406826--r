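#' Default tissue property table
#'
#' Relaxation and perfusion properties at 3 T for every tissue class the
#' procedural phantom can emit. One row per integer tissue label:
#' `rho` is the relative proton density (0--1], `t1_ms`/`t2_ms` the
#' longitudinal/transverse relaxation times in ms, `perfusion` the renal
#' blood flow in mL/100 g/min and `att_ms` the arterial transit time in ms.
#' Only the renal cortex and medulla classes carry perfusion; the arterial
#' transit times default to 1141 ms (cortex) and 1123 ms (medulla).
#'
#' Relaxation values are literature 3 T values and deliberately live in this
#' editable table rather than in code: simulating altered tissue relaxation
#' only requires passing a modified table.
#'
#' @param scenario `"healthy"` (cortex 250, medulla 50 mL/100 g/min on both
#'   sides) or `"abnormal_right"` (right kidney reduced to 100/20, left
#'   unchanged).
#' @return A tibble with columns `tissue_id`, `name`, `rho`, `t1_ms`,
#'   `t2_ms`, `perfusion`, `att_ms`.
#' @export
#' @examples
#' default_tissue_table()
default_tissue_table <- function(scenario = c("healthy", "abnormal_right")) {
  scenario <- match.arg(scenario)
  tab <- tibble::tibble(
    tissue_id = 0:8,
    name = c("background", "body", "liver", "spleen",
             "cortex_left", "medulla_left", "cortex_right", "medulla_right",
             "pelvis"),
    rho = c(1e-9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 1.0),
    t1_ms = c(1, 1412, 809, 1328, 1142, 1545, 1142, 1545, 4000),
    t2_ms = c(1, 50, 34, 61, 76, 81, 76, 81, 750),
    perfusion = c(0, 0, 0, 0, 250, 50, 250, 50, 0),
    att_ms = c(0, 0, 0, 0, 1141, 1123, 1141, 1123, 0)
  )
  tab$rho[tab$tissue_id == 0] <- 0
  if (scenario == "abnormal_right") {
    tab$perfusion[tab$name == "cortex_right"] <- 100
    tab$perfusion[tab$name == "medulla_right"] <- 20
  }
  validate_tissue_table(tab)
  tab
}

validate_tissue_table <- function(tab) {
  stopifnot(all(c("tissue_id", "name", "rho", "t1_ms", "t2_ms",
                  "perfusion", "att_ms") %in% names(tab)))
  body <- tab$rho > 0
  if (any(tab$rho < 0) || any(tab$rho > 1))
    stop_renasl("tissue rho must lie in [0, 1]")
  if (any(tab$t1_ms[body] <= 0) || any(tab$t2_ms[body] <= 0))
    stop_renasl("tissue relaxation times must be positive")
  if (any(tab$perfusion < 0))
    stop_renasl("tissue perfusion must be non-negative")
  perfused <- tab$name[tab$perfusion > 0]
  if (!all(grepl("^(cortex|medulla)_", perfused)))
    stop_renasl("perfusion > 0 is only allowed for renal cortex/medulla classes")
  invisible(tab)
}

# map a label array to a per-voxel tissue property
lookup_tissue <- function(labels, tissue_table, column) {
  vals <- numeric(max(tissue_table$tissue_id) + 1L)
  vals[tissue_table$tissue_id + 1L] <- tissue_table[[column]]
  out <- vals[as.integer(labels) + 1L]
  if (!is.null(dim(labels))) dim(out) <- dim(labels)
  out
}
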