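# Ventricular kinetic energy: per-voxel 1/2 m v^2 summed over a
# segmentation per cardiac phase, with peak/mean summary metrics.

#' Compute the kinetic-energy curve over a segmentation
#'
#' For each cardiac phase, `KE(t) = sum over segmented voxels of
#' 1/2 * (density * voxel_volume) * |v|^2`, with `|v|` the three-component
#' speed, reported in mJ. A phase-resolved (4-D) segmentation is honoured;
#' a static 3-D mask is broadcast to all phases with a warning.
#'
#' @param field a [velocity_field()].
#' @param segmentation logical mask on the voxel grid: either 3-D (static)
#'   or 4-D `(nx, ny, nz, n_phases)` (per phase).
#' @param density fluid density, g/mL (1.06 for blood; use the phantom
#'   fluid's density for phantom data).
#' @return A [ke_curve()].
#' @export
compute_ke <- function(field, segmentation, density = 1.06) {
  if (density <= 0) stop("density must be positive", call. = FALSE)
  d <- dim(field$velocities)
  sd_ <- dim(segmentation)
  if (length(sd_) == 3L) {
    if (!identical(sd_, d[1:3])) {
      stop("segmentation must match the voxel grid", call. = FALSE)
    }
    warning("static segmentation broadcast to all ", d[4], " phases")
    per_phase <- FALSE
  } else if (length(sd_) == 4L) {
    if (!identical(sd_, d[1:4])) {
      stop("per-phase segmentation must match the voxel grid and phase count",
           call. = FALSE)
    }
    per_phase <- TRUE
  } else {
    stop("segmentation must be a 3-D or 4-D logical array", call. = FALSE)
  }
  voxvol <- prod(field$voxel_spacing)  # mm^3
  nvox <- prod(d[1:3])
  ke <- numeric(d[4])
  for (k in seq_len(d[4])) {
    seg <- if (per_phase) segmentation[, , , k] else segmentation
    idx <- which(seg)
    if (length(idx) == 0L) {
      warning("empty segmentation at phase ", k, "; KE set to 0")
      ke[k] <- 0
      next
    }
    sp2 <- 0
    for (c_ in 1:3) {
      vmat <- matrix(field$velocities[, , , k, c_], nrow = nvox)
      sp2 <- sp2 + sum(vmat[idx]^2)
    }
    # 0.5 * rho[g/mL] * dV[mm^3] * v^2[(cm/s)^2] * 1e-7 -> mJ
    ke[k] <- 0.5 * density * voxvol * sp2 * 1e-7
  }
  ke_curve(ke, field$rr_interval, density = density)
}

#' Summarise a kinetic-energy curve over the cardiac cycle
#'
#' Splits the cycle into systole, early diastole and late diastole at the
#' supplied boundaries (fractions of the RR interval, typically derived
#' from cine imaging) and reports the within-window peaks plus the
#' full-cycle time-averaged mean.
#'
#' @param curve a [ke_curve()].
#' @param systole_end end of systole as a fraction of RR, in (0, 1).
#' @param early_diastole_end end of early diastole, in (`systole_end`, 1).
#' @return A one-row tibble: `peak_systolic`, `peak_early_diastolic`,
#'   `peak_late_diastolic`, `mean` (all mJ).
#' @export
ke_summary <- function(curve, systole_end = 0.35, early_diastole_end = 0.7) {
  if (!(systole_end > 0 && systole_end < early_diastole_end &&
        early_diastole_end < 1)) {
    stop("parameter error: need 0 < systole_end < early_diastole_end < 1",
         call. = FALSE)
  }
  frac <- curve$time_ms / curve$rr_interval
  win_max <- function(sel) if (any(sel)) max(curve$ke_mj[sel]) else NA_real_
  tibble::tibble(
    peak_systolic = win_max(frac < systole_end),
    peak_early_diastolic = win_max(frac >= systole_end &
                                     frac < early_diastole_end),
    peak_late_diastolic = win_max(frac >= early_diastole_end),
    mean = mean(curve$ke_mj)
  )
}
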