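# Through-plane flow quantification: planar velocity maps, ROI flow curves,
# per-beat flow volumes, contour transfer and the QP/QS ratio.

#' Extract a through-plane velocity map on an analysis plane
#'
#' Samples the three velocity components at every plane pixel centre by
#' trilinear interpolation and projects onto the plane normal. Pixels whose
#' centres fall outside the voxel volume are marked invalid (NA).
#'
#' @param field a [velocity_field()].
#' @param plane an [analysis_plane()].
#' @return An object of class `planar_flow_map`: list with `v_through`
#'   (array `extent[1] x extent[2] x n_phases`, cm/s), `valid` (logical
#'   matrix), `plane`, `rr_interval`, `n_phases`.
#' @export
extract_plane <- function(field, plane) {
  pc <- plane_pixel_coords(plane)
  pq <- as.matrix(expand.grid(p = pc$u, q = pc$v))
  world <- plane_to_world(plane, pq)
  ijk <- world_to_voxel(field, world)
  d <- dim(field$velocities)
  npix <- nrow(ijk)
  nt <- d[4]
  vth <- array(NA_real_, dim = c(plane$extent[1], plane$extent[2], nt))
  any_valid <- FALSE
  for (k in seq_len(nt)) {
    acc <- numeric(npix)
    valid_k <- rep(TRUE, npix)
    for (c_ in 1:3) {
      if (plane$normal[c_] == 0) next
      s <- sample_trilinear(array(field$velocities[, , , k, c_], dim = d[1:3]), ijk)
      valid_k <- valid_k & !is.na(s)
      acc <- acc + ifelse(is.na(s), 0, s) * plane$normal[c_]
    }
    # components with zero normal weight still require the point in-volume
    invol <- ijk[, 1] >= 0 & ijk[, 1] <= d[1] - 1 &
             ijk[, 2] >= 0 & ijk[, 2] <= d[2] - 1 &
             ijk[, 3] >= 0 & ijk[, 3] <= d[3] - 1
    valid_k <- valid_k & invol
    acc[!valid_k] <- NA_real_
    vth[, , k] <- acc
    any_valid <- any_valid || any(valid_k)
  }
  if (!any_valid) {
    stop("geometry error: analysis plane lies entirely outside the volume",
         call. = FALSE)
  }
  structure(
    list(v_through = vth, valid = !is.na(vth[, , 1]), plane = plane,
         rr_interval = field$rr_interval, n_phases = nt),
    class = "planar_flow_map"
  )
}

#' @export
print.planar_flow_map <- function(x, ...) {
  cat(sprintf("<planar_flow_map> %d x %d pixels, %d phases (%d valid pixels)\n",
              dim(x$v_through)[1], dim(x$v_through)[2], x$n_phases,
              sum(x$valid)))
  invisible(x)
}

#' Integrate flow through an ROI contour
#'
#' Per cardiac phase, the volumetric flow rate is the sum of through-plane
#' velocity times pixel area over pixels whose centres fall inside the
#' polygon (even-odd rule, half-open edge convention). The flow volume is
#' the cyclic trapezoidal integral of the curve over one RR interval.
#'
#' @param planar a `planar_flow_map` from [extract_plane()].
#' @param contour an [roi_contour()] in plane-local mm, or a list of one
#'   contour per cardiac phase.
#' @param flip if `TRUE`, negate the through-plane sign (the vessel-normal
#'   orientation is a convention, not a measurement).
#' @return A [flow_curve()]: per-phase `flow_ml_s`, `time_ms`, and
#'   `flow_volume_ml` per beat.
#' @export
integrate_flow <- function(planar, contour, flip = FALSE) {
  stopifnot(inherits(planar, "planar_flow_map"))
  nt <- planar$n_phases
  contours <- if (inherits(contour, "roi_contour")) {
    rep(list(contour), nt)
  } else {
    if (length(contour) != nt) {
      stop("per-phase contour list must have one contour per phase", call. = FALSE)
    }
    contour
  }
  pc <- plane_pixel_coords(planar$plane)
  pq <- as.matrix(expand.grid(p = pc$u, q = pc$v))
  ps <- planar$plane$pixel_spacing
  flow <- numeric(nt)
  for (k in seq_len(nt)) {
    verts <- contours[[k]]$vertices
    inside <- point_in_polygon(pq[, 1], pq[, 2], verts)
    if (!any(inside)) {
      stop("empty-ROI error: contour encloses no pixel centres", call. = FALSE)
    }
    v <- planar$v_through[, , k][inside]
    if (anyNA(v)) {
      stop("ROI contains pixels outside the sampled volume", call. = FALSE)
    }
    # cm/s * mm^2 = 10 mm^3/s = 0.01 mL/s
    flow[k] <- sum(v) * ps^2 * 0.01
  }
  if (flip) flow <- -flow
  flow_curve(flow, planar$rr_interval)
}

#' Transfer an ROI contour between analysis planes
#'
#' Re-expresses a contour drawn on one plane (e.g. a 2D-flow acquisition)
#' in the plane-local frame of another plane sharing the same world
#' coordinates (e.g. the matching plane of a 4D-flow dataset). The
#' world-space polygon is unchanged; round-trip transfer is the identity.
#'
#' @param contour an [roi_contour()] in `source_plane` coordinates.
#' @param source_plane,target_plane [analysis_plane()]s in a shared world
#'   frame. A warning is raised if the planes are more than 0.1 mm apart
#'   (the polygon is orthogonally projected onto the target plane).
#' @return The contour as an [roi_contour()] in `target_plane` coordinates.
#' @export
transfer_contour <- function(contour, source_plane, target_plane) {
  world <- plane_to_world(source_plane, contour$vertices)
  off <- (sweep(world, 2, target_plane$origin, "-") %*% target_plane$normal)
  if (max(abs(off)) > 0.1) {
    warning("contour lies ", signif(max(abs(off)), 3),
            " mm out of the target plane; projecting orthogonally")
  }
  roi_contour(world_to_plane(target_plane, world))
}

#' Pulmonary-to-systemic flow ratio (QP/QS)
#'
#' @param pulmonary_volume pulmonary (PA) flow volume, mL/beat.
#' @param systemic_volume systemic (aortic) flow volume, mL/beat.
#' @return The dimensionless ratio QP/QS (about 1 in the absence of shunts).
#' @export
qp_qs <- function(pulmonary_volume, systemic_volume) {
  if (any(systemic_volume <= 0)) {
    stop("domain error: systemic volume must be positive", call. = FALSE)
  }
  pulmonary_volume / systemic_volume
}
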