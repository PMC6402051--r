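#' Construct a 4D velocity field
#'
#' The central container of the package: a three-directional velocity field
#' sampled on a regular voxel grid over the cardiac cycle.
#'
#' Velocities are stored as a 5-D array with dimensions
#' `(nx, ny, nz, n_phases, 3)`; the last axis holds the x/y/z velocity
#' components in cm/s. Voxel indices are 0-based in all world/voxel maps;
#' world coordinates are in mm following the NIfTI affine convention with an
#' axis-aligned, positive-diagonal affine (`world = origin + spacing * index`).
#' The time axis is cyclic (retrospective gating): phase `t` and
#' `t + n_phases` refer to the same cardiac time, and phase `t` (1-based)
#' occurs at `(t - 1) * rr_interval / n_phases` ms.
#'
#' @param velocities numeric 5-D array `(nx, ny, nz, n_phases, 3)`, cm/s.
#' @param voxel_spacing length-3 positive numeric, mm.
#' @param origin length-3 numeric, world mm of voxel (0,0,0).
#' @param rr_interval RR interval, ms.
#' @param venc velocity-encoding limit per axis, cm/s; scalars are recycled
#'   to length 3.
#'
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(velocities, voxel_spacing, origin = c(0, 0, 0),
                           rr_interval, venc = c(150, 150, 150)) {
  venc <- rep_len(as.numeric(venc), 3L)
  x <- structure(
    list(
      velocities = velocities,
      voxel_spacing = as.numeric(voxel_spacing),
      origin = as.numeric(origin),
      rr_interval = as.numeric(rr_interval),
      n_phases = dim(velocities)[4L],
      venc = venc
    ),
    class = "velocity_field"
  )
  validate_velocity_field(x)
}

validate_velocity_field <- function(x) {
  d <- dim(x$velocities)
  if (length(d) != 5L || d[5L] != 3L) {
    stop("velocities must be a 5-D array (nx, ny, nz, n_phases, 3)",
         call. = FALSE)
  }
  if (length(x$voxel_spacing) != 3L || any(x$voxel_spacing <= 0)) {
    stop("voxel_spacing must be 3 positive values (mm)", call. = FALSE)
  }
  if (length(x$origin) != 3L) stop("origin must have length 3", call. = FALSE)
  if (!is.finite(x$rr_interval) || x$rr_interval <= 0) {
    stop("rr_interval must be a positive number of ms", call. = FALSE)
  }
  if (x$n_phases < 1L) stop("need at least one cardiac phase", call. = FALSE)
  if (any(!is.finite(x$venc)) || any(x$venc <= 0)) {
    stop("venc must be positive (cm/s)", call. = FALSE)
  }
  x
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$velocities)
  cat(sprintf(
    "<velocity_field> %d x %d x %d voxels, %d phases\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm, origin %s mm\n",
              paste(signif(x$voxel_spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  RR %.0f ms, VENC %s cm/s\n", x$rr_interval,
              paste(signif(x$venc, 4), collapse = "/")))
  invisible(x)
}

#' Construct a phase field
#'
#' Raw velocity-encoded phase images as produced by the scanner (or by
#' [encode_acquisition()]): one phase volume per encoding axis and cardiac
#' phase, all values in radians in `[-pi, pi)`. Grid and timing metadata
#' mirror [velocity_field()].
#'
#' @param phases numeric 5-D array `(nx, ny, nz, n_phases, 3)`, radians in
#'   `[-pi, pi)`.
#' @inheritParams velocity_field
#' @return An object of class `phase_field`.
#' @export
phase_field <- function(phases, voxel_spacing, origin = c(0, 0, 0),
                        rr_interval, venc = c(150, 150, 150)) {
  d <- dim(phases)
  if (length(d) != 5L || d[5L] != 3L) {
    stop("phases must be a 5-D array (nx, ny, nz, n_phases, 3)", call. = FALSE)
  }
  rng <- range(phases)
  if (rng[1] < -pi - 1e-9 || rng[2] >= pi + 1e-9) {
    stop("phase values must lie in [-pi, pi)", call. = FALSE)
  }
  structure(
    list(
      phases = phases,
      voxel_spacing = as.numeric(voxel_spacing),
      origin = as.numeric(origin),
      rr_interval = as.numeric(rr_interval),
      n_phases = d[4L],
      venc = rep_len(as.numeric(venc), 3L)
    ),
    class = "phase_field"
  )
}

#' @export
print.phase_field <- function(x, ...) {
  d <- dim(x$phases)
  cat(sprintf("<phase_field> %d x %d x %d voxels, %d phases, VENC %s cm/s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$venc, 4), collapse = "/")))
  invisible(x)
}

#' Construct a first-order background phase model
#'
#' An affine-in-space, time-independent model of the spurious background
#' velocity offset (eddy currents, concomitant gradients) per velocity
#' component: `v_bg = a0 + ax*x + ay*y + az*z` with world coordinates in mm.
#'
#' @param coefficients numeric 3 x 4 matrix; rows are the vx/vy/vz components,
#'   columns `a0` (cm/s), `ax`, `ay`, `az` (cm/s per mm).
#' @return An object of class `background_model`.
#' @export
background_model <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  if (!all(dim(coefficients) == c(3L, 4L))) {
    stop("coefficients must be a 3 x 4 matrix", call. = FALSE)
  }
  dimnames(coefficients) <- list(c("vx", "vy", "vz"),
                                 c("a0", "ax", "ay", "az"))
  structure(list(coefficients = coefficients), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("<background_model> v_bg = a0 + ax*x + ay*y + az*z  (cm/s; x,y,z in mm)\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Evaluate a background model at world points
#'
#' @param model a [background_model()].
#' @param points n x 3 matrix of world coordinates, mm.
#' @return n x 3 matrix of background velocities, cm/s.
#' @export
evaluate_background <- function(model, points) {
  points <- rbind(points)  # tolerate a single point as a vector
  if (ncol(points) != 3L) stop("points must be n x 3 (world mm)", call. = FALSE)
  X <- cbind(1, points)
  X %*% t(model$coefficients)
}

#' Construct an analysis plane
#'
#' An oriented, finite sampling plane in world coordinates on which
#' through-plane velocity maps are extracted ([extract_plane()]) and flow is
#' integrated over an ROI contour. Plane-local 2D coordinates (mm) have their
#' origin at the plane origin; pixel `(i, j)` (1-based) is centred at
#' `((i - (extent[1] + 1)/2) * pixel_spacing, (j - (extent[2] + 1)/2) * pixel_spacing)`.
#'
#' @param origin plane centre, world mm.
#' @param normal plane normal (through-plane direction); normalised internally.
#' @param u,v optional in-plane basis vectors; if omitted an orthonormal pair
#'   is constructed deterministically from `normal`.
#' @param pixel_spacing in-plane sampling step, mm.
#' @param extent integer 2-vector, number of pixels along `u` and `v`.
#' @return An object of class `analysis_plane`.
#' @export
analysis_plane <- function(origin, normal, u = NULL, v = NULL,
                           pixel_spacing = 1, extent = c(41L, 41L)) {
  normal <- as.numeric(normal)
  normal <- normal / sqrt(sum(normal^2))
  if (is.null(u)) {
    seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- seed - sum(seed * normal) * normal
    u <- u / sqrt(sum(u^2))
  } else {
    u <- as.numeric(u); u <- u / sqrt(sum(u^2))
  }
  if (is.null(v)) {
    v <- c(normal[2] * u[3] - normal[3] * u[2],
           normal[3] * u[1] - normal[1] * u[3],
           normal[1] * u[2] - normal[2] * u[1])
  } else {
    v <- as.numeric(v); v <- v / sqrt(sum(v^2))
  }
  B <- rbind(u, v, normal)
  if (max(abs(B %*% t(B) - diag(3))) > 1e-9) {
    stop("{u, v, normal} must be orthonormal (to 1e-9)", call. = FALSE)
  }
  structure(
    list(origin = as.numeric(origin), normal = normal, u = u, v = v,
         pixel_spacing = as.numeric(pixel_spacing),
         extent = as.integer(extent)),
    class = "analysis_plane"
  )
}

#' @export
print.analysis_plane <- function(x, ...) {
  cat(sprintf("<analysis_plane> origin (%s) mm, normal (%s)\n",
              paste(signif(x$origin, 4), collapse = ", "),
              paste(signif(x$normal, 4), collapse = ", ")))
  cat(sprintf("  %d x %d pixels at %.3g mm\n", x$extent[1], x$extent[2],
              x$pixel_spacing))
  invisible(x)
}

# Plane-local pixel-centre coordinates (mm): list(u = nu vector, v = nv vector)
plane_pixel_coords <- function(plane) {
  nu <- plane$extent[1]; nv <- plane$extent[2]; ps <- plane$pixel_spacing
  list(u = (seq_len(nu) - (nu + 1) / 2) * ps,
       v = (seq_len(nv) - (nv + 1) / 2) * ps)
}

# Plane-local (p, q) mm -> world mm; pq is n x 2
plane_to_world <- function(plane, pq) {
  pq <- rbind(pq)
  sweep(pq[, 1, drop = FALSE] %*% rbind(plane$u) +
          pq[, 2, drop = FALSE] %*% rbind(plane$v),
        2, plane$origin, "+")
}

# World mm -> plane-local (p, q) mm (orthogonal projection onto the plane)
world_to_plane <- function(plane, xyz) {
  xyz <- rbind(xyz)
  rel <- sweep(xyz, 2, plane$origin, "-")
  cbind(rel %*% plane$u, rel %*% plane$v)
}

#' Construct an ROI contour
#'
#' A closed polygon in plane-local coordinates (mm) outlining a vessel lumen
#' (or any region) on an [analysis_plane()]. Closure is implicit: the first
#' vertex must not repeat as the last. Self-intersecting polygons are
#' rejected.
#'
#' @param vertices n x 2 numeric matrix of ordered vertices, mm.
#' @return An object of class `roi_contour`.
#' @export
roi_contour <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("contour needs >= 3 vertices as an n x 2 matrix", call. = FALSE)
  }
  if (all(vertices[1, ] == vertices[nrow(vertices), ])) {
    stop("contour closure is implicit; first vertex must not be repeated",
         call. = FALSE)
  }
  if (polygon_self_intersects(vertices)) {
    stop("contour is self-intersecting", call. = FALSE)
  }
  structure(list(vertices = vertices), class = "roi_contour")
}

#' Regular polygon approximation of a circular ROI
#'
#' @param center circle centre in plane-local mm.
#' @param radius radius, mm.
#' @param n number of vertices.
#' @return An [roi_contour()].
#' @export
circle_contour <- function(center = c(0, 0), radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  roi_contour(cbind(center[1] + radius * cos(th),
                    center[2] + radius * sin(th)))
}

# Segment-intersection test on non-adjacent edges (O(n^2); contours are small)
polygon_self_intersects <- function(P) {
  n <- nrow(P)
  seg <- function(i) list(a = P[i, ], b = P[if (i == n) 1L else i + 1L, ])
  cross2 <- function(o, a, b) (a[1]-o[1])*(b[2]-o[2]) - (a[2]-o[2])*(b[1]-o[1])
  intersects <- function(s1, s2) {
    d1 <- cross2(s2$a, s2$b, s1$a); d2 <- cross2(s2$a, s2$b, s1$b)
    d3 <- cross2(s1$a, s1$b, s2$a); d4 <- cross2(s1$a, s1$b, s2$b)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n <= 3L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      if (intersects(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

#' Construct a flow curve
#'
#' Per-cardiac-phase volumetric flow rate through an ROI, with its cyclic
#' time integral over one beat (the flow volume).
#'
#' @param flow_ml_s per-phase flow rate, mL/s.
#' @param rr_interval RR interval, ms.
#' @return An object of class `flow_curve` with elements `flow_ml_s`,
#'   `time_ms`, `flow_volume_ml`, `rr_interval`, `n_phases`.
#' @export
flow_curve <- function(flow_ml_s, rr_interval) {
  n <- length(flow_ml_s)
  structure(
    list(flow_ml_s = as.numeric(flow_ml_s),
         time_ms = (seq_len(n) - 1) * rr_interval / n,
         flow_volume_ml = cyclic_integral(flow_ml_s, rr_interval) / 1000,
         rr_interval = rr_interval,
         n_phases = n),
    class = "flow_curve"
  )
}

# Cyclic trapezoidal integral of a per-phase series over one period.
# With uniform phase spacing this reduces to mean(values) * period.
cyclic_integral <- function(values, period) {
  n <- length(values)
  dt <- period / n
  sum((values + values[c(seq_len(n)[-1], 1L)]) / 2) * dt
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %d phases, RR %.0f ms\n", x$n_phases, x$rr_interval))
  cat(sprintf("  flow volume %.2f mL/beat; peak rate %.1f mL/s\n",
              x$flow_volume_ml, max(x$flow_ml_s)))
  invisible(x)
}

#' @export
as.data.frame.flow_curve <- function(x, ...) {
  data.frame(phase_index = seq_len(x$n_phases), time_ms = x$time_ms,
             flow_ml_s = x$flow_ml_s)
}

#' Construct a kinetic-energy curve
#'
#' Total kinetic energy inside a segmentation per cardiac phase, in mJ.
#'
#' @param ke_mj per-phase kinetic energy, mJ (must be non-negative).
#' @param rr_interval RR interval, ms.
#' @param density fluid density used, g/mL (metadata, logged in outputs).
#' @return An object of class `ke_curve`.
#' @export
ke_curve <- function(ke_mj, rr_interval, density = NA_real_) {
  if (any(ke_mj < 0)) stop("kinetic energy cannot be negative", call. = FALSE)
  n <- length(ke_mj)
  structure(
    list(ke_mj = as.numeric(ke_mj),
         time_ms = (seq_len(n) - 1) * rr_interval / n,
         rr_interval = rr_interval, n_phases = n, density = density),
    class = "ke_curve"
  )
}

#' @export
print.ke_curve <- function(x, ...) {
  cat(sprintf("<ke_curve> %d phases, RR %.0f ms, density %.3g g/mL\n",
              x$n_phases, x$rr_interval, x$density))
  cat(sprintf("  peak %.3g mJ, mean %.3g mJ\n", max(x$ke_mj), mean(x$ke_mj)))
  invisible(x)
}

#' @export
as.data.frame.ke_curve <- function(x, ...) {
  data.frame(phase_index = seq_len(x$n_phases), time_ms = x$time_ms,
             ke_mj = x$ke_mj)
}
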