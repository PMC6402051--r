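# Synthetic pulsatile-flow phantom with analytic ground truth.
#
# Emulates a pump-driven flow phantom and idealized great vessels:
# Womersley flow in a rigid tube (per-beat volume exact by construction),
# a Hill spherical vortex ring (kinetic energy known by quadrature), and a
# phase-contrast forward model adding wrap at VENC, affine background
# offsets and Gaussian phase noise. Ground truth is always computed from
# the analytic fields, never from the voxelized samples.

#' Define a pump program
#'
#' A periodic volumetric flow-rate waveform `Q(t)` as a truncated Fourier
#' series, constrained so its one-period integral equals the target stroke
#' volume exactly (the zero-frequency coefficient is set analytically).
#'
#' The default `"half_sine"` waveform ejects the full stroke volume as a
#' half-sine pulse occupying `systolic_fraction` of the cycle with zero flow
#' in diastole, a standard idealization of ventricular ejection; the
#' truncated series (not the ideal pulse) *is* the program waveform, so all
#' ground truth is self-consistent. `"constant"` gives steady flow
#' (Poiseuille limit).
#'
#' @param stroke_volume target per-beat volume, mL.
#' @param period cycle length, ms.
#' @param waveform `"half_sine"` or `"constant"`.
#' @param n_harmonics number of Fourier harmonics retained.
#' @param systolic_fraction ejection duration as a fraction of the cycle.
#' @return An object of class `pump_program` with elements `a0` (mL/s),
#'   `an`, `bn` (cosine/sine coefficients, mL/s), `period`, `stroke_volume`.
#' @export
pump_program <- function(stroke_volume, period = 1000,
                         waveform = c("half_sine", "constant"),
                         n_harmonics = 8L, systolic_fraction = 0.35) {
  waveform <- match.arg(waveform)
  if (period <= 0) stop("period must be positive (ms)", call. = FALSE)
  a0 <- stroke_volume / (period / 1000)  # mean flow, mL/s; integral exact
  if (waveform == "constant" || n_harmonics == 0L) {
    an <- bn <- numeric(0)
  } else {
    ts_ms <- systolic_fraction * period
    qp <- stroke_volume * pi / (2 * ts_ms / 1000)  # peak of the ideal pulse
    M <- 8192L
    tj <- (seq_len(M) - 1) * period / M
    qj <- ifelse(tj < ts_ms, qp * sin(pi * tj / ts_ms), 0)
    w <- 2 * pi / period
    an <- bn <- numeric(n_harmonics)
    for (n in seq_len(n_harmonics)) {
      an[n] <- 2 * mean(qj * cos(n * w * tj))
      bn[n] <- 2 * mean(qj * sin(n * w * tj))
    }
  }
  structure(
    list(stroke_volume = stroke_volume, period = period, a0 = a0,
         an = an, bn = bn, n_harmonics = length(an), waveform = waveform),
    class = "pump_program"
  )
}

#' @export
print.pump_program <- function(x, ...) {
  cat(sprintf("<pump_program> SV %.4g mL, period %.0f ms, %s, %d harmonics\n",
              x$stroke_volume, x$period, x$waveform, x$n_harmonics))
  invisible(x)
}

#' Evaluate a pump program's flow rate
#'
#' @param program a [pump_program()].
#' @param t_ms times, ms (vectorized; periodic).
#' @return Flow rate `Q(t)`, mL/s.
#' @export
pump_flow_rate <- function(program, t_ms) {
  w <- 2 * pi / program$period
  q <- rep(program$a0, length(t_ms))
  for (n in seq_len(program$n_harmonics)) {
    q <- q + program$an[n] * cos(n * w * t_ms) + program$bn[n] * sin(n * w * t_ms)
  }
  q
}

#' Specify phantom geometry and fluid
#'
#' @param geometry `"tube"` (Womersley flow in a rigid tube along z) or
#'   `"vortex_ring"` (Hill spherical vortex).
#' @param tube_radius tube radius, mm.
#' @param density fluid density, g/mL (1.00 water; use 1.06 for blood-like).
#' @param viscosity kinematic viscosity, mm^2/s (1.0 for water at ~20 C).
#' @param grid_shape integer 3-vector of voxels; default `c(40, 40, 16)` for
#'   tubes (the flow is axis-invariant, so z depth adds nothing) and
#'   `c(36, 36, 36)` for the vortex ring.
#' @param spacing isotropic voxel size, mm.
#' @param n_phases reconstructed cardiac phases.
#' @param ring_radius Hill vortex sphere radius `a`, mm.
#' @param ring_speed Hill vortex translation speed `U`, cm/s.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("tube", "vortex_ring"),
                         tube_radius = 12, density = 1.00, viscosity = 1.0,
                         grid_shape = NULL, spacing = 2.9, n_phases = 40L,
                         ring_radius = 16, ring_speed = 50) {
  geometry <- match.arg(geometry)
  if (is.null(grid_shape)) {
    grid_shape <- if (geometry == "tube") c(40L, 40L, 16L) else c(36L, 36L, 36L)
  }
  if (density <= 0) stop("density must be positive", call. = FALSE)
  if (viscosity <= 0) stop("viscosity must be positive", call. = FALSE)
  spec <- structure(
    list(geometry = geometry, tube_radius = tube_radius, density = density,
         viscosity = viscosity, grid_shape = as.integer(grid_shape),
         spacing = spacing, n_phases = as.integer(n_phases),
         ring_radius = ring_radius, ring_speed = ring_speed),
    class = "phantom_spec"
  )
  half <- min(grid_shape[1], grid_shape[2]) * spacing / 2
  if (geometry == "tube" && tube_radius + 2 * spacing > half) {
    stop("geometry error: tube does not fit in the grid with a stationary margin",
         call. = FALSE)
  }
  if (geometry == "vortex_ring" &&
      3 * ring_radius > min(grid_shape) * spacing / 2) {
    stop("geometry error: vortex ring (with far-field taper) does not fit in the grid",
         call. = FALSE)
  }
  spec
}

#' Womersley velocity profile in a rigid tube
#'
#' Axial velocity of fully developed pulsatile laminar flow in a rigid
#' circular tube driven by the pump program's flow waveform. Each Fourier
#' harmonic of `Q(t)` contributes the classical Bessel-function radial
#' profile; the zero-frequency harmonic contributes the parabolic Poiseuille
#' profile. By construction the cross-sectional integral of the returned
#' profile reproduces `Q(t)` harmonic by harmonic, and velocity vanishes at
#' the wall (no slip).
#'
#' @param r radial position(s), mm, `0 <= r <= tube_radius`.
#' @param t time(s), ms; recycled against `r`.
#' @param program a [pump_program()].
#' @param spec a [phantom_spec()] supplying `tube_radius` and `viscosity`.
#' @return Axial velocity, cm/s (vector, recycled to the common length of
#'   `r` and `t`).
#' @export
womersley_velocity <- function(r, t, program, spec) {
  n <- max(length(r), length(t))
  r <- rep_len(r, n); t <- rep_len(t, n)
  if (any(r < 0) || any(r > spec$tube_radius)) {
    stop("domain error: r must lie in [0, tube_radius]", call. = FALSE)
  }
  out <- numeric(n)
  for (tv in unique(t)) {
    sel <- t == tv
    out[sel] <- womersley_profile(r[sel], tv, program, spec)
  }
  out
}

# Radial profile at a single time; r vector (mm), returns cm/s.
womersley_profile <- function(r, t_ms, program, spec) {
  R <- spec$tube_radius
  A <- pi * R^2                               # mm^2
  u <- 2 * (program$a0 * 1000 / A) * (1 - (r / R)^2)  # mm/s, Poiseuille
  if (program$n_harmonics > 0) {
    w_s <- 2 * pi / (program$period / 1000)   # rad/s
    for (n in seq_len(program$n_harmonics)) {
      alpha <- R * sqrt(n * w_s / spec$viscosity)
      zeta <- alpha * exp(3i * pi / 4)
      bz <- bessel_j01_complex(c(zeta, zeta * r / R))
      j0z <- bz$j0[1]; j1z <- bz$j1[1]; j0r <- bz$j0[-1]
      g <- (1 - j0r / j0z) / (1 - 2 * j1z / (zeta * j0z))
      qhat <- (program$an[n] - 1i * program$bn[n]) * 1000  # mm^3/s
      u <- u + Re(qhat / A * g * exp(1i * n * 2 * pi * t_ms / program$period))
    }
  }
  u / 10                                      # cm/s
}

# Shared helper: axial Womersley velocity volume for one tube.
# Returns (nx*ny) x nt matrix of vz (cm/s) at the grid's (x, y) columns.
tube_axial_matrix <- function(xs, ys, center_xy, program, spec, t_ms) {
  R <- spec$tube_radius
  xy <- expand.grid(x = xs, y = ys)
  rr <- sqrt((xy$x - center_xy[1])^2 + (xy$y - center_xy[2])^2)
  inside <- rr < R
  out <- matrix(0, nrow(xy), length(t_ms))
  if (any(inside)) {
    rin <- rr[inside]
    prof <- vapply(t_ms, function(tv) womersley_profile(rin, tv, program, spec),
                   numeric(length(rin)))
    out[inside, ] <- prof
  }
  out
}

# Grid world axes for a phantom spec, centred on the world origin
phantom_grid_axes <- function(spec) {
  lapply(1:3, function(a) {
    n <- spec$grid_shape[a]
    (seq_len(n) - (n + 1) / 2) * spec$spacing
  })
}

phantom_origin <- function(spec) {
  -(spec$grid_shape - 1) / 2 * spec$spacing
}

#' Simulate a pulsatile tube-flow phantom dataset
#'
#' Samples Womersley flow in a rigid tube (axis along z, centred in the
#' grid) onto a voxel grid over one cardiac cycle. All voxels outside the
#' tube are stationary. The returned ground truth is computed from the
#' analytic program, not from the voxelized field: the per-beat volume
#' equals the program's stroke volume exactly.
#'
#' @param spec a [phantom_spec()] with `geometry = "tube"`.
#' @param program a [pump_program()].
#' @param center_xy tube axis position in world mm, default the grid centre.
#' @return A list with elements `field` (a [velocity_field()]) and `truth`
#'   (per-beat `volume_ml`, per-phase `flow_ml_s` and `time_ms`,
#'   `stationary_mask`, and a ready-made analysis `plane` and `contour`
#'   enclosing the tube).
#' @export
simulate_tube_dataset <- function(spec, program, center_xy = c(0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(program, "pump_program"))
  if (spec$geometry != "tube") stop("spec geometry must be 'tube'", call. = FALSE)
  ax <- phantom_grid_axes(spec)
  nt <- spec$n_phases
  t_ms <- (seq_len(nt) - 1) * program$period / nt
  d <- c(spec$grid_shape, nt, 3L)
  vel <- array(0, dim = d)
  vz <- tube_axial_matrix(ax[[1]], ax[[2]], center_xy, program, spec, t_ms)
  # broadcast over z (flow is axis-invariant): vz is (nx*ny) x nt
  for (k in seq_len(nt)) {
    vel[, , , k, 3] <- array(vz[, k], dim = spec$grid_shape[c(1, 2)])
  }
  field <- velocity_field(vel, voxel_spacing = rep(spec$spacing, 3),
                          origin = phantom_origin(spec),
                          rr_interval = program$period)
  xy <- expand.grid(x = ax[[1]], y = ax[[2]])
  rr <- sqrt((xy$x - center_xy[1])^2 + (xy$y - center_xy[2])^2)
  stat2d <- rr >= spec$tube_radius + spec$spacing
  stationary <- array(rep(stat2d, spec$grid_shape[3]), dim = spec$grid_shape)
  half <- spec$tube_radius + 2 * spec$spacing
  ps <- spec$spacing / 3
  npix <- 2L * ceiling(half / ps) + 1L
  plane <- analysis_plane(origin = c(center_xy, 0), normal = c(0, 0, 1),
                          pixel_spacing = ps, extent = c(npix, npix))
  contour <- circle_contour(c(0, 0), spec$tube_radius + spec$spacing)
  truth <- list(volume_ml = program$stroke_volume,
                flow_ml_s = pump_flow_rate(program, t_ms),
                time_ms = t_ms,
                stationary_mask = stationary,
                plane = plane, contour = contour)
  list(field = field, truth = truth)
}

#' Simulate an idealized two-vessel (aorta + pulmonary) phantom
#'
#' Two parallel Womersley tubes carrying the same pump program, emulating a
#' shunt-free systemic/pulmonary pair with equal beat volumes; the true
#' QP/QS ratio is exactly 1.
#'
#' @param spec a [phantom_spec()] with `geometry = "tube"`; the grid must be
#'   wide enough (x direction) to hold both tubes plus stationary margins.
#' @param program a [pump_program()] shared by both vessels.
#' @param separation distance between the tube axes, mm.
#' @return As [simulate_tube_dataset()], but `truth` carries per-vessel
#'   planes/contours (`plane_systemic`, `plane_pulmonary`, `contour`) and
#'   `qp_qs = 1`.
#' @export
simulate_two_tube_dataset <- function(spec, program, separation = 60) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- phantom_grid_axes(spec)
  need <- separation / 2 + spec$tube_radius + 2 * spec$spacing
  if (need > spec$grid_shape[1] * spec$spacing / 2) {
    stop("geometry error: two tubes do not fit in the grid", call. = FALSE)
  }
  centers <- list(systemic = c(-separation / 2, 0),
                  pulmonary = c(separation / 2, 0))
  nt <- spec$n_phases
  t_ms <- (seq_len(nt) - 1) * program$period / nt
  vel <- array(0, dim = c(spec$grid_shape, nt, 3L))
  xy <- expand.grid(x = ax[[1]], y = ax[[2]])
  stat2d <- rep(TRUE, nrow(xy))
  for (ctr in centers) {
    vz <- tube_axial_matrix(ax[[1]], ax[[2]], ctr, program, spec, t_ms)
    for (k in seq_len(nt)) {
      vel[, , , k, 3] <- vel[, , , k, 3] +
        array(vz[, k], dim = spec$grid_shape)  # recycles over z
    }
    rr <- sqrt((xy$x - ctr[1])^2 + (xy$y - ctr[2])^2)
    stat2d <- stat2d & (rr >= spec$tube_radius + spec$spacing)
  }
  field <- velocity_field(vel, voxel_spacing = rep(spec$spacing, 3),
                          origin = phantom_origin(spec),
                          rr_interval = program$period)
  stationary <- array(rep(stat2d, spec$grid_shape[3]), dim = spec$grid_shape)
  half <- spec$tube_radius + 2 * spec$spacing
  ps <- spec$spacing / 3
  npix <- 2L * ceiling(half / ps) + 1L
  mk_plane <- function(ctr) {
    analysis_plane(origin = c(ctr, 0), normal = c(0, 0, 1),
                   pixel_spacing = ps, extent = c(npix, npix))
  }
  truth <- list(volume_ml = program$stroke_volume, qp_qs = 1,
                flow_ml_s = pump_flow_rate(program, t_ms), time_ms = t_ms,
                stationary_mask = stationary,
                plane_systemic = mk_plane(centers$systemic),
                plane_pulmonary = mk_plane(centers$pulmonary),
                contour = circle_contour(c(0, 0), spec$tube_radius + spec$spacing))
  list(field = field, truth = truth)
}

#' Hill spherical vortex velocity field
#'
#' Classical Hill vortex of sphere radius `a` translating at speed `U` along
#' +z, in the laboratory frame (fluid at rest far away). Inside the sphere
#' the rotational interior solution applies; outside, the potential dipole
#' field, smoothly tapered to exactly zero between `taper[1]*a` and
#' `taper[2]*a` so that far-field voxels are truly stationary.
#'
#' @param points n x 3 matrix of world positions, mm.
#' @param ring_radius sphere radius `a`, mm.
#' @param speed translation speed `U`, cm/s.
#' @param center vortex centre, world mm.
#' @param taper inner/outer taper radii as multiples of `a`.
#' @return n x 3 matrix of velocities, cm/s.
#' @export
hill_vortex_velocity <- function(points, ring_radius, speed,
                                 center = c(0, 0, 0), taper = c(2, 3)) {
  points <- rbind(points)
  a <- ring_radius; U <- speed
  x <- points[, 1] - center[1]; y <- points[, 2] - center[2]
  z <- points[, 3] - center[3]
  s2 <- x^2 + y^2
  s <- sqrt(s2)
  R2 <- s2 + z^2
  R <- sqrt(R2)
  us <- uz <- numeric(length(s))
  inside <- R < a
  if (any(inside)) {
    us[inside] <- 1.5 * U * s[inside] * z[inside] / a^2
    uz[inside] <- 1.5 * U * (1 - (2 * s2[inside] + z[inside]^2) / a^2) + U
  }
  out <- !inside & R > 0
  if (any(out)) {
    R3 <- R[out]^3; R5 <- R[out]^5
    us[out] <- 1.5 * U * a^3 * s[out] * z[out] / R5
    uz[out] <- 0.5 * U * a^3 * (2 * z[out]^2 - s2[out]) / R5
    w <- rep(1, sum(out))
    rr <- R[out]
    ramp <- rr > taper[1] * a & rr < taper[2] * a
    w[ramp] <- 0.5 * (1 + cos(pi * (rr[ramp] - taper[1] * a) /
                                ((taper[2] - taper[1]) * a)))
    w[rr >= taper[2] * a] <- 0
    us[out] <- us[out] * w
    uz[out] <- uz[out] * w
  }
  fac <- ifelse(s > 0, us / s, 0)
  cbind(fac * x, fac * y, uz)
}

#' Simulate a vortex-ring phantom dataset
#'
#' Samples a static Hill spherical vortex (the idealized vortex ring formed
#' downstream of a pump nozzle) onto the voxel grid, identically for every
#' cardiac phase. Ground-truth kinetic energy inside the vortex sphere is
#' computed by midpoint quadrature of the analytic field at `refine`-fold
#' finer spacing than the acquisition grid.
#'
#' @param spec a [phantom_spec()] with `geometry = "vortex_ring"`.
#' @param refine truth-quadrature refinement factor relative to the grid.
#' @return A list with `field` (a [velocity_field()], RR fixed at 1000 ms)
#'   and `truth` (`ke_mj` per phase, `region_mask` = voxels inside the
#'   sphere, `stationary_mask`, `ring_radius`, `speed`).
#' @export
simulate_vortex_ring_dataset <- function(spec, refine = 4L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry != "vortex_ring") {
    stop("spec geometry must be 'vortex_ring'", call. = FALSE)
  }
  ax <- phantom_grid_axes(spec)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  v <- hill_vortex_velocity(pts, spec$ring_radius, spec$ring_speed)
  nt <- spec$n_phases
  vel <- array(0, dim = c(spec$grid_shape, nt, 3L))
  for (k in seq_len(nt)) {
    for (c_ in 1:3) vel[, , , k, c_] <- array(v[, c_], dim = spec$grid_shape)
  }
  field <- velocity_field(vel, voxel_spacing = rep(spec$spacing, 3),
                          origin = phantom_origin(spec),
                          rr_interval = 1000)
  R2 <- rowSums(pts^2)
  region <- array(R2 < spec$ring_radius^2, dim = spec$grid_shape)
  stationary <- array(sqrt(R2) >= 3 * spec$ring_radius + spec$spacing,
                      dim = spec$grid_shape)
  ke <- hill_vortex_ke_quadrature(spec$ring_radius, spec$ring_speed,
                                  spec$density, spec$spacing / refine)
  truth <- list(ke_mj = rep(ke, nt), region_mask = region,
                stationary_mask = stationary,
                ring_radius = spec$ring_radius, speed = spec$ring_speed)
  list(field = field, truth = truth)
}

# Midpoint-rule KE (mJ) of the analytic Hill vortex over the interior sphere
hill_vortex_ke_quadrature <- function(a, U, density, h) {
  n <- ceiling(2 * a / h)
  ax <- (seq_len(n) - (n + 1) / 2) * h
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  keep <- rowSums(pts^2) < a^2
  v <- hill_vortex_velocity(pts[keep, , drop = FALSE], a, U)
  # 0.5 * rho[g/mL] * dV[mm^3] * v^2[(cm/s)^2] * 1e-7 -> mJ
  0.5 * density * h^3 * sum(v^2) * 1e-7
}

#' Encode a velocity field as a phase-contrast acquisition
#'
#' Forward model of the scanner's velocity encoding: per axis, the phase is
#' `wrap(pi * (v + v_bg(x) + noise) / venc)` into `[-pi, pi)`, producing
#' exactly the corruptions the preprocessing stage must undo (aliasing at
#' VENC, affine background offsets, Gaussian velocity noise).
#'
#' @param field a [velocity_field()].
#' @param background optional [background_model()] added before encoding.
#' @param noise_sd Gaussian velocity-noise SD, cm/s (>= 0).
#' @param venc velocity-encoding limit per axis, cm/s.
#' @param seed optional integer; if given, noise is reproducible.
#' @return A [phase_field()].
#' @export
encode_acquisition <- function(field, background = NULL, noise_sd = 0,
                               venc = field$venc, seed = NULL) {
  venc <- rep_len(as.numeric(venc), 3L)
  if (any(venc <= 0)) stop("parameter error: venc must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(field$velocities)
  v <- field$velocities
  if (!is.null(background)) {
    bg <- background_volumes(field, background)
    for (k in seq_len(d[4])) {
      for (c_ in 1:3) v[, , , k, c_] <- v[, , , k, c_] + bg[[c_]]
    }
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  ph <- v
  for (c_ in 1:3) {
    x <- pi * v[, , , , c_] / venc[c_]
    ph[, , , , c_] <- ((x + pi) %% (2 * pi)) - pi
  }
  phase_field(ph, voxel_spacing = field$voxel_spacing, origin = field$origin,
              rr_interval = field$rr_interval, venc = venc)
}

# Evaluate a background model on the (separable) grid: list of three 3-D vols
background_volumes <- function(field, model) {
  ax <- grid_world_axes(field)
  d <- dim(field$velocities %||% field$phases)[1:3]
  X <- array(rep(ax[[1]], times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), dim = d)
  co <- model$coefficients
  lapply(1:3, function(c_) {
    co[c_, 1] + co[c_, 2] * X + co[c_, 3] * Y + co[c_, 4] * Z
  })
}

#' Draw a random first-order background model
#'
#' Coefficients drawn uniformly: offsets within `max_offset` cm/s, spatial
#' gradients within `max_gradient` cm/s per mm — the magnitudes typical of
#' eddy-current background offsets at the great vessels.
#'
#' @param max_offset bound on |a0|, cm/s.
#' @param max_gradient bound on |ax|, |ay|, |az|, cm/s per mm.
#' @param seed optional integer seed.
#' @return A [background_model()].
#' @export
random_background_model <- function(max_offset = 5, max_gradient = 0.05,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  background_model(cbind(stats::runif(3, -max_offset, max_offset),
                         matrix(stats::runif(9, -max_gradient, max_gradient), 3)))
}

#' Simulate a paired-cohort measurement table
#'
#' Generates the measurement table of a method-comparison study: per subject
#' and vessel, a reference (2D-flow) flow volume and a test (4D-flow) value
#' offset by a prescribed bias plus Gaussian disagreement — the input
#' expected by [build_comparison_table()].
#'
#' @param n_subjects number of subjects.
#' @param vessels vessel labels (become the `metric` column).
#' @param vessel_mean mean reference flow volume per vessel, mL (recycled).
#' @param subject_sd between-subject SD of the reference volume, mL.
#' @param offset_4d prescribed mean 4D - 2D difference, mL.
#' @param diff_sd SD of the 4D - 2D difference, mL.
#' @param seed optional integer seed.
#' @return A tibble with columns `subject`, `occasion`, `scanner`, `method`,
#'   `metric`, `value`.
#' @export
simulate_cohort_measurements <- function(n_subjects = 10,
                                         vessels = c("AAo", "DAo", "PA"),
                                         vessel_mean = c(80, 55, 80),
                                         subject_sd = 10, offset_4d = -4,
                                         diff_sd = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vessel_mean <- rep_len(vessel_mean, length(vessels))
  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_along(vessels)) {
      ref <- stats::rnorm(1, vessel_mean[j], subject_sd)
      test <- ref + stats::rnorm(1, offset_4d, diff_sd)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = sprintf("S%02d", i), occasion = "d1", scanner = "A",
        method = c("2D", "4D"), metric = vessels[j], value = c(ref, test))
    }
  }
  dplyr::bind_rows(rows)
}
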