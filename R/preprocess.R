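# Preprocessing: phase decoding, first-order background phase correction,
# and temporal unwrapping of velocity aliasing.

#' Decode phase images to velocities
#'
#' Standard phase-contrast relation `v = venc * phi / pi` per encoding axis,
#' mapping phase in `[-pi, pi)` to velocity in `[-venc, venc)`.
#'
#' @param phase a [phase_field()].
#' @param venc velocity-encoding limit per axis, cm/s (defaults to the
#'   field's own).
#' @return A [velocity_field()].
#' @export
decode_velocity <- function(phase, venc = phase$venc) {
  venc <- rep_len(as.numeric(venc), 3L)
  if (any(venc <= 0)) stop("parameter error: venc must be positive", call. = FALSE)
  v <- phase$phases
  for (c_ in 1:3) v[, , , , c_] <- venc[c_] * phase$phases[, , , , c_] / pi
  velocity_field(v, voxel_spacing = phase$voxel_spacing, origin = phase$origin,
                 rr_interval = phase$rr_interval, venc = venc)
}

#' Fit a first-order background phase model on stationary tissue
#'
#' Ordinary least-squares fit, per velocity component, of the time-averaged
#' velocity in stationary voxels against world coordinates:
#' `v = a0 + ax*x + ay*y + az*z`. The background is modelled as static
#' (time-independent), so the fit uses the temporal mean.
#'
#' @param field a [velocity_field()].
#' @param stationary logical 3-D mask of stationary voxels (same grid).
#' @return A [background_model()].
#' @export
fit_background <- function(field, stationary) {
  d <- dim(field$velocities)
  if (!identical(dim(stationary), d[1:3])) {
    stop("stationary mask must match the voxel grid", call. = FALSE)
  }
  idx <- which(stationary)
  if (length(idx) < 4L) {
    stop("rank-deficiency error: need >= 4 stationary voxels", call. = FALSE)
  }
  nvox <- prod(d[1:3])
  ax <- grid_world_axes(field)
  ijk <- arrayInd(idx, d[1:3])
  X <- cbind(1, ax[[1]][ijk[, 1]], ax[[2]][ijk[, 2]], ax[[3]][ijk[, 3]])
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    spans <- vapply(2:4, function(j) diff(range(X[, j])), numeric(1))
    flat <- c("x", "y", "z")[spans <= .Machine$double.eps * 100]
    stop("rank-deficiency error: stationary voxels are coplanar",
         if (length(flat)) paste0(" (no spread along ",
                                  paste(flat, collapse = ", "), ")"),
         call. = FALSE)
  }
  co <- matrix(0, 3, 4)
  for (c_ in 1:3) {
    vmat <- matrix(field$velocities[, , , , c_], nrow = nvox)  # nvox x nt
    vmean <- rowMeans(vmat)[idx]
    co[c_, ] <- qr.coef(qrX, vmean)
  }
  background_model(co)
}

#' Subtract a background model from a velocity field
#'
#' Removes the fitted affine background velocity at every voxel, identically
#' for every cardiac phase (the model is time-independent).
#'
#' @param field a [velocity_field()].
#' @param model a [background_model()] in the same world frame.
#' @return The corrected [velocity_field()].
#' @export
subtract_background <- function(field, model) {
  bg <- background_volumes(field, model)
  v <- field$velocities
  for (k in seq_len(field$n_phases)) {
    for (c_ in 1:3) v[, , , k, c_] <- v[, , , k, c_] - bg[[c_]]
  }
  field$velocities <- v
  field
}

#' Automatic stationary-tissue mask
#'
#' Fallback when no stationary mask is supplied: voxels whose velocity
#' varies little over the cardiac cycle (temporal SD below `sd_threshold`
#' on every component) are taken as stationary.
#'
#' @param field a [velocity_field()].
#' @param sd_threshold temporal velocity SD threshold, cm/s.
#' @return Logical 3-D mask.
#' @export
auto_stationary_mask <- function(field, sd_threshold = 2) {
  d <- dim(field$velocities)
  nvox <- prod(d[1:3])
  ok <- rep(TRUE, nvox)
  for (c_ in 1:3) {
    vmat <- matrix(field$velocities[, , , , c_], nrow = nvox)
    mu <- rowMeans(vmat)
    sd_t <- sqrt(rowSums((vmat - mu)^2) / max(1, d[4] - 1))
    ok <- ok & sd_t < sd_threshold
  }
  array(ok, dim = d[1:3])
}

#' Unwrap velocity aliasing along the time axis
#'
#' Temporal phase unwrapping per voxel and velocity component: scanning
#' phases cyclically from the phase of minimum global mean speed (the phase
#' least likely to be aliased), each inter-phase velocity jump larger than
#' VENC is corrected by the multiple of `2*venc` that minimises the jump,
#' i.e. the result minimises total temporal variation among whole-wrap
#' corrections. Voxels whose best correction still needs more than one wrap
#' in a single step are counted in the `n_flagged` attribute.
#'
#' @param field a decoded [velocity_field()].
#' @param venc velocity-encoding limit per axis, cm/s.
#' @return The unwrapped [velocity_field()], with attribute `n_flagged`
#'   (count of voxel-steps that required more than a single wrap).
#' @export
unwrap_velocity <- function(field, venc = field$venc) {
  venc <- rep_len(as.numeric(venc), 3L)
  d <- dim(field$velocities)
  nt <- d[4]
  if (nt == 1L) {
    attr(field, "n_flagged") <- 0L
    return(field)
  }
  nvox <- prod(d[1:3])
  # reference phase: minimum global mean speed
  speed_sum <- numeric(nt)
  for (k in seq_len(nt)) {
    sp2 <- 0
    for (c_ in 1:3) sp2 <- sp2 + field$velocities[, , , k, c_]^2
    speed_sum[k] <- mean(sqrt(sp2))
  }
  t0 <- which.min(speed_sum)
  order_t <- ((t0 - 1 + seq_len(nt) - 1) %% nt) + 1
  flagged <- 0L
  v <- field$velocities
  for (c_ in 1:3) {
    vmat <- matrix(v[, , , , c_], nrow = nvox)  # nvox x nt
    prev <- vmat[, order_t[1]]
    for (k in order_t[-1]) {
      dv <- vmat[, k] - prev
      wraps <- round(dv / (2 * venc[c_]))
      flagged <- flagged + sum(abs(wraps) > 1L)
      cur <- vmat[, k] - 2 * venc[c_] * wraps
      vmat[, k] <- cur
      prev <- cur
    }
    v[, , , , c_] <- array(vmat, dim = d[1:4])
  }
  field$velocities <- v
  attr(field, "n_flagged") <- flagged
  field
}
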