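# Shared small fixtures, built in code. Sizes are deliberately modest: the
# acceptance tests exercise the full default-resolution phantom; unit tests
# use reduced grids/phase counts where the property under test allows it.

small_tube_spec <- function(n_phases = 20L) {
  phantom_spec("tube", grid_shape = c(24L, 24L, 6L), spacing = 2.9,
               n_phases = n_phases, tube_radius = 10)
}

# Memoised small tube dataset (SV 25 mL): several tests reuse it read-only
.small_tube_cache <- new.env(parent = emptyenv())
small_tube_sim <- function() {
  if (is.null(.small_tube_cache$sim)) {
    .small_tube_cache$sim <- simulate_tube_dataset(
      small_tube_spec(), pump_program(25, 1000))
  }
  .small_tube_cache$sim
}

# Uniform axial plug-flow field: v = (0, 0, vz) cm/s everywhere
uniform_field <- function(vz = 10, shape = c(30L, 30L, 4L), spacing = 1,
                          n_phases = 4L, rr = 1000) {
  vel <- array(0, dim = c(shape, n_phases, 3L))
  vel[, , , , 3] <- vz
  velocity_field(vel, voxel_spacing = rep(spacing, 3),
                 origin = -(shape - 1) / 2 * spacing, rr_interval = rr)
}

# Brute-force signed-rank enumeration oracle: all 2^n sign assignments
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% rk)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value / truth - 1), tol)
}

# Full pipeline on a simulated tube dataset: encode with background (+ noise),
# decode, fit/subtract background on the true stationary mask, unwrap,
# quantify through-plane flow. Returns the measured per-beat volume (mL).
corrected_tube_volume <- function(sim, background, noise_sd = 0, venc = 150,
                                  seed = NULL) {
  ph <- encode_acquisition(sim$field, background = background,
                           noise_sd = noise_sd, venc = venc, seed = seed)
  dec <- decode_velocity(ph)
  fit <- fit_background(dec, sim$truth$stationary_mask)
  unw <- unwrap_velocity(subtract_background(dec, fit))
  fc <- integrate_flow(extract_plane(unw, sim$truth$plane), sim$truth$contour)
  fc$flow_volume_ml
}
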