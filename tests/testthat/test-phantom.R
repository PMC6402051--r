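test_that("complex Bessel J0/J1 match an independent reference", {
  # frozen values from scipy.special.jv at z = alpha * exp(3i*pi/4),
  # the argument family used by the Womersley profile
  alphas <- c(1, 5, 12, 30, 84.85)
  ref0 <- c(0.984381781213087 + 0.24956604003665972i,
            -6.230082478666357 + 0.11603438155020229i,
            -128.5116261565384 + 546.9485524542472i,
            -46117602.577984735 + 109955713.18250631i,
            -4.923039951201331e+24 + 4.244261960094878e+23i)
  ref1 <- c(-0.3958682610197113 + 0.3075566313755365i,
            0.35977666677667064 - 5.797907901792625i,
            -526.9634358973478 - 141.34979335525625i,
            -108110203.69317998 - 46885734.67207211i,
            -4.020582241352217e+23 - 4.904303267205579e+24i)
  r <- pc4dflow:::bessel_j01_complex(alphas * exp(3i * pi / 4))
  expect_lt(max(Mod(r$j0 - ref0) / Mod(ref0)), 1e-12)
  expect_lt(max(Mod(r$j1 - ref1) / Mod(ref1)), 1e-12)
  # and base::besselJ on the real axis
  x <- c(0.3, 2, 7.5, 20)
  rb <- pc4dflow:::bessel_j01_complex(x)
  expect_equal(Re(rb$j0), besselJ(x, 0), tolerance = 1e-12)
  expect_equal(Re(rb$j1), besselJ(x, 1), tolerance = 1e-12)
})

test_that("pump program integrates to the stroke volume exactly", {
  for (sv in c(12, 37)) {
    pg <- pump_program(sv, period = 900)
    q <- pump_flow_rate(pg, seq(0, 900, length.out = 20001)[-20001])
    expect_equal(mean(q) * 0.9, sv, tolerance = 1e-9)
  }
})

test_that("steady Womersley flow is Poiseuille", {
  spec <- phantom_spec("tube", tube_radius = 12)
  pg <- pump_program(30, 1000, "constant")
  mean_v <- 30 * 1000 / (pi * 12^2) / 10  # cm/s
  expect_equal(womersley_velocity(0, 0, pg, spec), 2 * mean_v, tolerance = 1e-12)
  expect_equal(womersley_velocity(12, 123, pg, spec), 0, tolerance = 1e-12)
  r <- c(3, 6, 9)
  expect_equal(womersley_velocity(r, 0, pg, spec),
               2 * mean_v * (1 - (r / 12)^2), tolerance = 1e-12)
})

test_that("Womersley cross-sectional flux reproduces the programmed waveform", {
  spec <- phantom_spec("tube", tube_radius = 12)
  pg <- pump_program(30, 1000)
  for (tt in c(0, 120, 350, 700)) {
    flux <- integrate(Vectorize(function(r) {
      womersley_velocity(r, tt, pg, spec) * 10 * 2 * pi * r  # mm^3/s density
    }), 0, 12, rel.tol = 1e-10)$value / 1000
    expect_equal(flux, pump_flow_rate(pg, tt), tolerance = 1e-3 * abs(pg$a0))
  }
  expect_error(womersley_velocity(12.5, 0, pg, spec), "domain error")
})

test_that("tube dataset: construction truth and stationarity", {
  sim <- small_tube_sim()
  expect_equal(sim$truth$volume_ml, 25)
  # voxels flagged stationary are identically zero at every phase
  stat_idx <- which(sim$truth$stationary_mask)
  for (k in c(1, 10)) {
    vz <- sim$field$velocities[, , , k, 3]
    expect_true(all(vz[stat_idx] == 0))
  }
  # zero-amplitude waveform -> all-zero field
  sim0 <- simulate_tube_dataset(small_tube_spec(4L), pump_program(0, 1000))
  expect_true(all(sim0$field$velocities == 0))
  expect_equal(sim0$truth$volume_ml, 0)
  # tube larger than grid -> geometry error
  expect_error(phantom_spec("tube", tube_radius = 40,
                            grid_shape = c(20, 20, 6)), "geometry error")
})

test_that("quantified flow matches tube construction truth within 3%", {
  sim <- small_tube_sim()
  fc <- integrate_flow(extract_plane(sim$field, sim$truth$plane),
                       sim$truth$contour)
  expect_rel_error(fc$flow_volume_ml, sim$truth$volume_ml, 0.03)
})

test_that("voxel flow estimates converge toward truth with resolution", {
  pg <- pump_program(25, 1000)
  err <- vapply(list(c(24L, 24L, 4L), c(48L, 48L, 4L)), function(shp) {
    spec <- phantom_spec("tube", grid_shape = shp, tube_radius = 10,
                         spacing = 2.9 * 24 / shp[1], n_phases = 10L)
    sim <- simulate_tube_dataset(spec, pg)
    fc <- integrate_flow(extract_plane(sim$field, sim$truth$plane),
                         sim$truth$contour)
    abs(fc$flow_volume_ml / 25 - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("Hill vortex: null case, density linearity and KE truth", {
  spec <- phantom_spec("vortex_ring", grid_shape = c(24, 24, 24), spacing = 4.35,
                       ring_radius = 16, ring_speed = 0, n_phases = 2L)
  sim0 <- simulate_vortex_ring_dataset(spec)
  expect_true(all(sim0$field$velocities == 0))
  expect_equal(sim0$truth$ke_mj, c(0, 0))

  spec1 <- phantom_spec("vortex_ring", grid_shape = c(24, 24, 24),
                        spacing = 4.35, ring_radius = 16, ring_speed = 40,
                        n_phases = 1L, density = 1.0)
  spec2 <- spec1; spec2$density <- 2.0
  ke1 <- simulate_vortex_ring_dataset(spec1)$truth$ke_mj[1]
  ke2 <- simulate_vortex_ring_dataset(spec2)$truth$ke_mj[1]
  expect_equal(ke2, 2 * ke1, tolerance = 1e-12)
})

test_that("Hill vortex field is continuous at the sphere and tapers to rest", {
  a <- 16; U <- 50
  th <- seq(0, pi, length.out = 11)
  on_sphere <- cbind(a * sin(th), 0, a * cos(th))
  v_in <- hill_vortex_velocity(on_sphere * (1 - 1e-9), a, U)
  v_out <- hill_vortex_velocity(on_sphere * (1 + 1e-9), a, U)
  expect_lt(max(abs(v_in - v_out)), 1e-5 * U)
  far <- cbind(c(3.1 * a, 0, 60), c(0, 3.5 * a, 0), c(0, 0, -3.2 * a))
  expect_true(all(hill_vortex_velocity(far, a, U) == 0))
})

test_that("phase encoding wraps, offsets and reproduces under a seed", {
  f <- uniform_field(vz = 1.5 * 150, shape = c(6, 6, 4), n_phases = 2L)
  ph <- encode_acquisition(f, venc = 150)
  dec <- decode_velocity(ph)
  expect_equal(unique(as.numeric(dec$velocities[, , , , 3])), -0.5 * 150,
               tolerance = 1e-9)

  f0 <- uniform_field(vz = 0, shape = c(6, 6, 4), n_phases = 2L)
  bg <- background_model(cbind(c(0, 0, 10), matrix(0, 3, 3)))
  dec2 <- decode_velocity(encode_acquisition(f0, background = bg, venc = 150))
  expect_equal(unique(as.numeric(dec2$velocities[, , , , 3])), 10,
               tolerance = 1e-9)

  ph_a <- encode_acquisition(f0, noise_sd = 5, venc = 150, seed = 99)
  ph_b <- encode_acquisition(f0, noise_sd = 5, venc = 150, seed = 99)
  expect_identical(ph_a$phases, ph_b$phases)
  expect_error(encode_acquisition(f0, venc = -1), "parameter error")
})

test_that("encode then decode is the identity for unaliased noiseless fields", {
  sim <- small_tube_sim()
  dec <- decode_velocity(encode_acquisition(sim$field, venc = 150))
  expect_lt(max(abs(dec$velocities - sim$field$velocities)), 1e-10)
})

test_that("mass conservation: flow agrees on any two cross-sections", {
  sim <- small_tube_sim()
  p1 <- sim$truth$plane
  p2 <- p1; p2$origin[3] <- p1$origin[3] + 4.4
  f1 <- integrate_flow(extract_plane(sim$field, p1), sim$truth$contour)
  f2 <- integrate_flow(extract_plane(sim$field, p2), sim$truth$contour)
  expect_rel_error(f2$flow_volume_ml, f1$flow_volume_ml, 0.02)
})

test_that("cohort simulator produces a complete paired design", {
  m <- simulate_cohort_measurements(n_subjects = 5, seed = 3)
  expect_equal(nrow(m), 5 * 3 * 2)
  expect_setequal(unique(m$method), c("2D", "4D"))
  counts <- table(m$subject, m$metric, m$method)
  expect_true(all(counts == 1))
})
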