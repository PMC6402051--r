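test_that("plane extraction projects onto the plane normal", {
  f <- uniform_field(vz = 10, shape = c(20, 20, 8), spacing = 2)
  axial <- analysis_plane(c(0, 0, 0), c(0, 0, 1), pixel_spacing = 1,
                          extent = c(11, 11))
  pm <- extract_plane(f, axial)
  expect_true(all(abs(pm$v_through - 10) < 1e-12, na.rm = TRUE))

  sagittal <- analysis_plane(c(0, 0, 0), c(1, 0, 0), pixel_spacing = 1,
                             extent = c(11, 5))
  pm2 <- extract_plane(f, sagittal)
  expect_true(all(abs(pm2$v_through) < 1e-12, na.rm = TRUE))

  outside <- analysis_plane(c(500, 0, 0), c(0, 0, 1), extent = c(5, 5))
  expect_error(extract_plane(f, outside), "geometry error")
})

test_that("extracted tube profile matches the analytic Womersley profile", {
  # grid fine enough (1.5 mm voxels on a 10 mm tube) that trilinear
  # interpolation resolves the Stokes-layer curvature
  spec <- phantom_spec("tube", grid_shape = c(32L, 32L, 6L), spacing = 1.5,
                       n_phases = 20L, tube_radius = 10)
  pg <- pump_program(25, 1000)
  sim <- simulate_tube_dataset(spec, pg)
  pm <- extract_plane(sim$field, sim$truth$plane)
  pc <- pc4dflow:::plane_pixel_coords(sim$truth$plane)
  k <- 4L  # mid-ejection phase
  t_ms <- (k - 1) * 1000 / spec$n_phases
  peak <- max(abs(pm$v_through[, , k]), na.rm = TRUE)
  mid <- (length(pc$v) + 1) / 2
  for (iu in seq(3, length(pc$u) - 2, by = 4)) {
    r <- abs(pc$u[iu])
    if (r >= spec$tube_radius - 2 * spec$spacing) next  # skip wall band
    v_interp <- pm$v_through[iu, mid, k]
    v_true <- womersley_velocity(r, t_ms, pg, spec)
    expect_lt(abs(v_interp - v_true), 0.02 * peak)
  }
})

test_that("plug flow integrates to the closed-form rate and volume", {
  # uniform 10 cm/s; square contour enclosing exactly 500 pixel centres
  f <- uniform_field(vz = 10, shape = c(40, 40, 6), spacing = 1.5,
                     n_phases = 5L, rr = 1000)
  plane <- analysis_plane(c(0, 0, 0), c(0, 0, 1), pixel_spacing = 1,
                          extent = c(51, 51))
  pm <- extract_plane(f, plane)
  sq <- roi_contour(rbind(c(-9.75, -9.75), c(10.25, -9.75),
                          c(10.25, 15.25), c(-9.75, 15.25)))
  fc <- integrate_flow(pm, sq)
  # 10 cm/s over 20 x 25 = 500 mm^2 of pixel centres -> 50 mL/s, 50 mL/beat
  expect_equal(fc$flow_ml_s, rep(50, 5), tolerance = 1e-9)
  expect_equal(fc$flow_volume_ml, 50, tolerance = 1e-9)

  # zero field -> zero volume
  f0 <- uniform_field(vz = 0, shape = c(40, 40, 6), spacing = 1.5, n_phases = 5L)
  fc0 <- integrate_flow(extract_plane(f0, plane), sq)
  expect_equal(fc0$flow_volume_ml, 0)

  tiny <- circle_contour(c(0.5, 0.5), 0.2, n = 8)  # encloses no centres
  expect_error(integrate_flow(pm, tiny), "empty-ROI")
})

test_that("static fields give flow volume = mean rate x period exactly", {
  f <- uniform_field(vz = 7, shape = c(20, 20, 4), spacing = 2, n_phases = 9L,
                     rr = 850)
  plane <- analysis_plane(c(0, 0, 0), c(0, 0, 1), pixel_spacing = 1,
                          extent = c(21, 21))
  fc <- integrate_flow(extract_plane(f, plane), circle_contour(c(0, 0), 8))
  expect_equal(fc$flow_volume_ml, mean(fc$flow_ml_s) * 850 / 1000,
               tolerance = 1e-12)
})

test_that("flow volume is invariant to in-plane basis rotation", {
  sim <- small_tube_sim()
  base <- sim$truth$plane
  fc0 <- integrate_flow(extract_plane(sim$field, base), sim$truth$contour)
  th <- 0.7
  rotated <- analysis_plane(base$origin, base$normal,
                            u = cos(th) * base$u + sin(th) * base$v,
                            v = -sin(th) * base$u + cos(th) * base$v,
                            pixel_spacing = base$pixel_spacing,
                            extent = base$extent)
  fc1 <- integrate_flow(extract_plane(sim$field, rotated), sim$truth$contour)
  expect_rel_error(fc1$flow_volume_ml, fc0$flow_volume_ml, 0.01)
})

test_that("plug-flow volume converges as pixel spacing halves", {
  f <- uniform_field(vz = 10, shape = c(40, 40, 6), spacing = 1.5, n_phases = 2L)
  ct <- circle_contour(c(0, 0), 12)
  vols <- vapply(c(1, 0.5), function(ps) {
    n <- 2L * ceiling(15 / ps) + 1L
    pl <- analysis_plane(c(0, 0, 0), c(0, 0, 1), pixel_spacing = ps,
                         extent = c(n, n))
    integrate_flow(extract_plane(f, pl), ct)$flow_volume_ml
  }, numeric(1))
  exact <- 10 * pi * 12^2 * 0.01  # v * A * T
  # boundary-pixel fraction bounds the error, which shrinks with spacing
  expect_lt(abs(vols[2] - exact), abs(vols[1] - exact) + 1e-9)
  expect_rel_error(vols[2], exact, 2 * pi * 12 * 0.5 / (pi * 12^2))
})

test_that("contour transfer is exact and frame-equivariant", {
  src <- analysis_plane(c(10, -5, 3), c(1, 2, 2), pixel_spacing = 1,
                        extent = c(21, 21))
  tgt <- analysis_plane(c(10, -5, 3), c(1, 2, 2),
                        u = NULL, v = NULL, pixel_spacing = 0.7,
                        extent = c(31, 31))
  # rotate target in-plane basis so the transfer is non-trivial
  th <- 0.5
  tgt <- analysis_plane(tgt$origin, tgt$normal,
                        u = cos(th) * tgt$u + sin(th) * tgt$v,
                        v = -sin(th) * tgt$u + cos(th) * tgt$v,
                        pixel_spacing = 0.7, extent = c(31, 31))
  ct <- circle_contour(c(2, 1), 5, n = 12)
  there <- transfer_contour(ct, src, tgt)
  back <- transfer_contour(there, tgt, src)
  expect_lt(max(abs(back$vertices - ct$vertices)), 1e-9)

  # translating both frames by the same vector leaves local vertices unchanged
  shift <- c(4, 4, -2)
  src2 <- src; src2$origin <- src$origin + shift
  tgt2 <- tgt; tgt2$origin <- tgt$origin + shift
  there2 <- transfer_contour(ct, src2, tgt2)
  expect_equal(there2$vertices, there$vertices, tolerance = 1e-9)
})

test_that("a transferred contour yields matching flow on a resampled grid", {
  pg <- pump_program(25, 1000)
  spec1 <- small_tube_spec(10L)
  spec2 <- phantom_spec("tube", grid_shape = c(32L, 32L, 6L), spacing = 2.2,
                        n_phases = 10L, tube_radius = 10)
  sim1 <- simulate_tube_dataset(spec1, pg)
  sim2 <- simulate_tube_dataset(spec2, pg)
  ct2 <- transfer_contour(sim1$truth$contour, sim1$truth$plane,
                          sim2$truth$plane)
  f1 <- integrate_flow(extract_plane(sim1$field, sim1$truth$plane),
                       sim1$truth$contour)
  f2 <- integrate_flow(extract_plane(sim2$field, sim2$truth$plane), ct2)
  expect_rel_error(f2$flow_volume_ml, f1$flow_volume_ml, 0.02)
})

test_that("QP/QS is the plain flow ratio with a guarded domain", {
  expect_equal(qp_qs(60, 60), 1.0)
  expect_equal(qp_qs(78, 60), 1.3)
  expect_error(qp_qs(60, 0), "domain error")
})

test_that("the --flip sign convention negates the curve", {
  sim <- small_tube_sim()
  pm <- extract_plane(sim$field, sim$truth$plane)
  fc <- integrate_flow(pm, sim$truth$contour)
  fcf <- integrate_flow(pm, sim$truth$contour, flip = TRUE)
  expect_equal(fcf$flow_ml_s, -fc$flow_ml_s)
  expect_equal(fcf$flow_volume_ml, -fc$flow_volume_ml)
})
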