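test_that("rest state: zero inflow with zero afterload pressure stays at rest", {
  v <- vessel_spec()
  q <- generate_inlet_flow(60, 0, v$R_i, rate = 200)
  res <- simulate_pulse_wave(v, windkessel_spec(P_venous = 0), q,
                             n_cycles = 2, dx = 8e-3)
  expect_lt(max(abs(res$pressure)), 1e-9)
  expect_lt(max(abs(res$flow)), 1e-15)
})

test_that("mass is conserved over the reported cycle", {
  expect_lt(sim_open_coarse()$conservation, 0.01)
  expect_lt(sim_cath_coarse()$conservation, 0.01)
})

test_that("probe extraction is linear interpolation on the stored fields", {
  res <- sim_open_coarse()
  j <- 21L
  w <- pressure_at(res, res$x_grid[j])
  expect_equal(w$samples, res$pressure[, j], tolerance = 1e-12)
  # midpoint between nodes of the (piecewise-linear) interpolant
  xm <- (res$x_grid[j] + res$x_grid[j + 1]) / 2
  wm <- pressure_at(res, xm)
  expect_equal(wm$samples, (res$pressure[, j] + res$pressure[, j + 1]) / 2,
               tolerance = 1e-12)
  # the experimental probe layout: 10 positions, 20 mm apart
  pr <- probe_pressures(res, seq(0.02, 0.20, by = 0.02))
  expect_length(pr, 10L)
  expect_true(all(vapply(pr, function(p)
    inherits(p$waveform, "pressure_waveform"), logical(1))))
  expect_error(pressure_at(res, 0.5), "outside")
})

test_that("catheter insertion raises peak and mean pressure at the tip", {
  p_open <- pressure_at(sim_open_coarse(), 0.14)$samples
  p_cath <- pressure_at(sim_cath_coarse(), 0.14)$samples
  expect_gt(max(p_cath), max(p_open))
  expect_gt(mean(p_cath), mean(p_open))
})

test_that("halving the grid changes the peak probe pressure by far less than 1%", {
  pk4 <- max(pressure_at(sim_open_coarse(), 0.14)$samples)
  fine <- cached("open2_n4", simulate_pulse_wave(
    default_vessel(), windkessel_spec(), default_inflow(),
    n_cycles = 4, dx = 2e-3))
  pk2 <- max(pressure_at(fine, 0.14)$samples)
  expect_lt(abs(pk4 - pk2) / pk2, 0.01)
})

test_that("invalid configurations are rejected with clear diagnostics", {
  v <- vessel_spec()
  q <- default_inflow()
  expect_error(simulate_pulse_wave(v, windkessel_spec(), q,
                                   catheter_insertion(R_c = 9e-3)), "R_c")
  expect_error(simulate_pulse_wave(v, windkessel_spec(), q,
                                   catheter_insertion(tip_position = 0.9)),
               "tip")
  expect_error(simulate_pulse_wave(v, windkessel_spec(), q,
                                   dt_internal = 0.002), "CFL")
  # discontinuous periodic extension of the inflow
  bad <- flow_waveform(seq(0, 1e-5, length.out = 200), rate = 200)
  expect_error(simulate_pulse_wave(v, windkessel_spec(), bad), "periodic")
})

test_that("windkessel tuning drives the tip peak towards the target", {
  v <- vessel_spec()
  q <- default_inflow()
  wk0 <- windkessel_spec(Rp = 5e8)
  wk <- tune_windkessel(v, q, target_psys = 106.4, probe_x = 0.14,
                        windkessel = wk0, iterations = 2,
                        n_cycles = 4, dx = 4e-3)
  res <- simulate_pulse_wave(v, wk, q, n_cycles = 4, dx = 4e-3)
  pk <- max(pressure_at(res, 0.14)$samples)
  expect_lt(abs(pk - 106.4), 2)
})
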