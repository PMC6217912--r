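test_that("generated waveform honours the amplitude contract", {
  w <- generate_pressure_waveform(waveform_params())
  expect_lt(abs(max(w$samples) - 106.4), 0.5)
  expect_lt(abs(min(w$samples) - 5.54), 0.5)
  expect_equal(length(w$samples), 10 * 100)
})

test_that("waveform parameter validation names the offending field", {
  expect_error(waveform_params(heart_rate = -1), "heart_rate")
  expect_error(waveform_params(p_sys = 50, p_dia = 80), "p_sys")
  expect_error(waveform_params(ring_freq = 0.5), "ring_freq")
  expect_error(waveform_params(n_cycles = 0), "n_cycles")
  expect_error(waveform_params(rate = NaN), "rate")
})

test_that("degenerate flat configuration yields a constant record", {
  w <- generate_pressure_waveform(
    waveform_params(p_sys = 80, p_dia = 80, ring_amp = 0))
  expect_true(all(w$samples == 80))
})

test_that("without the ring the diastolic decay has no local maximum", {
  w <- generate_pressure_waveform(waveform_params(ring_amp = 0, n_cycles = 1))
  cyc <- w$samples
  ipk <- which.max(cyc)
  d <- diff(cyc[ipk:length(cyc)])
  expect_true(all(d <= 0))
})

test_that("noiseless waveform is cycle-periodic for commensurate ring frequency", {
  # the dicrotic oscillator is phase-coherent across cycles, so exact
  # periodicity requires ring_freq to be a harmonic of the heart rate
  w <- generate_pressure_waveform(waveform_params(ring_freq = 5))
  m <- matrix(w$samples, ncol = 10)
  rms <- sqrt(mean((m[, -1] - m[, 1])^2))
  expect_lt(rms, 1e-6)
  # and for any ring frequency once the ring is absent
  w0 <- generate_pressure_waveform(waveform_params(ring_amp = 0))
  m0 <- matrix(w0$samples, ncol = 10)
  expect_lt(sqrt(mean((m0[, -1] - m0[, 1])^2)), 1e-6)
})

test_that("synthetic inlet flow has the prescribed cycle-mean and is periodic", {
  r <- 8e-3
  q <- generate_inlet_flow(60, 0.0821, r, rate = 1000)
  target <- 0.0821 * pi * r^2          # 1.651e-5 m^3/s
  expect_lt(abs(mean(q$samples) - target) / target, 0.01)
  expect_lt(abs(target - 1.651e-5) / 1.651e-5, 1e-3)
  # continuity of the periodic extension
  expect_lt(abs(q$samples[1] - q$samples[length(q$samples)]),
            1e-6 * max(q$samples))
  # linearity in mean velocity, and the zero-flow edge case
  q2 <- generate_inlet_flow(60, 2 * 0.0821, r, rate = 1000)
  expect_equal(mean(q2$samples), 2 * mean(q$samples), tolerance = 1e-12)
  q0 <- generate_inlet_flow(60, 0, r, rate = 1000)
  expect_true(all(q0$samples == 0))
  expect_error(generate_inlet_flow(0, 0.1, r), "heart_rate")
})

test_that("bubble distortion smooths the trace and passes through in the stiff limit", {
  w <- generate_pressure_waveform(waveform_params(n_cycles = 3))
  b <- add_bubble_distortion(w, degraded_fn = 3, degraded_zeta = 1.5)
  expect_equal(length(b$samples), length(w$samples))
  expect_equal(b$rate, w$rate)
  cs_clean <- curvature_sum(w, cycle_period = 1)$curvature_sum
  cs_bubble <- curvature_sum(b, cycle_period = 1)$curvature_sum
  expect_lt(cs_bubble, cs_clean)

  # f_n -> infinity limit: the transducer is transparent
  w1 <- generate_pressure_waveform(waveform_params(n_cycles = 1))
  p <- add_bubble_distortion(w1, degraded_fn = 1e4, degraded_zeta = 0.7)
  trans <- attr(p, "transient")
  keep <- wave_times(w1) > trans
  expect_lt(max(abs(p$samples[keep] - w1$samples[keep])), 0.1)

  # constant input -> identical constant output (unit DC gain)
  const <- pressure_waveform(rep(60, 200), rate = 100)
  out <- add_bubble_distortion(const, 3, 1.5)
  expect_lt(max(abs(out$samples - 60)), 1e-9)
})
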