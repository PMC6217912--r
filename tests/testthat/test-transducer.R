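test_that("consistency triangle: stated f_n implies dP/dV and the stated damping", {
  cs <- catheter_spec()   # 6F catheter anchored at f_n = 40 Hz
  # oracle: invert the natural-frequency expression directly
  dpdv_expected <- (2 * pi * 40)^2 * 998 * 0.8 / (pi * 0.32e-3^2)
  expect_equal(cs$dPdV, dpdv_expected, tolerance = 1e-10)
  expect_equal(cs$dPdV, 1.5677e14, tolerance = 1e-4)
  expect_equal(cs$f_n, 40, tolerance = 1e-6)
  expect_lt(abs(cs$zeta - 0.15) / 0.15, 0.05)   # printed value, within 5%
})

test_that("natural frequency and damping scale as the mass-spring formulas", {
  cs <- catheter_spec()
  f0 <- natural_frequency(cs)
  expect_equal(natural_frequency(cs, 4 * cs$dPdV), 2 * f0, tolerance = 1e-12)
  cl <- catheter_spec(l = 4 * cs$l, f_n = NULL, dPdV = cs$dPdV)
  expect_equal(natural_frequency(cl), f0 / 2, tolerance = 1e-12)
  z0 <- damping_coefficient(cs)
  cm <- within_spec(cs, mu = 2 * cs$mu)
  expect_equal(damping_coefficient(cm, cs$dPdV), 2 * z0, tolerance = 1e-12)
  cr <- list(R = 2 * cs$R, l = cs$l, mu = cs$mu, rho = cs$rho)
  expect_equal(damping_coefficient(cr, cs$dPdV), z0 / 8, tolerance = 1e-12)
})

test_that("modulus and compliance conversions are exact inverses and linear", {
  cs <- catheter_spec()
  x <- 1e14
  expect_equal(compliance_from_modulus(
    within_spec(cs, E_cath = modulus_from_compliance(cs, x))), x,
    tolerance = 1e-14)
  e1 <- compliance_from_modulus(cs)
  e2 <- compliance_from_modulus(within_spec(cs, E_cath = 2 * cs$E_cath))
  expect_equal(e2, 2 * e1, tolerance = 1e-14)
})

test_that("stored and derived transducer values must be mutually consistent", {
  dpdv <- (2 * pi * 40)^2 * 998 * 0.8 / (pi * 0.32e-3^2)
  expect_silent(catheter_spec(dPdV = dpdv, f_n = 40))
  expect_error(catheter_spec(dPdV = dpdv, f_n = 45), "f_n")
  expect_error(catheter_spec(dPdV = dpdv, zeta = 0.3), "zeta")
})

test_that("analytic amplitude response has the textbook landmarks", {
  expect_identical(amplitude_response(0, 40, 0.15), 1)
  expect_equal(amplitude_response(40, 40, 0.15), 1 / (2 * 0.15),
               tolerance = 1e-12)
  f <- seq(0, 400, by = 0.5)
  expect_true(all(amplitude_response(f, 40, 1 / sqrt(2)) <= 1 + 1e-9))
  expect_error(amplitude_response(-1, 40, 0.15), "f")
})

test_that("time-domain transducer matches the analytic gain within 2%", {
  f_n <- 2; rate <- 400
  for (zeta in c(0.15, 0.8)) {
    for (r in c(0.1, 0.5, 1, 2, 5)) {
      f <- r * f_n
      dur <- max(12, 6 / f + 4 / (zeta * 2 * pi * f_n))
      tt <- seq(0, dur, by = 1 / rate)
      w <- pressure_waveform(10 * sin(2 * pi * f * tt), rate = rate)
      out <- measure_with_catheter(w, f_n, zeta)
      gain <- tail_amplitude(out, keep_s = 2 / f) / 10
      expect_lt(abs(gain - amplitude_response(f, f_n, zeta)) /
                  amplitude_response(f, f_n, zeta), 0.02)
    }
  }
})

test_that("transducer has unit DC gain and strong high-frequency attenuation", {
  const <- pressure_waveform(rep(100, 500), rate = 100)
  out <- measure_with_catheter(const, f_n = 40, zeta = 0.15)
  expect_lt(max(abs(out$samples - 100)), 0.01)

  # pure sinusoid a decade above f_n is almost erased
  rate <- 2000; f_n <- 2; f <- 10 * f_n
  tt <- seq(0, 10, by = 1 / rate)
  w <- pressure_waveform(sin(2 * pi * f * tt), rate = rate)
  out <- measure_with_catheter(w, f_n, zeta = 0.15)
  expect_lt(tail_amplitude(out, keep_s = 1), 0.02)
})

test_that("critically damped systems never amplify sinusoidal peak-to-peak", {
  rate <- 500; f_n <- 2
  for (f in c(0.2, 1, 2, 5, 20)) {
    tt <- seq(0, max(8, 3 / f), by = 1 / rate)
    w <- pressure_waveform(sin(2 * pi * f * tt), rate = rate)
    out <- measure_with_catheter(w, f_n, zeta = 0.8)
    expect_lte(tail_amplitude(out, keep_s = 2 / f), 1 + 1e-6)
  }
})

test_that("non-positive damping is rejected as unstable", {
  w <- pressure_waveform(rep(1, 10), rate = 10)
  expect_error(measure_with_catheter(w, 40, 0), "instab|zeta")
  expect_error(measure_with_catheter(w, 40, -0.1), "instab|zeta")
})
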