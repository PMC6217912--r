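test_that("feature extraction recovers the waveform's landmark pressures", {
  w <- generate_pressure_waveform(waveform_params())
  f <- extract_features(w, cycle_period = 1)
  expect_lt(abs(f$P_s - 106.4), 0.5)
  expect_lt(abs(f$P_d - 5.54), 0.5)
  expect_lt(abs(f$pulse_pressure - 100.86), 1.0)
  expect_identical(f$pulse_pressure, f$P_s - f$P_d)
  expect_true(f$notch_present)
  # the notch lies between the systolic peak and the cycle end
  t_peak <- (which.max(w$samples[901:1000]) - 1) / 100 + 9
  expect_gt(f$notch_time, t_peak)
  expect_lt(f$notch_time, 10)
})

test_that("features of degenerate records", {
  const <- pressure_waveform(rep(80, 200), rate = 100)
  f <- extract_features(const, cycle_period = 1)
  expect_identical(f$P_s, f$P_d)
  expect_identical(f$pulse_pressure, 0)
  expect_false(f$notch_present)
  expect_true(is.na(f$foot_time))

  noring <- generate_pressure_waveform(waveform_params(ring_amp = 0))
  expect_false(extract_features(noring, cycle_period = 1)$notch_present)

  expect_error(extract_features(const, cycle_period = 5), "complete cycle")
})

test_that("foot detection: ramp identity, translation equivariance, smoothing delay", {
  rate <- 100
  tt <- seq(0, 2, by = 1 / rate)
  ramp <- pmax(0, pmin(1, (tt - 0.5) / 0.4)) * 50 + 10
  w <- pressure_waveform(ramp, rate = rate)
  expect_lt(abs(detect_foot(w) - 0.5), 1 / rate + 1e-9)

  # exact 10 ms shift (one sample at 100 Hz)
  cyc <- generate_pressure_waveform(waveform_params(n_cycles = 2))
  shifted <- pressure_waveform(c(cyc$samples[1], head(cyc$samples, -1)),
                               rate = cyc$rate)
  f0 <- detect_foot(cyc, cycle_start = 0.2, window = 1)
  f1 <- detect_foot(shifted, cycle_start = 0.21, window = 1)
  expect_lt(abs((f1 - f0) - 0.01), 1e-4)

  # heavy low-pass smoothing delays the detected upstroke
  lp <- measure_periodic(cyc, f_n = 3, zeta = 1.5, period = 1)
  f_clean <- detect_foot(cyc, cycle_start = 1, window = 1)
  f_lp <- detect_foot(lp, cycle_start = lp$t0, window = 1)
  expect_gt(f_lp %% 1, f_clean %% 1)

  flat <- pressure_waveform(rep(3, 100), rate = 100)
  expect_error(detect_foot(flat), "upstroke")
})

test_that("foot-to-foot PWV is exact on constructed pure-delay probe sets", {
  rate <- 1000
  tt <- seq(0, 1.5, by = 1 / rate)
  shape <- function(t) 10 + 90 / (1 + exp(-(t - 0.4) / 0.01))
  mk <- function(delay) pressure_waveform(shape(tt - delay), rate = rate)

  # two probes 100 mm apart, 16.6 ms transit -> 6.02 m/s
  probes <- list(list(position = 0.02, waveform = mk(0)),
                 list(position = 0.12, waveform = mk(0.0166)))
  pw <- pwv_foot_to_foot(probes, dx = 0.10)
  expect_lt(abs(pw$pwv - 0.10 / 0.0166) / (0.10 / 0.0166), 0.01)

  # three pairs with 10 ms transit at 80 mm -> 8 m/s, mean of ratios
  probes4 <- lapply(0:3, function(i)
    list(position = 0.02 + 0.08 * i, waveform = mk(0.01 * i)))
  pw3 <- pwv_foot_to_foot(probes4, dx = 0.08)
  expect_equal(nrow(pw3$pairs), 3L)
  expect_equal(pw3$pwv, 8, tolerance = 1e-3)

  # errors: no admissible pair; non-positive transit time
  expect_error(pwv_foot_to_foot(probes, dx = 0.5), "no probe pair")
  rev <- list(list(position = 0.02, waveform = mk(0.02)),
              list(position = 0.12, waveform = mk(0)))
  expect_error(pwv_foot_to_foot(rev, dx = 0.10), "transit")
})

test_that("amplitude spectrum: single-tone identity, Parseval, DC rejection", {
  rate <- 100
  tt <- seq(0, 10 - 1 / rate, by = 1 / rate)
  w <- pressure_waveform(10 * sin(2 * pi * 1 * tt) + 50, rate = rate)
  s <- amplitude_spectrum(w, pad_factor = 8)
  ipk <- which.max(s$amps)
  expect_equal(s$freqs[ipk], 1, tolerance = 1e-9)
  expect_lt(abs(s$amps[ipk] - 10) / 10, 0.02)
  expect_equal(s$fundamental, 1, tolerance = 1e-9)

  # peak-frequency recovery for an off-bin tone, within one padded bin
  w2 <- pressure_waveform(5 * sin(2 * pi * 3.3 * tt), rate = rate)
  s2 <- amplitude_spectrum(w2, pad_factor = 8)
  expect_lt(abs(s2$freqs[which.max(s2$amps)] - 3.3), rate / (8 * length(tt)) + 1e-9)

  # Parseval consistency on the unpadded transform
  w3 <- generate_pressure_waveform(waveform_params())
  s3 <- amplitude_spectrum(w3, pad_factor = 1)
  x <- w3$samples - mean(w3$samples)
  msq <- mean(x^2)
  n <- length(x)
  two_sided_sq <- s3$amps^2 / 4
  two_sided_sq[1] <- s3$amps[1]^2
  if (n %% 2 == 0) two_sided_sq[length(two_sided_sq)] <- s3$amps[length(s3$amps)]^2
  # positive and negative frequency halves contribute equally
  total <- 2 * sum(two_sided_sq) - two_sided_sq[1] -
    if (n %% 2 == 0) two_sided_sq[length(two_sided_sq)] else 0
  expect_lt(abs(total - msq) / msq, 0.01)

  # constant signal: nothing survives detrending
  dc <- pressure_waveform(rep(25, 400), rate = rate)
  expect_true(all(amplitude_spectrum(dc, 8)$amps < 1e-9))
  expect_error(amplitude_spectrum(w, pad_factor = 0), "pad_factor")
})

test_that("secondary peak: dicrotic line, ring ablation, damping suppression", {
  w <- generate_pressure_waveform(waveform_params())
  s <- amplitude_spectrum(w, pad_factor = 8)
  sec <- secondary_peak(s)
  expect_lt(abs(sec - 5.4), 0.2)
  amp_at <- function(s, f0) s$amps[which.min(abs(s$freqs - f0))]

  # without the ring, the 5.4 Hz neighbourhood loses its amplitude
  w0 <- generate_pressure_waveform(waveform_params(ring_amp = 0))
  s0 <- amplitude_spectrum(w0, pad_factor = 8)
  expect_lt(amp_at(s0, 5.4), amp_at(s, 5.4))

  # a heavily damped measurement suppresses the secondary peak
  deg <- measure_periodic(w, f_n = 4, zeta = 0.8, period = 1)
  tiled <- pressure_waveform(rep(deg$samples, 10), rate = deg$rate)
  sdeg <- amplitude_spectrum(tiled, pad_factor = 8)
  expect_lt(amp_at(sdeg, 5.4), amp_at(s, 5.4))
})

test_that("curvature sum: line zero, affine invariance, threshold behaviour", {
  line <- pressure_waveform(seq(0, 1, length.out = 100), rate = 100)
  expect_equal(curvature_sum(line)$curvature_sum, 0, tolerance = 1e-9)

  w <- generate_pressure_waveform(waveform_params())
  q <- curvature_sum(w, cycle_period = 1)
  expect_gt(q$curvature_sum, 3.85)   # clean trace classified as control
  expect_false(q$distorted)

  # affine amplitude rescaling leaves the statistic unchanged
  w2 <- pressure_waveform(3 * w$samples + 50, rate = w$rate)
  expect_equal(curvature_sum(w2, cycle_period = 1)$curvature_sum,
               q$curvature_sum, tolerance = 1e-12)

  # severe low-pass distortion strips curvature
  lp <- measure_periodic(w, f_n = 2, zeta = 2, period = 1)
  qlp <- curvature_sum(lp, cycle_period = 1)
  expect_lt(qlp$curvature_sum, q$curvature_sum)

  const <- pressure_waveform(rep(80, 100), rate = 100)
  expect_error(curvature_sum(const), "degenerate")
})

test_that("curvature sum agrees with an independent spline-based computation", {
  w <- generate_pressure_waveform(waveform_params(n_cycles = 1, rate = 500))
  x <- w$samples
  y <- (x - min(x)) / (max(x) - min(x))
  tt <- seq(0, 1, length.out = length(y))
  sf <- stats::splinefun(tt, y, method = "natural")
  grid <- seq(tt[2], tt[length(tt) - 1], length.out = 4001)
  kappa <- abs(sf(grid, deriv = 2)) / (1 + sf(grid, deriv = 1)^2)^1.5
  oracle <- mean(kappa) * (max(grid) - min(grid))
  cs <- curvature_sum(w)$curvature_sum
  expect_lt(abs(cs - oracle) / oracle, 0.10)
})
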