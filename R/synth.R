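#' Parameters of the synthetic arterial pressure waveform
#'
#' Defaults mirror the operating point of the pulsatile flow phantom the
#' package models: 60 beats per minute, a 106.4 mmHg systolic peak over a
#' deliberately low 5.54 mmHg end-diastolic pressure (pulse pressure
#' 100.86 mmHg), a damped dicrotic oscillation at 5.4 Hz, and 100 Hz
#' sampling.
#'
#' @param heart_rate beats per minute.
#' @param p_sys target peak systolic pressure (mmHg).
#' @param p_dia end-diastolic pressure (mmHg); must not exceed `p_sys`.
#' @param ring_freq frequency of the damped dicrotic oscillation (Hz); must
#'   exceed the cycle frequency `heart_rate / 60` when `ring_amp > 0`.
#' @param ring_decay exponential decay rate of the oscillation (1/s).
#' @param ring_amp oscillation amplitude (mmHg); 0 removes the dicrotic
#'   notch entirely.
#' @param n_cycles number of cardiac cycles to generate (integer >= 1).
#' @param rate sampling frequency (Hz).
#' @param seed integer seed used by stochastic additions such as
#'   [add_noise()]; the generator itself is deterministic.
#' @return A validated list of class `waveform_params`.
#' @export
waveform_params <- function(heart_rate = 60, p_sys = 106.4, p_dia = 5.54,
                            ring_freq = 5.4, ring_decay = 6, ring_amp = 20,
                            n_cycles = 10, rate = 100, seed = 1L) {
  check_positive(heart_rate = heart_rate, rate = rate)
  for (f in c("p_sys", "p_dia", "ring_freq", "ring_decay", "ring_amp")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_param(f, "must be a finite number")
  }
  if (p_sys < p_dia) stop_param("p_sys", "must be >= p_dia")
  if (ring_amp < 0) stop_param("ring_amp", "must be non-negative")
  if (ring_amp > 0 && ring_freq <= heart_rate / 60)
    stop_param("ring_freq", "must exceed the cycle frequency heart_rate/60")
  if (!is.numeric(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles))
    stop_param("n_cycles", "must be an integer >= 1")
  structure(list(heart_rate = heart_rate, p_sys = p_sys, p_dia = p_dia,
                 ring_freq = ring_freq, ring_decay = ring_decay,
                 ring_amp = ring_amp, n_cycles = as.integer(n_cycles),
                 rate = rate, seed = as.integer(seed)),
            class = "waveform_params")
}

# Fixed shape fractions of the cycle (documented in the methods vignette):
# systolic upstroke 25% of the period, diastolic decay time constant 20%,
# dicrotic ring onset 10% after the peak with a 5% smooth onset ramp.
SYS_FRAC <- 0.25
DIA_TAU_FRAC <- 0.20
RING_ONSET_FRAC <- 0.10
RING_RAMP_FRAC <- 0.05

#' Generate a synthetic arterial-like pressure waveform
#'
#' Piecewise-analytic pulse: a raised-cosine systolic upstroke from `p_dia`
#' to `p_sys`, a smooth (C1-continuous) diastolic run-off of the form
#' `(1 + t/tau) exp(-t/tau)` pinned to end exactly at `p_dia`, and an
#' exponentially damped dicrotic oscillation starting shortly after
#' end-systole that produces the dicrotic notch. Each feature maps
#' one-to-one onto an observable: peak, pulse pressure, notch, and the
#' secondary spectral peak at `ring_freq`.
#'
#' The dicrotic oscillator is phase-coherent in global time (a fixed
#' `ring_freq` carrier re-excited every cycle), the physical picture of a
#' fixed resonant mode of the system. Consequently the waveform's amplitude
#' spectrum contains a genuine line at `ring_freq`, and the waveform is
#' exactly cycle-periodic whenever `ring_freq` is an integer multiple of the
#' cycle frequency (see the methods vignette).
#'
#' @param params a [waveform_params()] object.
#' @return A [pressure_waveform()] whose maximum equals `p_sys` and whose
#'   minimum equals `p_dia` to within 0.5 mmHg (for `ring_amp` small
#'   relative to the pulse pressure).
#' @examples
#' w <- generate_pressure_waveform(waveform_params())
#' max(w$samples)  # 106.4
#' @export
generate_pressure_waveform <- function(params = waveform_params()) {
  if (!inherits(params, "waveform_params"))
    params <- do.call(waveform_params, as.list(params))
  p <- params
  T_cyc <- 60 / p$heart_rate
  n <- round(p$n_cycles * T_cyc * p$rate)
  t <- (seq_len(n) - 1) / p$rate
  u <- t %% T_cyc

  amp <- p$p_sys - p$p_dia
  t_up <- SYS_FRAC * T_cyc
  tau <- DIA_TAU_FRAC * T_cyc
  D <- T_cyc - t_up
  dfun <- function(x) (1 + x / tau) * exp(-x / tau)

  base <- ifelse(u <= t_up,
                 p$p_dia + amp * 0.5 * (1 - cos(pi * u / t_up)),
                 p$p_dia + amp * (dfun(u - t_up) - dfun(D)) / (1 - dfun(D)))
  if (amp == 0) base <- rep(p$p_dia, n)

  if (p$ring_amp > 0) {
    s0 <- t_up + RING_ONSET_FRAC * T_cyc
    ramp_len <- RING_RAMP_FRAC * T_cyc
    dr <- u - s0
    ramp <- ifelse(dr <= 0, 0,
                   ifelse(dr >= ramp_len, 1, sin(pi * dr / (2 * ramp_len))^2))
    env <- ramp * exp(-p$ring_decay * pmax(dr, 0))
    base <- base + p$ring_amp * env * sin(2 * pi * p$ring_freq * t)
  }
  pressure_waveform(base, rate = p$rate, t0 = 0)
}

#' Generate a synthetic pulsatile inlet flow waveform
#'
#' Stand-in for a measured inflow profile: a systolic ejection pulse (sine
#' squared, with a configurable fast rise and slower fall) followed by
#' near-zero diastolic flow. The cycle-mean flow equals
#' `mean_velocity * pi * lumen_radius^2` by construction, so the mean flow
#' velocity - and hence the Reynolds number - is set directly.
#'
#' @param heart_rate beats per minute.
#' @param mean_velocity cycle-mean flow velocity (m/s).
#' @param lumen_radius vessel inner radius (m).
#' @param n_cycles number of cycles (integer >= 1).
#' @param rate sampling frequency (Hz).
#' @param ejection_frac fraction of the cycle occupied by ejection.
#' @param rise_frac fraction of the ejection occupied by the rise; smaller
#'   values give a sharper wavefront.
#' @return A [flow_waveform()] with attribute `period` (s).
#' @examples
#' q <- generate_inlet_flow(60, 0.0821, 8e-3)
#' mean(q$samples) * 1e6  # cycle-mean flow, cm^3/s scale
#' @export
generate_inlet_flow <- function(heart_rate, mean_velocity, lumen_radius,
                                n_cycles = 1, rate = 1000,
                                ejection_frac = 0.35, rise_frac = 0.25) {
  check_positive(heart_rate = heart_rate, lumen_radius = lumen_radius,
                 rate = rate, ejection_frac = ejection_frac,
                 rise_frac = rise_frac)
  if (!is.numeric(mean_velocity) || length(mean_velocity) != 1L ||
      !is.finite(mean_velocity) || mean_velocity < 0)
    stop_param("mean_velocity", "must be a non-negative finite number")
  if (!is.numeric(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles))
    stop_param("n_cycles", "must be an integer >= 1")
  T_cyc <- 60 / heart_rate
  t_ej <- ejection_frac * T_cyc
  t_r <- rise_frac * t_ej
  t_f <- t_ej - t_r
  q_mean <- mean_velocity * pi * lumen_radius^2
  q_peak <- q_mean * T_cyc / (0.5 * t_ej)   # sin^2 halves average to 1/2
  n <- round(n_cycles * T_cyc * rate)
  tc <- ((seq_len(n) - 1) / rate) %% T_cyc
  q <- ifelse(tc < t_r, q_peak * sin(0.5 * pi * tc / t_r)^2,
              ifelse(tc < t_ej, q_peak * cos(0.5 * pi * (tc - t_r) / t_f)^2, 0))
  out <- flow_waveform(q, rate = rate, t0 = 0)
  attr(out, "period") <- T_cyc
  out
}

#' Distort a waveform through a degraded (bubble-like) transducer
#'
#' Air bubbles in the catheter lumen lower the natural frequency and raise
#' the damping of the catheter-manometer system. This helper passes a
#' waveform through the second-order transducer model with such degraded
#' parameters; the result is an over-smoothed trace that the curvature-sum
#' quality check ([curvature_sum()]) classifies as distorted.
#'
#' @param w a [pressure_waveform()].
#' @param degraded_fn degraded natural frequency (Hz).
#' @param degraded_zeta degraded damping coefficient.
#' @return A [pressure_waveform()] of the same length and rate.
#' @seealso [measure_with_catheter()]
#' @export
add_bubble_distortion <- function(w, degraded_fn = 3, degraded_zeta = 1.5) {
  measure_with_catheter(w, f_n = degraded_fn, zeta = degraded_zeta)
}
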