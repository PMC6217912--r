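---
title: "Models and methods behind cathwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cathwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathwave)
```

# The problem

Invasive blood-pressure measurement through a fluid-filled catheter is
biased in two distinct ways. First, the catheter body partially obstructs
the vessel: the flow must squeeze through the annular gap between catheter
and wall, which multiplies the local hydraulic resistance and raises the
pressure upstream of and at the tip. Second, the fluid column that couples
the vessel to the external transducer behaves as an underdamped or
overdamped second-order system, so the recorded waveform is a filtered
version of the true one - resonance near the natural frequency, attenuation
above it. Both effects corrupt clinically used quantities: peak systolic
pressure, pulse pressure, the dicrotic notch, and the foot-to-foot pulse
wave velocity (PWV).

`cathwave` provides a desk-scale model chain for studying these biases
against an ideal, wire-like measurement (a transducer sitting exactly at
the measurement site with no dynamics): a synthetic waveform generator, a
reduced-order 1-D pulse-wave model of a compliant tube with an insertable
coaxial catheter, the second-order catheter-manometer model, and the
analysis stack (features, PWV, spectra, curvature-based quality control).

The default parameter set describes a pulsatile flow phantom: a silicone
tube of inner radius 8 mm, outer radius 9.5 mm and wall modulus 384 kPa,
perfused with room-temperature water (viscosity 1.002e-3 Pa s, density
998 kg/m^3) at 60 bpm, with mean-flow Reynolds number ~1308 and Womersley
number ~20; the inserted catheter is a 6F device (external radius 1 mm,
radius ratio 0.125, tip at z = 140 mm) whose fluid-filled lumen has a
natural frequency of 40 Hz and damping coefficient ~0.156.

# The synthetic waveform generator

`generate_pressure_waveform()` builds each cycle from three analytic
pieces, chosen so that every feature the analysis stack extracts is
controlled by exactly one parameter:

* a raised-cosine systolic upstroke from `p_dia` to `p_sys` over the first
  25% of the period;
* a diastolic run-off of the form `(1 + t/tau) exp(-t/tau)` with
  `tau = 0.2 T`, rescaled ("pinned") to end exactly at `p_dia`. This shape
  starts with zero slope, so the junction at the systolic peak is
  C1-continuous and the pulse's spectral envelope falls off quickly - which
  keeps the pulse harmonics from masking the dicrotic line (below);
* an exponentially damped dicrotic oscillation at `ring_freq` (default
  5.4 Hz, amplitude 20 mmHg, decay 6 1/s) starting 10% of a period after
  the peak with a 5%-of-period smooth onset ramp. Its first downward swing
  followed by the rebound is the dicrotic notch.

Defaults (`waveform_params()`): 60 bpm, `p_sys = 106.4` mmHg, `p_dia =
5.54` mmHg (pulse pressure 100.86 mmHg - the phantom runs a deliberately
low diastole), 10 cycles at 100 Hz. Gaussian noise is available through
`add_noise()` but off by default: measured signals are treated as clean
once they pass the curvature-sum bubble check.

**Phase coherence of the dicrotic ring.** The oscillator is a fixed
5.4 Hz carrier re-excited every cycle, i.e. phase-coherent in global time,
which is the physical picture of a resonant mode of the hydraulic system.
This choice matters for spectroscopy: a signal that is *exactly* 1
s-periodic can only carry spectral lines at integer multiples of 1 Hz, so a
per-cycle phase-reset ring could never place a spectral peak at 5.4 Hz no
matter how the spectrum is interpolated. With the coherent carrier the
waveform has a genuine line at 5.4 Hz (and modulation sidebands at
5.4 +/- k Hz, all smaller). The trade-off is that exact cycle-to-cycle
periodicity holds only when `ring_freq` is an integer multiple of the cycle
frequency; the periodicity property is therefore tested at a commensurate
ring frequency, and at the default 5.4 Hz consecutive cycles differ only in
the ring's phase.

What the generator does *not* emulate: beat-to-beat variability, baseline
drift, respiratory modulation, and measurement quantisation. Tests passing
on these clean signals say nothing about robustness to those artefacts.

# The 1-D pulse-wave model

`simulate_pulse_wave()` solves the standard 1-D conservation system for
cross-sectional area `A(x, t)` and volumetric flow `Q(x, t)`,

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\big(Q^2/A_f\big) +
  \frac{A_f}{\rho_f}\,\partial_x p = -\frac{A_f}{\rho_f} R'(x)\, Q,$$

closed by a linear tube law \(p = (A - A_0)/C_A\) with
\(C_A = 2\pi R_i^3/(E_s h)\), which reproduces the Moens-Korteweg speed
\(c_0 = \sqrt{E_s h / (2 \rho_f R_i)}\) at the reference area. A linear law
suffices here because the pressure range is modest and the PWV checks use
the linearised wave speed anyway; a full nonlinear wall model would change
none of the mechanisms under study. Note one consequence worth keeping in
mind: at a working pressure of ~100 mmHg the tube is visibly distended
(`A > A_0`), and since the local wave speed is
\(\sqrt{A/(\rho_f C_A)}\), the simulated PWV sits 10-15% above the
reference-geometry Moens-Korteweg value - the same direction as the
phantom's measured speeds.

**The catheter** is a rigid coaxial rod from its tip to the outlet
(matching how such a catheter is inserted facing the flow and pulled back).
In that segment the flow area is reduced by \(\pi R_c^2\) (tapered over two
grid cells at the tip) and the Poiseuille friction coefficient
\(R' = 8\mu/(\pi R_i^4)\) is multiplied by the annular resistance ratio

$$\frac{R_{ann}}{R_{open}} = \frac{1}{1 - k^4 - (1-k^2)^2/\ln(1/k)},
  \qquad k = R_c/R_i,$$

the exact steady annular-Poiseuille result (verified in the tests against
numerical integration of the annular velocity profile). The area reduction
also changes the segment's wave speed and characteristic impedance, so the
tip is a partial reflection site - the second mechanism by which the
catheter perturbs the upstream pressure.

**Boundary conditions.** The inlet prescribes a periodic flow (the
synthetic ejection profile of `generate_inlet_flow()`: a sine-squared pulse
with a fast rise, near-zero diastolic flow, and cycle-mean
\(U \pi R_i^2\)); the missing inlet state is closed with the backward
characteristic. The outlet couples the forward characteristic to a
Windkessel. The Windkessel is implemented in RCR form: a proximal
resistance `R1`, a compliance `C` and a distal resistance `Rp`. `R1 = 0`
gives the classical 2-element configuration; the default `R1 = "match"`
sets `R1` to the tube's characteristic impedance \(Z_0 = \rho_f c_0/A_0\).
The matched default is a deliberate design choice: a 2-element Windkessel
is purely capacitive at pulse frequencies and reflects most of an incident
wave regardless of its parameter values, which turns a short
prescribed-flow tube into an organ-pipe resonator - probe waveforms are
then dominated by standing waves, foot-to-foot transit times are
unrecoverable, and the small resistive effect of the catheter drowns in
interference. The matched RCR absorbs incident waves (it is also the more
faithful lumped model of a physical compliance chamber connected through
tubing), leaving clean travelling waveforms from which both catheter
mechanisms can be read directly. Both configurations remain available, and
the PWV-bias experiment deliberately uses a partially reflective one (see
below).

The phantom's afterload values are undocumented; `Rp` is calibrated with
`tune_windkessel()` so that the uncatheterised model peaks at ~106 mmHg at
the tip probe, and the shipped defaults (`Rp = 7.106e8` Pa s/m^3,
`C = 1.3e-9` m^3/Pa) are the result of that calibration. The model cannot
simultaneously reproduce the phantom's very low diastole and 100 mmHg pulse
pressure with the printed mean flow and wall stiffness - the tube's own
distributed compliance bounds the achievable pulse pressure - so the peak,
not the pulse pressure, is the calibration target.

**Numerics.** Explicit MacCormack (two-step Lax-Wendroff class) on a
uniform grid, default `dx = 2` mm. The integrator sub-steps internally at
the CFL limit `dt_int <= 0.8 dx / (c_max + u_max)` (about 0.25 ms for the
default tube - the CFL condition is checked at initialisation and a forced
larger step is rejected with a diagnostic); `dt` is only the storage
interval of the returned fields, default 1 ms so that foot timing can be
resolved. The tube and Windkessel start at the mean working pressure
(`(Rp + R1) x mean flow`), so the periodic state is reached within the
default 5 cycles and the last cycle is reported. Mass conservation over the
reported cycle (inflow minus outflow minus storage change) is returned with
every result and asserted below 1% of stroke volume in the tests; typical
values are a few 1e-4. Halving `dx` (the internal step follows via CFL)
moves the peak probe pressure by well under 0.1%. The test suite runs the
model at `dx = 4` mm with 4 cycles where only directions matter, and at the
production `dx = 2` mm with 5-6 cycles for the quantitative checks; those
sizes keep a full suite run under a minute on one core.

# The catheter-manometer model

The transducer is the classical mass-spring-damper:
\(\ddot y + 2\zeta\omega_n \dot y + \omega_n^2 y = \omega_n^2 p(t)\). Its
parameters derive from the catheter geometry and lumen fluid:

$$f_n = \frac{1}{2\pi}\sqrt{\frac{\pi R^2}{\rho l}\frac{dP}{dV}}, \qquad
  \zeta = \frac{4\mu l}{R^3}\,\big(\rho l \pi\, dP/dV\big)^{-1/2}.$$

The inverse compliance `dP/dV` can in principle be obtained from the
catheter's Young's modulus. The published form of that relation is
dimensionally ambiguous, and the definition of the annulus thickness it
uses is unstated; `compliance_from_modulus()` implements the one algebraic
grouping of the quoted factors that has the dimension of a pressure
(`E = dPdV * 2 t V / (3 pi l)`, checked by an internal unit audit, with
`modulus_from_compliance()` as its exact inverse) - but for the default 6F
catheter this grouping does not reproduce the stated 40 Hz natural
frequency. The package therefore anchors transducer dynamics through the
natural frequency whenever one is known
(`compliance_from_natural_frequency()`, which is unambiguous); the
modulus route is retained, flagged, for catheters specified only by
material. For the default catheter: `dP/dV = 1.568e14` Pa/m^3 and
`zeta = 0.156`, consistent with the quoted 0.15 within 5%.

`measure_with_catheter()` integrates the ODE with fixed-step RK4 at the
waveform rate, sub-stepping so that `f_n * dt_sub <= 0.05`, with the input
interpolated linearly between samples. Time-domain integration (rather
than FFT-domain multiplication) handles transients and non-periodic
records and matches the physical series system. Integration starts from
rest at the first input sample - a constant record passes through exactly
(unit DC gain) - and the first `2/(zeta omega_n)` seconds are flagged as
transient in an attribute that `extract_features()` honours. For periodic
records, `measure_periodic()` tiles the steady cycle, filters, and keeps
the final copy, so the start-up transient never contaminates analysis. The
steady-state sinusoidal gain of the integrator matches the analytic
response \(|H(f)| = 1/\sqrt{(1-r^2)^2 + (2\zeta r)^2}\) within 2% over two
decades of frequency (tested).

**Nominal versus degraded dynamics.** With the nominal parameters
(f_n = 40 Hz, zeta = 0.156) the model is nearly transparent at 5.4 Hz
(gain ~1.02): a second-order system with those constants *cannot* suppress
the dicrotic component, even though real fluid-filled catheter traces lose
it. The damping observed in practice comes from the fluid column itself,
whose effective in-situ parameters are unknown and certainly far from the
bench values. The comparison pipeline therefore always carries a second,
"degraded" configuration (default f_n = 4 Hz, zeta = 0.8, bubble-like in
character; `add_bubble_distortion()` exposes the same mechanism) that
exhibits the notch suppression, spectral damping and PWV inflation of real
traces, while the nominal column isolates the purely obstructive bias.
This split is stated in the report rather than hidden in a single tuned
number.

# Waveform analysis

**Foot detection** (`detect_foot()`) uses the intersecting-tangents
variant of the foot-to-foot family: the foot is where the tangent at the
steepest point of the upstroke crosses the horizontal line through the
pre-upstroke minimum. Among several published variants this one is robust
to the dicrotic notch and standard in the PWV literature. The tangent
point is the *first* local maximum of the derivative (central differences,
quadratic sub-sample refinement) after the pre-upstroke minimum that
reaches 60% of the window's maximum slope - taking the first qualifying
maximum keys the estimate to the incident wavefront rather than to later,
reflection-boosted slopes. Translation equivariance is exact for
whole-sample shifts and tested to 0.1 ms.

**PWV** (`pwv_foot_to_foot()`) forms every probe pair at the requested
separation (the 10-probe, 20 mm-spaced layout yields several pairs for
each of 80/100/120 mm), requires strictly positive transit times (a
non-positive one signals reflection-contaminated feet and is an error, not
a number), and averages `dx/dt` over pairs - the mean-of-ratios convention;
whether the original protocol averaged ratios or inverted a mean transit
is not stated, and at these transit-time spreads the difference is far
below the acceptance tolerances.

**Spectra** (`amplitude_spectrum()`): mean removal, zero padding by a
configurable factor (default 8), single-sided amplitudes `2|X|/n` so a
pure tone of amplitude `a` reads `a`. Zero padding interpolates the
spectrum; it does not add resolution, which remains `rate/n`. Parseval
consistency of the unpadded transform is asserted in the tests within 1%.
`secondary_peak()` returns the largest local maximum above an exclusion
band (default f > 3 Hz, keeping the fundamental and its first harmonics
out) subject to an amplitude floor (default 1% of the fundamental peak);
candidates within one *natural* resolution bin of the band edge are
rejected, because a local maximum there is the Dirichlet-kernel tail of an
excluded harmonic, not a separate peak. Absence is a valid result
(`NA`).

**Curvature QC** (`curvature_sum()`): one cycle is normalised to the unit
square, the curvature \(\kappa = |y''|/(1+y'^2)^{3/2}\) is accumulated by
central differences, and the integral (sum x step) is compared with the
published threshold 3.85. The exact normalisation used when that threshold
was derived is not restated in the source describing the phantom
experiment, so the unit-square procedure here is a reconstruction of the
method's intent, kept with the published constant; it reproduces the
reported behaviour (clean traces score well above the threshold - the
default synthetic waveform scores ~9.6, within shouting distance of the
6-8.7 reported for clean signals; heavily smoothed traces drop far below).
The direction of the test - *below* threshold means distorted - is likewise
inferred from the fact that clean signals score above it, and is stated
explicitly in the object. Degenerate (constant) cycles are an error, not a
classification.

# The comparison experiment and what the properties mean

`run_comparison()` executes the full chain: solve the model with and
without the catheter, extract probe pressures, treat the uncatheterised
trace as the wire measurement, pass the catheterised tip trace through the
nominal and degraded transducer models, and compute features, pulse
pressures, PWV per separation, spectral summaries, curvature QC and the
headline percentages. Reports are deterministic for a fixed configuration
(byte-identical JSON), carry a provenance block (config hash, package
version, seed), and round-trip through `write_report()`/`read_report()`.

Three experiment-level properties deserve comment:

* **Obstructive peak bias.** The catheterised run's tip peak exceeds the
  open run's, the excess grows with catheter radius over the clinically
  relevant range (radius ratios up to 0.25 are tested), and it vanishes as
  `R_c -> 0`. At the phantom's k = 0.125 the laminar annular mechanism
  yields a small but strictly positive bias - the *direction* of the
  experimentally observed overestimation, not its magnitude: the published
  24% arose in a system whose outlet boundary itself carried the
  catheter-elevated pressure, and entrance/unsteady effects at Re ~1300
  exceed the laminar floor modelled here. At radius ratios well above the
  tested range a competing effect appears in this model: the annular
  segment's raised friction damps the tube's residual resonance, and peak
  monotonicity is no longer guaranteed.
* **PWV accuracy.** Foot-to-foot PWV from the uncatheterised model at
  120 mm separation lands within 20% of the reference Moens-Korteweg
  speed; the excess over the closed form is the pressure-distension effect
  noted above.
* **PWV inflation by damping.** Heavy low-pass distortion inflates
  foot-to-foot PWV *only in the presence of reflected or common-mode
  pressure*: in a perfectly matched line every frequency component
  translates at the same speed, so filtering shifts all feet equally and
  the transit time is invariant (in practice, weak dispersion even biases
  it slightly the other way). The directionality experiment therefore runs
  under a partially reflective afterload (`R1 = Z0/4`): there, the smoothed
  upstroke blends with reflections whose lag shrinks towards the outlet,
  feet compress toward simultaneity, and the degraded-signal PWV exceeds
  the undistorted one. Under the fully reflective 2-element outlet the
  effect is much larger still, but the *undistorted* feet then fail with
  the non-positive-transit-time error by design.

# Known limitations

* One-dimensional physics: no tip vortices, no radial gradients, no
  eccentric or moving catheter, Newtonian fluid, laminar friction. The
  published cross-sectional pressure variation around the tip (~1 mmHg)
  suggests the radial part is minor, but the laminar friction floor
  understates the obstructive bias at physiological Reynolds numbers.
* Linear tube law: correct wave speeds near the working point, but the
  distension bias against the reference Moens-Korteweg speed is inherent.
* The transducer model is a single lumped second-order stage; distributed
  (transmission-line) lumen dynamics and frequency-dependent lumen friction
  are out of scope, which is precisely why the degraded column is a
  configuration, not a derivation.
* The curvature threshold 3.85 is adopted as a published constant; its
  normalisation here is a reconstruction.
* Windkessel values are calibrated, not measured; magnitudes that depend
  on the real afterload (absolute overestimation percentages, absolute
  PWV of degraded traces) are reproduced in direction and mechanism only.
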