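# Shared fixtures: simulations are expensive, so runs used by several tests
# are computed once per session and cached here.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

default_vessel <- function() vessel_spec()

default_inflow <- function(rate = 1000) {
  generate_inlet_flow(60, 0.0821, vessel_spec()$R_i, rate = rate)
}

# open-tube and catheterised runs on the coarse test grid
sim_open_coarse <- function() cached("open4", simulate_pulse_wave(
  default_vessel(), windkessel_spec(), default_inflow(),
  n_cycles = 4, dx = 4e-3))

sim_cath_coarse <- function() cached("cath4", simulate_pulse_wave(
  default_vessel(), windkessel_spec(), default_inflow(),
  catheter = catheter_insertion(), n_cycles = 4, dx = 4e-3))

# runs on the production grid, used by the acceptance criteria
sim_open_fine <- function() cached("open2", simulate_pulse_wave(
  default_vessel(), windkessel_spec(), default_inflow(),
  n_cycles = 5, dx = 2e-3))

sim_cath_fine <- function(R_c) cached(sprintf("cath2_%g", R_c),
  simulate_pulse_wave(
    default_vessel(), windkessel_spec(), default_inflow(),
    catheter = catheter_insertion(R_c = R_c), n_cycles = 5, dx = 2e-3))

# steady-state amplitude of the tail of a sinusoidal response
tail_amplitude <- function(w, keep_s) {
  n <- length(w$samples)
  k <- min(n, round(keep_s * w$rate))
  seg <- w$samples[(n - k + 1):n]
  (max(seg) - min(seg)) / 2
}

# independent oracle: hydraulic resistance ratio of annular vs open Poiseuille
# flow from numerical integration of the velocity profile
annular_ratio_oracle <- function(k) {
  u <- function(r) 1 - r^2 + (1 - k^2) * log(r) / log(1 / k)
  q_ann <- stats::integrate(function(r) 2 * pi * r * u(r), k, 1,
                            rel.tol = 1e-12)$value
  q_open <- pi / 2   # integral of 2 pi r (1 - r^2) from 0 to 1
  q_open / q_ann
}

# shallow field replacement on a spec list, bypassing revalidation
within_spec <- function(cs, ...) {
  repl <- list(...)
  for (nm in names(repl)) cs[[nm]] <- repl[[nm]]
  cs
}
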