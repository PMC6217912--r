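#' Compliant-vessel specification
#'
#' Geometry, wall material and working fluid of the compliant tube. Defaults
#' are the silicone "aorta" of the flow phantom: inner radius 8 mm, outer
#' radius 9.5 mm, wall Young's modulus 384 kPa, wall density 1250 kg/m^3,
#' and water at room temperature as the working fluid. The tube length is
#' a free choice of the rig; 0.4 m accommodates the 20-200 mm probe range
#' with margin to the outlet.
#'
#' @param length tube length (m).
#' @param R_i inner radius (m).
#' @param R_o outer radius (m); wall thickness is `R_o - R_i`.
#' @param E_s wall Young's modulus (Pa).
#' @param rho_s wall density (kg/m^3).
#' @param mu working-fluid dynamic viscosity (Pa s).
#' @param rho_f working-fluid density (kg/m^3).
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(length = 0.4, R_i = 8e-3, R_o = 9.5e-3,
                        E_s = 384e3, rho_s = 1250,
                        mu = 1.002e-3, rho_f = 998) {
  check_positive(length = length, R_i = R_i, R_o = R_o, E_s = E_s,
                 rho_s = rho_s, mu = mu, rho_f = rho_f)
  if (R_o <= R_i) stop_param("R_o", "must exceed R_i (wall thickness > 0)")
  structure(list(length = length, R_i = R_i, R_o = R_o, E_s = E_s,
                 rho_s = rho_s, mu = mu, rho_f = rho_f),
            class = "vessel_spec")
}

#' Windkessel afterload specification
#'
#' Lumped model of the downstream circulation terminating the tube: a
#' peripheral resistance `Rp` discharging a compliance `C` towards the
#' venous pressure, optionally behind a proximal resistance `R1`. With
#' `R1 = 0` this is the classical 2-element Windkessel; the default
#' `R1 = "match"` sets the proximal resistance equal to the tube's
#' characteristic impedance, which absorbs incident waves at the outlet
#' (the standard RCR configuration of 1-D haemodynamics) and is also the
#' more faithful lumped model of a compliance chamber connected through
#' tubing. The phantom's afterload values are not documented, so `Rp` is
#' calibrated to a target peak systolic pressure (see [tune_windkessel()]);
#' the shipped default reproduces a 106.4 mmHg peak at the 140 mm probe
#' under the default inflow.
#'
#' @param Rp peripheral resistance (Pa s/m^3).
#' @param C compliance (m^3/Pa).
#' @param P_venous reference outflow pressure (mmHg).
#' @param R1 proximal resistance (Pa s/m^3), `0`, or `"match"` to use the
#'   tube's characteristic impedance.
#' @return An object of class `windkessel_spec`.
#' @export
windkessel_spec <- function(Rp = 7.106e8, C = 1.3e-9, P_venous = 0,
                            R1 = "match") {
  check_positive(Rp = Rp, C = C)
  if (!is.numeric(P_venous) || !is.finite(P_venous))
    stop_param("P_venous", "must be a finite number (mmHg)")
  if (!(identical(R1, "match") ||
        (is.numeric(R1) && length(R1) == 1L && is.finite(R1) && R1 >= 0)))
    stop_param("R1", "must be \"match\" or a non-negative number")
  structure(list(Rp = Rp, C = C, P_venous = P_venous, R1 = R1),
            class = "windkessel_spec")
}

#' Coaxial catheter insertion
#'
#' Placement of a rigid coaxial catheter inside the vessel. The catheter is
#' inserted facing the flow, so the annular segment extends from the tip to
#' the outlet. Defaults match the phantom experiment: a 1 mm external radius
#' (radius ratio 0.125 against the 8 mm lumen) with the tip at z = 140 mm.
#'
#' @param R_c catheter external radius (m); must be smaller than the vessel
#'   inner radius.
#' @param tip_position axial coordinate of the tip (m, from the inlet).
#' @return An object of class `catheter_insertion`.
#' @export
catheter_insertion <- function(R_c = 1e-3, tip_position = 0.14) {
  check_positive(R_c = R_c)
  if (!is.numeric(tip_position) || !is.finite(tip_position) || tip_position < 0)
    stop_param("tip_position", "must be a non-negative finite number")
  structure(list(R_c = R_c, tip_position = tip_position),
            class = "catheter_insertion")
}

#' Reynolds number of the mean flow
#'
#' `Re = 2 R_i U rho_f / mu`, based on the lumen diameter and the mean flow
#' velocity.
#'
#' @param R_i vessel inner radius (m).
#' @param U mean flow velocity (m/s); may be zero.
#' @param rho_f fluid density (kg/m^3).
#' @param mu fluid dynamic viscosity (Pa s).
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(8e-3, 0.0821, 998, 1.002e-3)  # ~1308
#' @export
reynolds_number <- function(R_i, U, rho_f, mu) {
  check_positive(R_i = R_i, rho_f = rho_f, mu = mu)
  if (!is.numeric(U) || any(!is.finite(U)) || any(U < 0))
    stop_param("U", "must be non-negative and finite")
  2 * R_i * U * rho_f / mu
}

#' Womersley number
#'
#' `alpha = R_i * sqrt(2 pi f rho_f / mu)`: the ratio of pulsatile inertial
#' to viscous effects.
#'
#' @param R_i vessel inner radius (m).
#' @param f pulse frequency (Hz).
#' @param rho_f fluid density (kg/m^3).
#' @param mu fluid dynamic viscosity (Pa s).
#' @return Dimensionless Womersley number.
#' @examples
#' womersley_number(8e-3, 1, 998, 1.002e-3)  # ~20
#' @export
womersley_number <- function(R_i, f, rho_f, mu) {
  check_positive(R_i = R_i, f = f, rho_f = rho_f, mu = mu)
  R_i * sqrt(2 * pi * f * rho_f / mu)
}

#' Moens-Korteweg wave speed
#'
#' Closed-form pulse wave speed of a thin-walled elastic tube,
#' `c = sqrt(E_s h / (2 rho_f R_i))` with wall thickness `h = R_o - R_i`,
#' evaluated at the reference (unpressurised) geometry.
#'
#' @param v a [vessel_spec()].
#' @return Wave speed (m/s).
#' @examples
#' moens_korteweg_speed(vessel_spec())  # ~6.0 m/s
#' @export
moens_korteweg_speed <- function(v) {
  stopifnot(inherits(v, "vessel_spec"))
  h <- v$R_o - v$R_i
  sqrt(v$E_s * h / (2 * v$rho_f * v$R_i))
}

#' Annular-obstruction resistance ratio
#'
#' Factor by which the hydraulic resistance of steady pressure-driven flow
#' increases when a coaxial rod of radius ratio `k = R_c / R_i` is inserted
#' into a tube, from the annular Poiseuille solution:
#' `1 / (1 - k^4 - (1 - k^2)^2 / ln(1/k))`. Returns 1 at `k = 0` (no
#' catheter) and increases strictly with `k`; over the radius-ratio range
#' 0.3-0.7 the factor spans roughly 3 to 33.
#'
#' @param k radius ratio, `0 <= k < 1`. Vectorised.
#' @return Resistance ratio (>= 1).
#' @examples
#' annular_resistance_ratio(c(0, 0.125, 0.3, 0.7))
#' @export
annular_resistance_ratio <- function(k) {
  if (!is.numeric(k) || anyNA(k) || any(!is.finite(k)))
    stop_param("k", "must be finite")
  if (any(k < 0) || any(k >= 1))
    stop_param("k", "must satisfy 0 <= k < 1")
  out <- rep(1, length(k))
  pos <- k > 0
  kp <- k[pos]
  out[pos] <- 1 / (1 - kp^4 - (1 - kp^2)^2 / log(1 / kp))
  out
}

#' Catheter-to-vessel radius ratio
#'
#' @param R_c catheter external radius (m).
#' @param R_i vessel inner radius (m).
#' @return `R_c / R_i`.
#' @examples
#' radius_ratio(1e-3, 8e-3)     # 0.125, the phantom's 6F catheter
#' radius_ratio(0.18e-3, 8e-3)  # 0.0225, the pressure wire
#' @export
radius_ratio <- function(R_c, R_i) {
  check_positive(R_i = R_i)
  if (!is.numeric(R_c) || any(!is.finite(R_c)) || any(R_c < 0))
    stop_param("R_c", "must be non-negative and finite")
  R_c / R_i
}
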