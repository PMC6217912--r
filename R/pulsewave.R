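#' Simulate pulse-wave propagation in a compliant tube
#'
#' Reduced-order 1-D model of the phantom: mass and momentum conservation,
#' \deqn{\partial A/\partial t + \partial Q/\partial x = 0, \qquad
#'       \partial Q/\partial t + \partial (Q^2/A_f)/\partial x +
#'       (A_f/\rho_f)\,\partial p/\partial x = -f,}
#' closed by a linear tube law `p = (A - A0) / C_A` with cross-sectional
#' compliance `C_A = 2 pi R_i^3 / (E_s h)` (which reproduces the
#' Moens-Korteweg speed at the reference area). Friction `f` is of
#' Poiseuille form `(A_f/rho) R' Q` with `R' = 8 mu / (pi R_i^4)` in the
#' open tube; in the catheterised segment (tip to outlet) the flow area is
#' reduced by `pi R_c^2` and `R'` is multiplied by
#' [annular_resistance_ratio()] of the radius ratio. The inlet has a
#' prescribed periodic flow; the outlet is coupled to a Windkessel (see
#' [windkessel_spec()]) through the outgoing characteristic.
#'
#' Time stepping is explicit MacCormack (two-step Lax-Wendroff class) on a
#' uniform grid. The integrator sub-steps internally at the CFL limit
#' `dt_int <= cfl * dx / (c_max + u_max)`, verified at initialisation; `dt`
#' is the storage interval of the returned fields. The tube and Windkessel
#' are initialised at the mean working pressure so the periodic state is
#' reached within the default number of cycles; fields of the final cycle
#' are returned.
#'
#' @param vessel a [vessel_spec()].
#' @param windkessel a [windkessel_spec()].
#' @param inflow a [flow_waveform()] prescribing inlet flow over one period
#'   (attribute `period`, else the record span is taken as the period). The
#'   periodic extension must be continuous.
#' @param catheter a [catheter_insertion()], or `NULL` for the open tube.
#' @param n_cycles number of cycles to simulate; the last is reported.
#' @param dx grid spacing (m).
#' @param dt storage interval of the returned fields (s).
#' @param cfl Courant-number safety factor for the internal step.
#' @param dt_internal optional forced internal time step (s); an error with
#'   a CFL diagnostic is raised if it exceeds the stability limit.
#' @return An object of class `simulation_result`: list with `x_grid` (m),
#'   `t_grid` (s, relative to the start of the reported cycle), matrices
#'   `pressure` (mmHg), `flow` (m^3/s) and `area` (m^2) of dimension
#'   `length(t_grid) x length(x_grid)`, plus `conservation` (cycle volume
#'   residual as a fraction of stroke volume), `c0`, `Z0` and `meta`.
#' @examples
#' \donttest{
#' v <- vessel_spec()
#' q <- generate_inlet_flow(60, 0.0821, v$R_i)
#' res <- simulate_pulse_wave(v, windkessel_spec(), q, n_cycles = 3, dx = 4e-3)
#' res$conservation  # well below 0.01
#' }
#' @export
simulate_pulse_wave <- function(vessel, windkessel, inflow, catheter = NULL,
                                n_cycles = 5, dx = 2e-3, dt = 1e-3,
                                cfl = 0.8, dt_internal = NULL) {
  stopifnot(inherits(vessel, "vessel_spec"),
            inherits(windkessel, "windkessel_spec"),
            inherits(inflow, "flow_waveform"))
  if (!is.null(catheter) && !inherits(catheter, "catheter_insertion"))
    stop_param("catheter", "must be a catheter_insertion or NULL")
  check_positive(n_cycles = n_cycles, dx = dx, dt = dt, cfl = cfl)

  v <- vessel
  h <- v$R_o - v$R_i
  A0 <- pi * v$R_i^2
  CA <- 2 * pi * v$R_i^3 / (v$E_s * h)
  c0 <- sqrt(A0 / (v$rho_f * CA))
  Z0 <- v$rho_f * c0 / A0
  R1 <- if (identical(windkessel$R1, "match")) Z0 else windkessel$R1
  Rp <- windkessel$Rp
  Cwk <- windkessel$C
  Pven <- windkessel$P_venous * MMHG_PA

  N <- round(v$length / dx) + 1L
  x <- seq(0, v$length, length.out = N)

  # occluded area profile; the tip is tapered over ~2 cells
  Ac <- rep(0, N)
  if (!is.null(catheter)) {
    if (catheter$R_c >= v$R_i)
      stop_param("R_c", "catheter radius must be smaller than the lumen radius")
    if (catheter$tip_position > v$length)
      stop_param("tip_position", "catheter tip lies outside the tube")
    s <- pmin(pmax((x - catheter$tip_position) / (2 * dx), 0), 1)
    Ac <- pi * catheter$R_c^2 * (0.5 - 0.5 * cos(pi * s))
  }
  Rl <- 8 * v$mu / (pi * v$R_i^4)
  fr <- if (is.null(catheter)) rep(Rl, N) else {
    k <- catheter$R_c / v$R_i
    Rl * (1 + (annular_resistance_ratio(k) - 1) * Ac / (pi * catheter$R_c^2))
  }

  # periodic inlet flow
  period <- attr(inflow, "period") %||% (length(inflow$samples) / inflow$rate)
  qs <- inflow$samples
  np <- round(period * inflow$rate)
  if (np < 2L) stop_param("inflow", "inflow period shorter than 2 samples")
  qs <- qs[seq_len(min(np, length(qs)))]
  if (abs(qs[1] - qs[length(qs)]) >
      0.05 * max(abs(qs)) + 1e-12)
    stop_param("inflow", "periodic extension is discontinuous (first and last samples differ)")
  qfun <- approxfun(c((seq_along(qs) - 1) / inflow$rate, period),
                    c(qs, qs[1]))
  qin <- function(t) qfun(t %% period)

  Qm <- mean(qs)
  Qpk <- max(abs(qs))
  umax <- Qpk / (A0 - max(Ac))
  dt_lim <- cfl * dx / (c0 + umax + 1)
  dti <- dt_internal %||% dt_lim
  if (dti > dx / (c0 + umax))
    stop(sprintf(paste0("CFL violation: dt_internal = %.3g s exceeds the ",
                        "stability limit dx / (c_max + u_max) = %.3g s"),
                 dti, dx / (c0 + umax)), call. = FALSE)
  nst <- ceiling(period / dti)
  dti <- period / nst
  stor <- max(1L, round(dt / dti))

  # start at the periodic working point
  P_init <- Pven + (Rp + R1) * Qm
  A <- rep(A0 + CA * P_init, N)
  Q <- rep(Qm, N)
  Pc <- Pven + Rp * Qm

  pres <- function(A) (A - A0) / CA
  rhs <- function(A, Q, ddx) {
    Af <- A - Ac
    list(-ddx(Q),
         -(ddx(Q^2 / Af) + (Af / (v$rho_f * CA)) * ddx(A)) -
           (Af / v$rho_f) * fr * Q)
  }
  fwd <- function(z) c(diff(z), 0) / dx
  bwd <- function(z) c(0, diff(z)) / dx
  apply_bc <- function(A, Q, Pc, t, dt) {
    Q1 <- qin(t)
    p1 <- pres(A[2]) - Z0 * (Q[2] - Q1)
    W <- pres(A[N - 1]) + Z0 * Q[N - 1]
    QN <- (W - Pc) / (Z0 + R1)
    pN <- Pc + R1 * QN
    list(A1 = A0 + CA * p1, Q1 = Q1, AN = A0 + CA * pN, QN = QN,
         Pc = Pc + dt * (QN - (Pc - Pven) / Rp) / Cwk)
  }

  total <- as.integer(n_cycles) * nst
  nkeep <- length(seq.int(0L, nst - 1L, by = stor))
  P_store <- matrix(0, nkeep, N)
  Q_store <- matrix(0, nkeep, N)
  A_store <- matrix(0, nkeep, N)
  t_store <- numeric(nkeep)
  ik <- 0L
  vol_in <- 0; vol_out <- 0; A_cycle_start <- NULL
  t <- 0
  last_start <- total - nst

  for (s in seq_len(total)) {
    if (s - 1L >= last_start && (s - 1L - last_start) %% stor == 0L) {
      ik <- ik + 1L
      P_store[ik, ] <- pres(A) / MMHG_PA
      Q_store[ik, ] <- Q
      A_store[ik, ] <- A
      t_store[ik] <- (s - 1L - last_start) * dti
    }
    if (s - 1L == last_start) A_cycle_start <- A
    r1 <- rhs(A, Q, fwd)
    Ap <- A + dti * r1[[1]]
    Qp <- Q + dti * r1[[2]]
    b <- apply_bc(Ap, Qp, Pc, t + dti, dti)
    Ap[1] <- b$A1; Qp[1] <- b$Q1; Ap[N] <- b$AN; Qp[N] <- b$QN
    Pc_p <- b$Pc
    r2 <- rhs(Ap, Qp, bwd)
    An <- 0.5 * (A + Ap + dti * r2[[1]])
    Qn <- 0.5 * (Q + Qp + dti * r2[[2]])
    b2 <- apply_bc(An, Qn, Pc, t + dti, dti)
    An[1] <- b2$A1; Qn[1] <- b2$Q1; An[N] <- b2$AN; Qn[N] <- b2$QN
    Pc <- 0.5 * (Pc_p + b2$Pc)
    A <- An; Q <- Qn
    t <- t + dti
    if (s %% 200L == 0L && (any(!is.finite(A)) || any(!is.finite(Q))))
      stop(sprintf(paste0("solution diverged at t = %.4g s: non-finite field ",
                          "values (CFL/stability diagnostic: dt_int = %.3g s, ",
                          "limit = %.3g s)"), t, dti, dx / (c0 + umax)),
           call. = FALSE)
    if (s >= last_start + 1L) {
      vol_in <- vol_in + Q[1] * dti
      vol_out <- vol_out + Q[N] * dti
    }
  }
  if (any(!is.finite(A)) || any(!is.finite(Q)))
    stop("solution diverged: non-finite final fields", call. = FALSE)
  if (any(A_store - matrix(Ac, nkeep, N, byrow = TRUE) <= 0))
    stop("solution invalid: non-positive flow area", call. = FALSE)

  storage <- sum(A - A_cycle_start) * dx
  sv <- max(Qm * period, .Machine$double.eps)
  structure(list(x_grid = x, t_grid = t_store,
                 pressure = P_store, flow = Q_store, area = A_store,
                 conservation = abs(vol_in - vol_out - storage) / sv,
                 c0 = c0, Z0 = Z0,
                 meta = list(period = period, dx = dx, dt = stor * dti,
                             dt_internal = dti, n_cycles = n_cycles,
                             catheter = catheter, R1 = R1)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(paste0("<simulation_result> %d x %d (t x x) fields over one ",
                     "cycle of %g s\n  pressure range [%.2f, %.2f] mmHg; ",
                     "conservation residual %.2e of stroke volume\n"),
              nrow(x$pressure), ncol(x$pressure), x$meta$period,
              min(x$pressure), max(x$pressure), x$conservation))
  invisible(x)
}

#' Extract the pressure waveform at an axial position
#'
#' Linear interpolation in space at probe position `x`, resampled in time to
#' `rate` by linear interpolation. This is the "wire" (ideal) measurement:
#' the transducer is taken to sit exactly at the probe with no dynamics.
#'
#' @param res a [simulate_pulse_wave()] result.
#' @param x axial position (m); must lie within the grid.
#' @param rate output sampling rate (Hz); default the stored rate.
#' @return A [pressure_waveform()].
#' @export
pressure_at <- function(res, x, rate = NULL) {
  stopifnot(inherits(res, "simulation_result"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min(res$x_grid) || x > max(res$x_grid))
    stop(sprintf("probe position %.4g m is outside the tube [0, %.4g m]",
                 x, max(res$x_grid)), call. = FALSE)
  p_x <- apply(res$pressure, 1L, function(row) approx(res$x_grid, row, x)$y)
  rate_store <- 1 / res$meta$dt
  if (is.null(rate) || isTRUE(all.equal(rate, rate_store)))
    return(pressure_waveform(p_x, rate = rate_store, t0 = res$t_grid[1]))
  check_positive(rate = rate)
  tt <- seq(res$t_grid[1], res$t_grid[length(res$t_grid)], by = 1 / rate)
  pressure_waveform(approx(res$t_grid, p_x, tt)$y, rate = rate, t0 = tt[1])
}

#' Extract pressure waveforms at several probe positions
#'
#' @param res a [simulate_pulse_wave()] result.
#' @param positions axial positions (m).
#' @param rate output sampling rate (Hz); default the stored rate.
#' @return A list with one element per position, each a list with `position`
#'   and `waveform` - the layout expected by [pwv_foot_to_foot()].
#' @export
probe_pressures <- function(res, positions, rate = NULL) {
  lapply(positions, function(p)
    list(position = p, waveform = pressure_at(res, p, rate = rate)))
}

#' Calibrate the Windkessel to a target peak systolic pressure
#'
#' The phantom's afterload was adjusted to reach a physiological systolic
#' pressure, but its resistance and compliance values are not documented.
#' This helper scales the peripheral resistance by secant iteration until
#' the uncatheterised model's peak pressure at `probe_x` matches
#' `target_psys`.
#'
#' @param vessel a [vessel_spec()].
#' @param inflow a [flow_waveform()] (see [generate_inlet_flow()]).
#' @param target_psys target peak systolic pressure (mmHg).
#' @param probe_x probe position at which the peak is evaluated (m).
#' @param windkessel starting [windkessel_spec()].
#' @param iterations number of secant updates.
#' @param ... further arguments passed to [simulate_pulse_wave()].
#' @return A [windkessel_spec()] with calibrated `Rp`.
#' @export
tune_windkessel <- function(vessel, inflow, target_psys = 106.4,
                            probe_x = 0.14, windkessel = windkessel_spec(),
                            iterations = 3, ...) {
  check_positive(target_psys = target_psys, iterations = iterations)
  wk <- windkessel
  period <- attr(inflow, "period") %||% (length(inflow$samples) / inflow$rate)
  Qm <- mean(inflow$samples[seq_len(round(period * inflow$rate))])
  peak_at <- function(wk) {
    res <- simulate_pulse_wave(vessel, wk, inflow, ...)
    max(pressure_at(res, probe_x)$samples)
  }
  for (i in seq_len(iterations)) {
    pk <- peak_at(wk)
    # a unit change in Rp moves the mean (hence the peak) by ~ Qm mmHg/Pa
    wk$Rp <- wk$Rp + (target_psys - pk) * MMHG_PA / Qm
    if (wk$Rp <= 0) stop("tune_windkessel: resistance update became non-positive",
                         call. = FALSE)
  }
  wk
}
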