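#' Configuration of the wire-vs-catheter comparison experiment
#'
#' Bundles every sub-specification of the end-to-end experiment: the vessel
#' and its afterload, the catheter (placement and transducer dynamics), the
#' inlet flow, the synthetic-waveform parameters, the probe layout and the
#' analysis settings.
#'
#' The transducer distortion stage carries two settings: the nominal
#' catheter dynamics (derived from the catheter spec, e.g. f_n = 40 Hz,
#' zeta = 0.156 for the default 6F catheter) and a degraded, fluid-column /
#' bubble-like configuration (default f_n = 4 Hz, zeta = 0.8). The nominal
#' second-order model is nearly transparent below 10 Hz and cannot suppress
#' the 5.4 Hz dicrotic component; the degraded column exhibits the notch
#' suppression and PWV inflation seen in real fluid-filled catheter traces
#' (see the methods vignette).
#'
#' @param vessel a [vessel_spec()].
#' @param windkessel a [windkessel_spec()].
#' @param catheter a [catheter_insertion()].
#' @param transducer a [catheter_spec()] supplying the nominal dynamics.
#' @param waveform a [waveform_params()] (used for the heart rate and for
#'   synthetic-waveform stages).
#' @param flow list with `mean_velocity` (m/s), `ejection_frac`, `rise_frac`.
#' @param probes axial probe positions (m); all must lie inside the vessel.
#' @param analysis list with `pad_factor`, `dx` (separations, m),
#'   `exclusion_band` (Hz), `curvature_threshold`, `degraded_fn` (Hz),
#'   `degraded_zeta`.
#' @param numerics list with `n_cycles`, `dx` (m), `dt` (s).
#' @param seed integer seed funnelled to every stochastic stage.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(vessel = vessel_spec(),
                              windkessel = windkessel_spec(),
                              catheter = catheter_insertion(),
                              transducer = catheter_spec(),
                              waveform = waveform_params(),
                              flow = list(mean_velocity = 0.0821,
                                          ejection_frac = 0.35,
                                          rise_frac = 0.25),
                              probes = seq(0.02, 0.20, by = 0.02),
                              analysis = list(pad_factor = 8,
                                              dx = c(0.08, 0.10, 0.12),
                                              exclusion_band = 3,
                                              curvature_threshold = 3.85,
                                              degraded_fn = 4,
                                              degraded_zeta = 0.8),
                              numerics = list(n_cycles = 5, dx = 2e-3,
                                              dt = 1e-3),
                              seed = 1L) {
  stopifnot(inherits(vessel, "vessel_spec"),
            inherits(windkessel, "windkessel_spec"),
            inherits(catheter, "catheter_insertion"),
            inherits(transducer, "catheter_spec"),
            inherits(waveform, "waveform_params"))
  if (any(probes < 0) || any(probes > vessel$length))
    stop_param("probes", "probe positions must lie inside the vessel")
  for (dxv in analysis$dx) {
    pos <- round(probes / 1e-6)
    if (!any(outer(pos, pos, function(a, b) b - a) == round(dxv / 1e-6)))
      stop_param("analysis$dx",
                 sprintf("separation %g m is not achievable from the probe layout", dxv))
  }
  if (catheter$tip_position > vessel$length)
    stop_param("catheter", "tip position outside the vessel")
  structure(list(vessel = vessel, windkessel = windkessel,
                 catheter = catheter, transducer = transducer,
                 waveform = waveform, flow = flow, probes = probes,
                 analysis = analysis, numerics = numerics,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @noRd
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # strip classes/attributes for a stable canonical form
  canon <- rapply(unclass(cfg), function(x) x, how = "replace")
  saveRDS(canon, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the wire-vs-catheter comparison experiment
#'
#' Orchestrates the full pipeline: the 1-D model is solved twice (with and
#' without the catheter); probe pressures are extracted from each run; the
#' "wire" signal is the uncatheterised probe pressure taken as-is (identity
#' transducer at the tip), while the "catheter" signal is the catheterised
#' run's tip-probe pressure passed through the second-order transducer
#' model, with both the nominal and the degraded dynamics. All analyses
#' (features, pulse pressure, PWV per separation, spectra, curvature QC) are
#' then applied and collected into a report. Since the reported cycle is
#' periodic, the transducer stage tiles it three times and keeps the final
#' copy, so filter start-up transients do not contaminate the analysed
#' cycle. The run is deterministic for a fixed config.
#'
#' @param cfg an [experiment_config()].
#' @return A list of class `comparison_report`; see Details.
#' @details Report fields: `peak_overestimation_pct` (nominal transducer)
#'   and `peak_overestimation_degraded_pct`, both
#'   `(catheter P_s - wire P_s) / wire P_s * 100` at the tip probe;
#'   `pulse_pressure_ratio_pct = wire PP / catheter PP * 100`; `pwv_wire`
#'   and `pwv_catheter` (m/s, named by separation; the catheter column uses
#'   the degraded dynamics); `spectra` (fundamental, secondary frequency and
#'   secondary amplitude for wire and degraded-catheter tip signals); `qc`
#'   (curvature sums and flags); `features_wire`, `features_catheter`;
#'   `provenance` (config hash, package version, seed).
#' @export
run_comparison <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  v <- cfg$vessel
  period <- 60 / cfg$waveform$heart_rate
  inflow <- stage("inflow", generate_inlet_flow(
    cfg$waveform$heart_rate, cfg$flow$mean_velocity, v$R_i,
    rate = 1 / cfg$numerics$dt,
    ejection_frac = cfg$flow$ejection_frac, rise_frac = cfg$flow$rise_frac))

  sim_open <- stage("simulate_open", simulate_pulse_wave(
    v, cfg$windkessel, inflow, catheter = NULL,
    n_cycles = cfg$numerics$n_cycles, dx = cfg$numerics$dx,
    dt = cfg$numerics$dt))
  sim_cath <- stage("simulate_catheter", simulate_pulse_wave(
    v, cfg$windkessel, inflow, catheter = cfg$catheter,
    n_cycles = cfg$numerics$n_cycles, dx = cfg$numerics$dx,
    dt = cfg$numerics$dt))

  tip <- cfg$catheter$tip_position
  fn_nom <- cfg$transducer$f_n
  zeta_nom <- cfg$transducer$zeta
  fn_deg <- cfg$analysis$degraded_fn
  zeta_deg <- cfg$analysis$degraded_zeta

  wire_tip <- pressure_at(sim_open, tip)
  cath_tip_true <- pressure_at(sim_cath, tip)
  cath_tip_nom <- stage("measure",
                        measure_periodic(cath_tip_true, fn_nom, zeta_nom, period))
  cath_tip_deg <- stage("measure",
                        measure_periodic(cath_tip_true, fn_deg, zeta_deg, period))

  feat <- function(w) extract_features(w, cycle_period = period, transient = 0)
  f_wire <- stage("features", feat(wire_tip))
  f_nom <- stage("features", feat(cath_tip_nom))
  f_deg <- stage("features", feat(cath_tip_deg))

  over_pct <- function(f_cath) (f_cath$P_s - f_wire$P_s) / f_wire$P_s * 100

  pwv_for <- function(sim, fn = NULL, zeta = NULL) {
    pr <- probe_pressures(sim, cfg$probes)
    if (!is.null(fn))
      pr <- lapply(pr, function(p) {
        p$waveform <- measure_periodic(p$waveform, fn, zeta, period)
        p
      })
    sapply(cfg$analysis$dx, function(d)
      pwv_foot_to_foot(pr, d, window = period)$pwv)
  }
  pwv_wire <- stage("pwv", pwv_for(sim_open))
  pwv_cath <- stage("pwv", pwv_for(sim_cath, fn_deg, zeta_deg))
  names(pwv_wire) <- names(pwv_cath) <- sprintf("dx_%gmm", cfg$analysis$dx * 1e3)

  spec_of <- function(w) {
    s <- amplitude_spectrum(w, cfg$analysis$pad_factor)
    sec <- secondary_peak(s, exclusion_band = cfg$analysis$exclusion_band)
    sec_amp <- if (is.na(sec)) NA_real_ else s$amps[which.min(abs(s$freqs - sec))]
    list(fundamental = s$fundamental, secondary = sec, secondary_amp = sec_amp)
  }
  spectra <- stage("spectra", list(wire = spec_of(wire_tip),
                                   catheter = spec_of(cath_tip_deg)))

  qc_of <- function(w) {
    q <- curvature_sum(w, cycle_period = period,
                       threshold = cfg$analysis$curvature_threshold)
    list(curvature_sum = q$curvature_sum, distorted = q$distorted)
  }
  qc <- stage("qc", list(wire = qc_of(wire_tip), catheter = qc_of(cath_tip_deg)))

  structure(list(
    peak_overestimation_pct = over_pct(f_nom),
    peak_overestimation_degraded_pct = over_pct(f_deg),
    pulse_pressure_ratio_pct = f_wire$pulse_pressure / f_nom$pulse_pressure * 100,
    pwv_wire = pwv_wire,
    pwv_catheter = pwv_cath,
    spectra = spectra,
    qc = qc,
    features_wire = unclass(f_wire),
    features_catheter = unclass(f_nom),
    conservation = c(open = sim_open$conservation, catheter = sim_cath$conservation),
    provenance = list(config_hash = config_hash(cfg),
                      package_version = as.character(packageVersion("cathwave")),
                      seed = cfg$seed)),
    class = "comparison_report")
}

#' Apply the transducer model to a periodic record
#'
#' Tiles the last complete cycle of `w` `reps` times, passes the tiled
#' record through [measure_with_catheter()] and returns the final copy, so
#' the filter's start-up transient has died out and the result represents
#' continuous measurement of a periodic signal.
#'
#' @param w a [pressure_waveform()] containing at least one complete cycle.
#' @param f_n transducer natural frequency (Hz).
#' @param zeta damping coefficient.
#' @param period cycle period (s).
#' @param reps number of tiled copies (>= 2 recommended).
#' @return A [pressure_waveform()] spanning one cycle.
#' @export
measure_periodic <- function(w, f_n, zeta, period, reps = 3L) {
  n_per <- round(period * w$rate)
  n_cyc <- max(1L, length(w$samples) %/% n_per)
  cyc <- w$samples[(n_cyc - 1L) * n_per + seq_len(n_per)]
  tiled <- pressure_waveform(rep(cyc, reps), rate = w$rate, t0 = w$t0)
  m <- measure_with_catheter(tiled, f_n, zeta)
  out <- pressure_waveform(m$samples[(reps - 1L) * n_per + seq_len(n_per)],
                           rate = w$rate, t0 = w$t0)
  attr(out, "transient") <- 0
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  peak overestimation (nominal f_n/zeta): %+.3f %%\n",
              x$peak_overestimation_pct))
  cat(sprintf("  peak overestimation (degraded):         %+.3f %%\n",
              x$peak_overestimation_degraded_pct))
  cat(sprintf("  pulse pressure ratio wire/catheter:     %.1f %%\n",
              x$pulse_pressure_ratio_pct))
  cat("  PWV wire     [m/s]:", sprintf("%.2f", x$pwv_wire), "\n")
  cat("  PWV catheter [m/s]:", sprintf("%.2f", x$pwv_catheter), "\n")
  cat(sprintf("  wire spectrum: fundamental %.2f Hz, secondary %.2f Hz\n",
              x$spectra$wire$fundamental, x$spectra$wire$secondary))
  invisible(x)
}

#' Serialise a comparison report to JSON
#'
#' Deterministic output: two runs with an identical config produce
#' byte-identical files.
#'
#' @param report a [run_comparison()] report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a serialised comparison report
#'
#' @param path JSON file written by [write_report()].
#' @return A list of class `comparison_report`.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(rep, class = "comparison_report")
}

# ---- configuration files ----------------------------------------------------

#' Write an experiment configuration to YAML
#'
#' @param cfg an [experiment_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  lst <- rapply(unclass(cfg), unclass, how = "replace")
  # drop derivable transducer fields that the constructor recomputes
  yaml::write_yaml(lst, path, precision = 12)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' The parsed file is revalidated through the spec constructors, so
#' `read_experiment_config(write_experiment_config(cfg))` is semantically
#' identical to `cfg`.
#'
#' @param path YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- y$transducer
  # the stored dPdV is authoritative; f_n and zeta are rederived from it
  tr$f_n <- NULL
  tr$zeta <- NULL
  experiment_config(
    vessel = do.call(vessel_spec, y$vessel),
    windkessel = do.call(windkessel_spec, y$windkessel),
    catheter = do.call(catheter_insertion, y$catheter),
    transducer = do.call(catheter_spec, tr),
    waveform = do.call(waveform_params, y$waveform),
    flow = y$flow,
    probes = as.numeric(y$probes),
    analysis = y$analysis,
    numerics = y$numerics,
    seed = y$seed)
}

#' Generate the versioned fixture set used by the test suite
#'
#' Writes a small set of waveform CSVs (a clean synthetic trace, a
#' bubble-distorted copy, a noisy copy) plus a JSON manifest with MD5
#' checksums. Regeneration with the same seed is byte-identical.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed integer seed for the noisy fixture.
#' @return Named character vector of the written file paths, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create fixture directory: ", out_dir, call. = FALSE)
  params <- waveform_params(n_cycles = 3, seed = seed)
  clean <- generate_pressure_waveform(params)
  bubble <- add_bubble_distortion(clean)
  noisy <- add_noise(clean, sd = 1, seed = seed)
  paths <- c(clean = file.path(out_dir, "clean.csv"),
             bubble = file.path(out_dir, "bubble.csv"),
             noisy = file.path(out_dir, "noisy.csv"))
  write_waveform_csv(clean, paths[["clean"]])
  write_waveform_csv(bubble, paths[["bubble"]])
  write_waveform_csv(noisy, paths[["noisy"]])
  manifest <- list(version = as.character(packageVersion("cathwave")),
                   seed = as.integer(seed),
                   waveform = unclass(params),
                   files = lapply(paths, function(p)
                     list(name = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = file.path(out_dir, "manifest.json")))
}
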