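#' Write / read waveforms in the two-column CSV dialect
#'
#' Waveforms are stored as `time_ns,value` CSV with a JSON sidecar
#' (`<path>.json`) holding the metadata (units, energy, sample spacing).
#'
#' @param pulse A [current_pulse()] or [voltage_pulse()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(pulse, path) {
  t <- (seq_along(pulse$samples) - 1) * pulse$dt
  utils::write.csv(data.frame(time_ns = t, value = pulse$samples),
                   path, row.names = FALSE)
  meta <- list(class = class(pulse)[1], dt = pulse$dt,
               units = if (inherits(pulse, "current_pulse")) "uA" else "mV",
               energy = if (inherits(pulse, "current_pulse")) pulse$energy
                        else pulse$source_energy)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_waveform
#' @param path Input CSV path (with a `<path>.json` sidecar).
#' @return For `read_waveform`: the reconstructed pulse object.
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- if (nrow(d) > 1) d$time_ns[2] - d$time_ns[1] else meta$dt
  en <- if (is.null(meta$energy)) NA_real_ else as.numeric(meta$energy)
  if (identical(meta$class, "current_pulse"))
    current_pulse(d$value, dt = dt, energy = en)
  else voltage_pulse(d$value, dt = dt, source_energy = en)
}

#' Write / read threshold scans in the scan CSV dialect
#'
#' Columns: `threshold_keV`, `counts`, `n_pulses`, `beam_keV`,
#' `deadtime_ns` (the last three constant per file).
#'
#' @param scan A `threshold_scan`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_threshold_scan <- function(scan, path) {
  n <- length(scan$threshold_keV)
  utils::write.csv(data.frame(
    threshold_keV = scan$threshold_keV, counts = scan$counts,
    n_pulses = rep(attr(scan, "n_pulses"), n),
    beam_keV = rep(attr(scan, "beam_keV"), n),
    deadtime_ns = rep(attr(scan, "deadtime_ns"), n)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_scan
#' @export
read_threshold_scan <- function(path) {
  d <- utils::read.csv(path)
  structure(data.frame(threshold_keV = d$threshold_keV, counts = d$counts),
            n_pulses = d$n_pulses[1], beam_keV = d$beam_keV[1],
            deadtime_ns = d$deadtime_ns[1], clock_ns = 10,
            class = c("threshold_scan", "data.frame"))
}

# energy/deadtime campaign used for the pulse-shape threshold scans of
# each detector module (long and short shaping settings; some deadtimes
# only usable at the higher beam energies)
scan_campaign <- function(module) {
  stopifnot(module %in% 1:4)
  grid <- function(energies, deadtimes, restricted = numeric(0),
                   restricted_min_energy = 60) {
    out <- expand.grid(energy = energies, deadtime_ns = deadtimes)
    out[!(out$deadtime_ns %in% restricted &
            out$energy < restricted_min_energy), ]
  }
  switch(module,
    `1` = list(long = grid(c(40, 60, 70), c(70, 80, 90, 100), c(90, 100)),
               short = grid(c(60, 70), c(70, 80))),
    `2` = list(long = grid(c(40, 60, 80), c(70, 80, 90, 100), 100),
               short = grid(c(40, 60), c(70, 80, 90), 90)),
    `3` = list(long = grid(40, seq(40, 100, 10)),
               short = grid(40, seq(40, 70, 10))),
    `4` = list(long = grid(40, seq(40, 100, 10)),
               short = grid(40, seq(40, 70, 10))))
}

#' Generate a set of synthetic threshold-scan fixture files
#'
#' Simulates the threshold-scan campaign of one detector module (beam
#' energies and deadtime settings for both shaping settings) with the given
#' shaper parameters and writes each scan in the scan CSV dialect, named
#' `scan_module<m>_<setting>_E<energy>_td<deadtime>.csv`.
#'
#' @param dir Output directory (created if needed).
#' @param module Module profile (1-4), selecting the energy/deadtime grid.
#' @param tau0 Prototype filter time constant, ns.
#' @param B_short Short-setting scale factor.
#' @param n_pulses Pulses per scan (0 gives empty scans with valid headers).
#' @param seed RNG seed (fixed seed gives byte-identical output).
#' @param geometry A [detector_geometry()].
#' @return Character vector of file paths, invisibly.
#' @export
generate_fixture_scans <- function(dir, module = 1, tau0 = 19.6,
                                   B_short = 27.8 / 39.2, n_pulses = 2000,
                                   seed = 1, geometry = detector_geometry()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  camp <- scan_campaign(module)
  paths <- character(0)
  for (setting in names(camp)) {
    cfg <- shaper_config("prototype", tau0,
                         B = if (setting == "long") 1 else B_short)
    tab <- camp[[setting]]
    for (r in seq_len(nrow(tab))) {
      E <- tab$energy[r]; td <- tab$deadtime_ns[r]
      scan <- if (n_pulses > 0) {
        simulate_threshold_scan(E, td, cfg, n_pulses = n_pulses,
                                seed = seed + 1000 * module +
                                  100 * (setting == "short") + r,
                                geometry = geometry)[[1]]
      } else {
        structure(data.frame(threshold_keV = numeric(0), counts = numeric(0)),
                  n_pulses = 0, beam_keV = E, deadtime_ns = td, clock_ns = 10,
                  class = c("threshold_scan", "data.frame"))
      }
      p <- file.path(dir, sprintf("scan_module%d_%s_E%g_td%g.csv",
                                  module, setting, E, td))
      write_threshold_scan(scan, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Default end-to-end run configuration
#'
#' All defaults equal the printed operating point of the study: module-1
#' prototype time constants, the standard geometry and noise sources, a
#' 120-kVp beam with 20 cm soft tissue.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1,
    geometry = list(pixel_pitch_x = 0.4, pixel_pitch_y = 0.5,
                    wafer_thickness = 500, bias_voltage = 400,
                    doping = 4.6e11, temperature = 300,
                    strip_length = 30, n_segments = 9, dead_layer = 0.6),
    shaper = list(tau0 = 19.6, B_short = 27.8 / 39.2, tau_s = 14),
    noise = list(i_csa_rms = 0.45, v_filter_rms = 2.72, Gf = 5, Cdet = 5),
    counting = list(clock_ns = 10, exclude_below_keV = 15),
    beam = list(kvp = 120, tissue_cm = 20, filtration_al_mm = 8.38,
                filtration_be_mm = 0.8, anode_angle = 10.5),
    fixtures = list(module = 1, n_pulses = 2000),
    response = list(n_photons = 2e5)
  ), class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Unspecified fields fall back to [default_run_config()].
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_pcd(sprintf("config file '%s' not found", path), "configuration_error")
  user <- if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_pcd("the yaml package is required for YAML configs",
               "configuration_error")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  for (blk in names(user)) {
    if (is.list(user[[blk]])) {
      for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
    } else cfg[[blk]] <- user[[blk]]
  }
  cfg
}

#' Run the full simulate-scan-fit-report pipeline
#'
#' Generates the fixture scan campaign, extracts E1/2 from every scan,
#' recovers the shaper time constants by grid search, computes the
#' noise/gain ratios of the two shaping settings and the dose-efficiency
#' summary, and writes a JSON report plus CSV outputs (sigma versus shaping
#' time, the power-compensation curve) into `out_dir`. All seeds and the
#' noise normalization constants are recorded in the report.
#'
#' @param config A `run_config` (list) or a path to a JSON/YAML file.
#' @param out_dir Output directory.
#' @param verbose Print stage progress.
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempdir(),
                         verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop_pcd(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "pipeline_error"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- stage("geometry", do.call(detector_geometry, config$geometry))
  src <- stage("noise-sources", do.call(noise_sources, config$noise))
  seed <- config$seed

  scan_dir <- file.path(out_dir, "scans")
  paths <- stage("fixtures", generate_fixture_scans(
    scan_dir, module = config$fixtures$module, tau0 = config$shaper$tau0,
    B_short = config$shaper$B_short, n_pulses = config$fixtures$n_pulses,
    seed = seed, geometry = geom))

  meas <- stage("e-half", {
    rows <- lapply(paths, function(p) {
      s <- read_threshold_scan(p)
      setting <- if (grepl("_long_", p)) "long" else "short"
      eh <- tryCatch(extract_e_half(s, config$counting$exclude_below_keV),
                     error = function(e) NA_real_)
      data.frame(energy = attr(s, "beam_keV"),
                 deadtime_ns = attr(s, "deadtime_ns"),
                 e_half_keV = eh, setting = setting)
    })
    out <- do.call(rbind, rows)
    out[is.finite(out$e_half_keV), ]
  })

  fit <- stage("shape-fit", fit_shape_params(meas, geometry = geom))

  ratios <- stage("ratios", {
    long <- shaper_config("prototype", fit$tau0, B = 1)
    short <- shaper_config("prototype", fit$tau0, B = fit$B_short)
    gl <- channel_gain(long, geom); gs <- channel_gain(short, geom)
    sl <- sigma_total(long, src, gain = gl, geometry = geom)
    ss <- sigma_total(short, src, gain = gs, geometry = geom)
    list(gain_ratio = gl / gs,
         sigma_keV_ratio = sl[["sigma_keV"]] / ss[["sigma_keV"]],
         gain_long = gl, gain_short = gs,
         sigma_keV_long = sl[["sigma_keV"]],
         sigma_keV_short = ss[["sigma_keV"]])
  })

  dose <- stage("dose-efficiency", {
    beam <- do.call(beam_config, config$beam)
    dep <- detector_response(tube_spectrum(beam), geom,
                             n_photons = config$response$n_photons,
                             seed = seed + 7)
    list(threshold_8keV = dose_efficiency(dep, 8),
         threshold_4keV = dose_efficiency(dep, 4))
  })

  sig <- stage("sigma-vs-tau", sigma_vs_tau(c(40, 100, 200, 400), src, geom))
  utils::write.csv(sig, file.path(out_dir, "sigma_vs_tau.csv"),
                   row.names = FALSE)
  pow <- stage("power-tradeoff", power_tradeoff_curve(sources = src,
                                                      geometry = geom))
  utils::write.csv(pow, file.path(out_dir, "power_tradeoff.csv"),
                   row.names = FALSE)

  norm <- noise_normalization(src, geom)
  report <- list(
    config = unclass(config),
    shape_fit = list(tau0 = fit$tau0, B_short = fit$B_short,
                     tau_long = fit$tau_long, tau_short = fit$tau_short,
                     mse = fit$mse, n_records = fit$n_records),
    ratios = ratios,
    dose_efficiency = dose,
    noise_normalization = list(k_csa = norm$k_csa, k_filter = norm$k_filter,
                               gain_ref_mV_per_keV = norm$gain_ref,
                               sigma_ref_mV = norm$sigma_ref_mV),
    n_scans = length(paths))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
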