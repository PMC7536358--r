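#' Clocked comparator bank
#'
#' Up to eight strictly increasing thresholds, a clock period and a
#' deadtime that must be an integer multiple of the clock period. The
#' comparator outputs are sampled once per clock cycle; a sample above the
#' lowest threshold triggers a count, the pulse is classified by the
#' highest threshold exceeded among the samples inside the deadtime window,
#' and the channel is live again one deadtime after the trigger (so a pulse
#' still above threshold at that sample is counted again).
#'
#' @param thresholds Strictly increasing thresholds (same units as the
#'   waveforms fed to [count_frame()]; keV for calibrated waveforms).
#' @param clock_ns Clock period tau_c, ns.
#' @param deadtime_ns Deadtime tau_d, ns (multiple of `clock_ns`).
#' @return An object of class `comparator_bank`.
#' @export
comparator_bank <- function(thresholds, clock_ns = 10, deadtime_ns) {
  if (length(thresholds) < 1L || length(thresholds) > 8L)
    stop_pcd("between 1 and 8 thresholds are supported", "invalid_config")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_pcd("thresholds must be strictly increasing", "invalid_config")
  if (deadtime_ns %% clock_ns != 0)
    stop_pcd("deadtime must be an integer multiple of the clock period",
             "invalid_config")
  structure(list(thresholds = thresholds, clock_ns = clock_ns,
                 deadtime_ns = deadtime_ns),
            class = "comparator_bank")
}

#' @export
print.comparator_bank <- function(x, ...) {
  cat(sprintf("<comparator_bank: %d thresholds [%s], clock %g ns, deadtime %g ns>\n",
              length(x$thresholds), paste(x$thresholds, collapse = ", "),
              x$clock_ns, x$deadtime_ns))
  invisible(x)
}

#' Count a waveform frame through the comparator bank
#'
#' Samples the waveform at `n * clock + phase`, applying the trigger and
#' deadtime logic of [comparator_bank()]. The clock phase is randomized
#' uniformly per frame unless given.
#'
#' @param waveform Numeric waveform (units of the bank thresholds), or a
#'   [voltage_pulse()].
#' @param bank A [comparator_bank()].
#' @param dt Waveform sample spacing, ns (must be <= clock/2).
#' @param seed Optional RNG seed for the phase.
#' @param phase Clock phase in ns (`[0, clock)`); randomized when NULL.
#' @return Integer vector of counts per energy bin (bin i = highest
#'   threshold exceeded is i), with attributes `n_triggers` and `phase`.
#' @export
count_frame <- function(waveform, bank, dt = 2, seed = NULL, phase = NULL) {
  if (inherits(waveform, "voltage_pulse")) {
    dt <- waveform$dt
    waveform <- waveform$samples
  }
  stopifnot(inherits(bank, "comparator_bank"))
  if (dt > bank$clock_ns / 2)
    stop_pcd("waveform must be sampled at <= clock/2 spacing", "invalid_config")
  step <- bank$clock_ns / dt
  if (step != round(step))
    stop_pcd("clock period must be a multiple of the waveform spacing",
             "invalid_config")
  with_seed(seed, {
    if (is.null(phase)) phase <- stats::runif(1, 0, bank$clock_ns)
    off <- 1 + round(phase / dt)
    idx <- seq(off, length(waveform), by = step)     # clock-sample indices
    v <- waveform[idx]
    nd <- bank$deadtime_ns / bank$clock_ns           # deadtime in clock ticks
    nb <- length(bank$thresholds)
    counts <- integer(nb)
    above <- which(v > bank$thresholds[1])
    ntrig <- 0L
    i <- 1L
    while (i <= length(above)) {
      k <- above[i]
      ntrig <- ntrig + 1L
      win <- v[k:min(k + nd - 1L, length(v))]
      bin <- findInterval(max(win), bank$thresholds)
      counts[bin] <- counts[bin] + 1L
      # live again nd ticks after the trigger
      nxt <- k + nd
      while (i <= length(above) && above[i] < nxt) i <- i + 1L
    }
    structure(counts, n_triggers = ntrig, phase = phase)
  })
}

#' Poisson pulse train over a frame
#'
#' Builds the summed voltage waveform of a frame: the number of photons is
#' Poisson with mean `flux * T`, arrival times are uniform on `[0, T]`,
#' deposit energies are drawn from the supplied deposited-energy spectrum,
#' and each photon contributes the keV-calibrated standard pulse shape
#' scaled by its energy. Optionally adds an electronic-noise realization.
#'
#' @param flux Photon flux, photons per second.
#' @param frame_us Frame length T, us.
#' @param spectrum A deposited-energy [energy_spectrum()] (or a single
#'   energy in keV for monochromatic trains).
#' @param config A [shaper_config()].
#' @param sources Optional [noise_sources()] for additive noise.
#' @param geometry A [detector_geometry()].
#' @param dt Sample spacing, ns.
#' @param seed RNG seed.
#' @return List of class `pulse_train`: `waveform` (keV-calibrated), `dt`,
#'   `times`, `energies`, `flux`, `frame_us`.
#' @export
pulse_train <- function(flux, frame_us = 150, spectrum, config,
                        sources = NULL, geometry = detector_geometry(),
                        dt = 2, seed = NULL) {
  with_seed(seed, {
    n_samp <- ceiling(frame_us * 1e3 / dt)
    N <- stats::rpois(1, flux * frame_us * 1e-6)
    times <- sort(stats::runif(N, 0, frame_us * 1e3))
    energies <- if (inherits(spectrum, "energy_spectrum")) {
      bw <- if (length(spectrum$energies) > 1) diff(spectrum$energies[1:2]) else 0
      idx <- sample.int(length(spectrum$energies), N, replace = TRUE,
                        prob = spectrum$values)
      spectrum$energies[idx] + stats::runif(N, -bw / 2, bw / 2)
    } else rep(spectrum, N)
    sh <- standard_shape(config, geometry)
    kern <- sh$shape
    wav <- numeric(n_samp + length(kern))
    i0 <- floor(times / dt) + 1L
    for (j in seq_len(N)) {
      rng <- i0[j]:(i0[j] + length(kern) - 1L)
      wav[rng] <- wav[rng] + energies[j] * kern
    }
    wav <- wav[seq_len(n_samp)]
    if (!is.null(sources)) {
      g <- channel_gain(config, geometry)
      wav <- wav + noise_realization(config, sources, duration = frame_us,
                                     dt = dt, geometry = geometry) / g
    }
    structure(list(waveform = wav, dt = dt, times = times,
                   energies = energies, flux = flux, frame_us = frame_us),
              class = "pulse_train")
  })
}

#' Simulate a lowest-threshold scan
#'
#' Scans the lowest comparator threshold across a grid for a monochromatic
#' beam at one or more deadtime settings, mimicking the DAC-scan pulse-shape
#' measurement. Counts are normalized by the number of unique pulses, so a
#' threshold where pulses are double-counted reads 2 and the single-count
#' plateau reads 1.
#'
#' Two backends are available: `"fast"` applies the clock/deadtime trigger
#' arithmetic per pulse to the noise-free pulse shape (each pulse gets an
#' independent uniform clock phase); `"frame"` synthesizes a long waveform
#' of well-separated pulses (optionally with electronic noise) and runs
#' [count_frame()] per threshold. The two agree in the absence of noise.
#'
#' @param beam_energy Beam energy, keV.
#' @param deadtimes Deadtime settings, ns (multiples of the clock).
#' @param config A [shaper_config()].
#' @param thresholds Threshold grid, keV; default `seq(1, E + 10, 0.5)`.
#' @param n_pulses Pulses per scan.
#' @param seed RNG seed.
#' @param method `"fast"` or `"frame"`.
#' @param sources Optional [noise_sources()] (frame method only) for
#'   waveform noise.
#' @param geometry A [detector_geometry()].
#' @param clock_ns Clock period, ns.
#' @return A list of `threshold_scan` objects (one per deadtime): a
#'   data.frame `threshold_keV`, `counts` with attributes `n_pulses`,
#'   `beam_keV`, `deadtime_ns`, `clock_ns`.
#' @export
simulate_threshold_scan <- function(beam_energy, deadtimes, config,
                                    thresholds = NULL, n_pulses = 1000,
                                    seed = NULL, method = c("fast", "frame"),
                                    sources = NULL,
                                    geometry = detector_geometry(),
                                    clock_ns = 10) {
  method <- match.arg(method)
  if (is.null(thresholds))
    thresholds <- seq(1, beam_energy + 10, by = 0.5)
  sh <- standard_shape(config, geometry)
  v_keV <- beam_energy * sh$shape          # keV-calibrated pulse
  dt <- sh$dt
  with_seed(seed, {
    lapply(deadtimes, function(td) {
      if (td %% clock_ns != 0)
        stop_pcd("deadtime must be a multiple of the clock", "invalid_config")
      counts <- if (method == "fast") {
        L <- vapply(thresholds, function(th)
          as.numeric(pulse_length(v_keV, th, dt = dt)), numeric(1))
        u <- stats::runif(n_pulses, 0, clock_ns)
        vapply(L, function(l) {
          if (l <= 0) return(0L)
          sum(pmax(ceiling((l - u) / td), 0))
        }, numeric(1))
      } else {
        spacing <- ceiling((length(v_keV) * dt + td + 4 * clock_ns) /
                             clock_ns) * clock_ns
        n_samp_p <- spacing / dt
        # de-correlate each pulse from the clock grid: random sub-clock
        # start offset on the waveform grid
        jit <- sample.int(clock_ns / dt, n_pulses, replace = TRUE) - 1L
        wav <- numeric(n_samp_p * n_pulses + clock_ns / dt)
        for (j in seq_len(n_pulses)) {
          i0 <- (j - 1L) * n_samp_p + jit[j]
          rng <- (i0 + 1L):(i0 + length(v_keV))
          wav[rng] <- wav[rng] + v_keV
        }
        if (!is.null(sources)) {
          g <- channel_gain(config, geometry)
          nz <- noise_realization(config, sources,
                                  duration = length(wav) * dt / 1e3,
                                  dt = dt, geometry = geometry) / g
          wav <- wav + nz[seq_along(wav)]
        }
        vapply(thresholds, function(th) {
          cf <- count_frame(wav, comparator_bank(th, clock_ns, td), dt = dt)
          sum(cf)
        }, numeric(1))
      }
      structure(data.frame(threshold_keV = thresholds, counts = counts),
                n_pulses = n_pulses, beam_keV = beam_energy,
                deadtime_ns = td, clock_ns = clock_ns,
                class = c("threshold_scan", "data.frame"))
    })
  })
}

#' Normalized counts of a threshold scan
#' @param scan A `threshold_scan`.
#' @return Numeric vector `counts / n_pulses`.
#' @export
normalized_counts <- function(scan) {
  scan$counts / attr(scan, "n_pulses")
}

#' @export
plot.threshold_scan <- function(x, ...) {
  graphics::plot(x$threshold_keV, normalized_counts(x), type = "b",
                 xlab = "lowest threshold (keV)", ylab = "normalized counts",
                 ...)
  graphics::abline(h = c(1, 1.5, 2), lty = 3, col = "grey")
  invisible(x)
}

#' Extract the half-double-counting threshold E1/2
#'
#' The threshold at which the normalized counts cross 1.5, i.e. where half
#' of the pulses are counted twice: there the pulse length equals the
#' deadtime plus half a clock cycle. Thresholds below the noise/triple-count
#' exclusion region are ignored; the crossing is linearly interpolated.
#'
#' @param scan A `threshold_scan` from [simulate_threshold_scan()] (or a
#'   data.frame with `threshold_keV` and `counts` plus an `n_pulses`
#'   attribute).
#' @param exclude_below Exclusion threshold, keV.
#' @return E1/2 in keV.
#' @export
extract_e_half <- function(scan, exclude_below = 15) {
  norm <- normalized_counts(scan)
  thr <- scan$threshold_keV
  keep <- thr >= exclude_below
  norm <- norm[keep]; thr <- thr[keep]
  # last index still >= 1.5 followed by a drop below
  below <- which(norm < 1.5)
  above <- which(norm >= 1.5)
  if (!length(above) || !length(below) || min(below) == 1L)
    stop_pcd("no 2->1 transition found in the scan", "extraction_error")
  i <- max(above[above < max(below)])
  if (i == length(norm) || norm[i + 1] >= 1.5)
    stop_pcd("no 2->1 transition found in the scan", "extraction_error")
  # linear interpolation between thr[i] and thr[i+1]
  thr[i] + (1.5 - norm[i]) / (norm[i + 1] - norm[i]) * (thr[i + 1] - thr[i])
}

#' Lowest threshold and deadtime for a shaping time
#'
#' The lowest threshold is 4 sigma of the calibrated noise at that shaping
#' time (one noise count per 150-us frame on average); the deadtime is the
#' length of a 100-keV pulse at that threshold, rounded up to a clock
#' multiple.
#'
#' @param tau Shaping time, ns (ideal channel).
#' @param sources A [noise_sources()].
#' @param geometry A [detector_geometry()].
#' @param clock_ns Clock period, ns.
#' @return List with `threshold_keV`, `pulse_length_ns`, `deadtime_ns`.
#' @export
deadtime_for <- function(tau, sources = noise_sources(),
                         geometry = detector_geometry(), clock_ns = 10) {
  cfg <- ideal_config_at(tau)
  g <- channel_gain(cfg, geometry)
  s <- sigma_total(cfg, sources, gain = g, geometry = geometry)
  thr <- 4 * s[["sigma_keV"]]
  sh <- standard_shape(cfg, geometry)
  L <- as.numeric(pulse_length(100 * sh$shape, thr, dt = sh$dt))
  list(threshold_keV = thr, pulse_length_ns = L,
       deadtime_ns = ceiling(L / clock_ns) * clock_ns)
}

#' Output versus input count rate
#'
#' Simulates frames of Poisson pulse trains at each input flux and counts
#' them with the lowest threshold at 4 sigma and the deadtime set to the
#' 100-keV pulse length for the given shaping time.
#'
#' @param fluxes Input count rates, photons/s (interactions per channel).
#' @param tau Shaping time, ns (ideal channel).
#' @param spectrum Deposited-energy [energy_spectrum()] for the pulse
#'   energies.
#' @param n_frames Frames per flux point.
#' @param seed RNG seed.
#' @param sources,geometry,frame_us,clock_ns Passed through.
#' @param noise Add electronic noise to the waveforms.
#' @return data.frame `input_rate`, `output_rate` (counts/s), `threshold_keV`,
#'   `deadtime_ns`.
#' @export
count_rate_curve <- function(fluxes, tau, spectrum, n_frames = 50,
                             seed = NULL, sources = noise_sources(),
                             geometry = detector_geometry(),
                             frame_us = 150, clock_ns = 10, noise = FALSE) {
  setup <- deadtime_for(tau, sources, geometry, clock_ns)
  cfg <- ideal_config_at(tau)
  bank <- comparator_bank(setup$threshold_keV, clock_ns, setup$deadtime_ns)
  with_seed(seed, {
    out <- vapply(fluxes, function(fl) {
      tot <- 0L
      for (fr in seq_len(n_frames)) {
        tr <- pulse_train(fl, frame_us, spectrum, cfg,
                          sources = if (noise) sources else NULL,
                          geometry = geometry)
        tot <- tot + sum(count_frame(tr$waveform, bank, dt = tr$dt))
      }
      tot / (n_frames * frame_us * 1e-6)
    }, numeric(1))
    data.frame(input_rate = fluxes, output_rate = out,
               threshold_keV = setup$threshold_keV,
               deadtime_ns = setup$deadtime_ns)
  })
}
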