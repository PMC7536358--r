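# Mass attenuation coefficients (cm^2/g) on a sparse energy grid (keV),
# log-log interpolated. Values from standard compilations; soft tissue is
# the ICRU-44 four-component composition (water-like at CT energies).
# Tungsten includes the K edge at 69.525 keV (two nodes bracketing it).
.mu_rho_tables <- list(
  soft_tissue = list(
    E = c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
    mu = c(5.37, 1.693, 0.823, 0.379, 0.270, 0.227, 0.206, 0.183, 0.170, 0.150)),
  Al = list(
    E = c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
    mu = c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2018,
           0.1704, 0.1378)),
  Be = list(
    E = c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
    mu = c(0.6466, 0.307, 0.2251, 0.1792, 0.164, 0.1554, 0.1493, 0.1401,
           0.1328, 0.119)),
  Si = list(
    E = c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
    mu = c(33.89, 10.34, 4.464, 1.436, 0.7012, 0.4385, 0.3207, 0.2228,
           0.1835, 0.1448)),
  W = list(
    E = c(10, 15, 20, 30, 40, 50, 60, 69.5, 69.55, 80, 100, 150),
    mu = c(96.91, 139.4, 65.73, 22.73, 10.67, 5.949, 3.713, 2.552, 11.23,
           7.810, 4.438, 1.581))
)

# coherent (Rayleigh) part for silicon, cm^2/g; subtracted to obtain the
# photoelectric part (coherent scattering deposits nothing and is treated
# as no interaction throughout)
.si_coherent <- list(
  E = c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  mu = c(0.33, 0.21, 0.146, 0.082, 0.052, 0.036, 0.026, 0.016, 0.011, 0.005))

.densities <- c(soft_tissue = 1.06, Al = 2.699, Be = 1.848, Si = 2.33, W = 19.3)

loglog_interp <- function(tab, energies) {
  exp(stats::approx(log(tab$E), log(tab$mu), xout = log(energies),
                    rule = 2)$y)
}

#' Mass attenuation coefficient lookup
#'
#' Log-log interpolated mass attenuation coefficients from the embedded
#' tables (1-150 keV; values below the lowest table node are clamped).
#'
#' @param material One of `"soft_tissue"`, `"Al"`, `"Be"`, `"Si"`, `"W"`.
#' @param energies Photon energies, keV.
#' @return mu/rho in cm^2/g.
#' @export
mass_attenuation <- function(material, energies) {
  if (!material %in% names(.mu_rho_tables))
    stop_pcd(sprintf("unknown material '%s'", material), "material_error")
  loglog_interp(.mu_rho_tables[[material]], energies)
}

#' Klein-Nishina total cross section per electron
#'
#' @param energy Photon energy, keV.
#' @return Cross section in barn.
#' @export
kn_total_cross_section <- function(energy) {
  k <- energy / .const$mec2_keV
  re2 <- 0.0794098  # classical electron radius squared, barn
  term <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * re2 * term
}

#' Compton edge energy
#'
#' Maximum electron recoil energy `2 E^2 / (m_e c^2 + 2 E)`.
#' @param energy Incident photon energy, keV.
#' @return Edge energy, keV.
#' @export
compton_edge <- function(energy) {
  2 * energy^2 / (.const$mec2_keV + 2 * energy)
}

# silicon interaction coefficients (cm^-1): photoelectric and incoherent.
# Incoherent from Klein-Nishina (free electrons, Z = 14, A = 28.085);
# photoelectric as total minus incoherent minus tabulated coherent.
si_interaction_mu <- function(energies) {
  ne_per_g <- 14 / 28.085 * 6.02214076e23        # electrons per gram
  incoh <- kn_total_cross_section(energies) * 1e-24 * ne_per_g *
    .densities[["Si"]]
  total <- mass_attenuation("Si", energies) * .densities[["Si"]]
  coh <- loglog_interp(.si_coherent, energies) * .densities[["Si"]]
  photo <- pmax(total - incoh - coh, 1e-8)
  list(photo = photo, incoh = incoh)
}

# vectorised sampling of Compton electron energies from the Klein-Nishina
# angular distribution (free electron), by rejection on cos(theta)
sample_kn_deposit <- function(energies) {
  n <- length(energies)
  k <- energies / .const$mec2_keV
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  # envelope: the KN differential in cos(theta) is bounded by its forward value
  while (length(todo)) {
    kk <- k[todo]
    ct <- stats::runif(length(todo), -1, 1)
    r <- 1 / (1 + kk * (1 - ct))          # E'/E
    w <- r^2 * (r + 1 / r - (1 - ct^2))   # dSigma/dcos up to a constant
    wmax <- 2                              # forward: r=1, w = 2 - 0 = 2
    acc <- stats::runif(length(todo)) * wmax < w
    hit <- todo[acc]
    out[hit] <- energies[hit] * (1 - r[acc])
    todo <- todo[!acc]
  }
  out
}

#' Energy spectrum container
#'
#' A histogram-style spectrum on a keV grid (bin centers, uniform width).
#'
#' @param energies Bin centers, keV.
#' @param values Relative fluence or counts per bin (non-negative).
#' @param kind `"incident"` or `"deposited"`.
#' @return An object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(energies, values, kind = c("incident", "deposited")) {
  kind <- match.arg(kind)
  if (any(values < 0)) stop_pcd("spectrum values must be non-negative",
                                "invalid_spectrum")
  structure(list(energies = energies, values = values, kind = kind),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum (%s): %d bins, %g-%g keV, mean %.1f keV>\n",
              x$kind, length(x$energies), min(x$energies), max(x$energies),
              mean_energy(x)))
  invisible(x)
}

#' @export
plot.energy_spectrum <- function(x, ...) {
  graphics::plot(x$energies, x$values, type = "s", xlab = "energy (keV)",
                 ylab = if (x$kind == "incident") "relative fluence" else "counts",
                 ...)
  invisible(x)
}

#' Mean energy of a spectrum
#' @param spectrum An [energy_spectrum()].
#' @return Fluence-weighted mean energy, keV.
#' @export
mean_energy <- function(spectrum) {
  stats::weighted.mean(spectrum$energies, spectrum$values)
}

#' X-ray beam configuration
#'
#' @param kvp Tube voltage, kV.
#' @param anode_angle Tungsten anode angle, degrees.
#' @param filtration_al_mm Inherent aluminum filtration, mm.
#' @param filtration_be_mm Beryllium window, mm.
#' @param tissue_cm Soft-tissue (patient) filtration, cm.
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(kvp = 120, anode_angle = 10.5,
                        filtration_al_mm = 8.38, filtration_be_mm = 0.8,
                        tissue_cm = 20) {
  if (kvp <= 0) stop_pcd("kvp must be positive", "invalid_config")
  if (any(c(filtration_al_mm, filtration_be_mm, tissue_cm) < 0))
    stop_pcd("filtrations must be non-negative", "invalid_config")
  structure(list(kvp = kvp, anode_angle = anode_angle,
                 filtration_al_mm = filtration_al_mm,
                 filtration_be_mm = filtration_be_mm,
                 tissue_cm = tissue_cm),
            class = "beam_config")
}

#' Semi-empirical filtered tungsten tube spectrum
#'
#' A Kramers-type bremsstrahlung photon fluence, `N(E) dE` proportional to
#' `(E0 - E)/E`, self-filtered through an effective tungsten path scaled by
#' the anode angle, with tungsten K characteristic lines (Kalpha1/2,
#' Kbeta1/2) added as a fixed fraction of the bremsstrahlung fluence when
#' the tube voltage exceeds the K edge. Inherent (Be, Al) and patient
#' (soft-tissue) filtration are applied per Beer-Lambert. The result is
#' normalized to unit total fluence.
#'
#' @param beam A [beam_config()].
#' @param bin_width Energy bin width, keV.
#' @param emin Lowest tabulated energy, keV.
#' @param w_eff_um Effective tungsten self-filtration path at a 10.5-degree
#'   anode, um.
#' @param k_line_fraction Characteristic-line share of the bremsstrahlung
#'   photon fluence (before inherent filtration).
#' @return An [energy_spectrum()] (`kind = "incident"`).
#' @export
tube_spectrum <- function(beam = beam_config(), bin_width = 0.5, emin = 1,
                          w_eff_um = 2, k_line_fraction = 0.09) {
  stopifnot(inherits(beam, "beam_config"))
  E <- seq(emin + bin_width / 2, beam$kvp, by = bin_width)
  n <- pmax(beam$kvp / E - 1, 0)                      # Kramers photon fluence
  # anode self-filtration: effective W path, scaled to the takeoff angle
  w_path_cm <- w_eff_um * 1e-4 * sin(10.5 * pi / 180) /
    sin(beam$anode_angle * pi / 180)
  n <- n * exp(-mass_attenuation("W", E) * .densities[["W"]] * w_path_cm)
  # tungsten K lines
  if (beam$kvp > 69.525 && k_line_fraction > 0) {
    lines <- data.frame(E = c(57.98, 59.32, 67.1, 69.07),
                        w = c(0.31, 0.54, 0.12, 0.03))
    tot <- k_line_fraction * sum(n)
    for (i in seq_len(nrow(lines))) {
      j <- which.min(abs(E - lines$E[i]))
      n[j] <- n[j] + tot * lines$w[i]
    }
  }
  sp <- energy_spectrum(E, n, "incident")
  sp <- attenuate(sp, "Be", beam$filtration_be_mm, units = "mm")
  sp <- attenuate(sp, "Al", beam$filtration_al_mm, units = "mm")
  if (beam$tissue_cm > 0)
    sp <- attenuate(sp, "soft_tissue", beam$tissue_cm, units = "cm")
  sp$values <- sp$values / sum(sp$values)
  sp
}

#' Beer-Lambert filtration of a spectrum
#'
#' @param spectrum An [energy_spectrum()].
#' @param material Material name in the attenuation tables.
#' @param thickness Thickness in `units`.
#' @param units `"cm"` or `"mm"`.
#' @return The attenuated [energy_spectrum()].
#' @export
attenuate <- function(spectrum, material, thickness, units = c("cm", "mm")) {
  units <- match.arg(units)
  stopifnot(inherits(spectrum, "energy_spectrum"))
  if (thickness < 0) stop_pcd("thickness must be non-negative", "material_error")
  t_cm <- if (units == "mm") thickness / 10 else thickness
  mu <- mass_attenuation(material, spectrum$energies) * .densities[[material]]
  energy_spectrum(spectrum$energies, spectrum$values * exp(-mu * t_cm),
                  spectrum$kind)
}

#' Deposited-energy response of the silicon detector
#'
#' Monte-Carlo sampling of the simplified silicon response: each photon is
#' drawn from the incident spectrum, attenuated by the dead layer at the
#' pixel top, and interacts in the active strip length with probability
#' `1 - exp(-mu * L)` using the photoelectric-plus-incoherent interaction
#' coefficient. Photoelectric events deposit the full energy; Compton
#' events deposit a Klein-Nishina electron energy. Photons absorbed in the
#' dead layer or passing through are excluded. Deposits are histogrammed on
#' the 0.5-keV grid starting at 1 keV; deposits below the lowest bin edge
#' (`min_deposit`) are unregistrable and excluded like zero-deposit events.
#'
#' @param incident An [energy_spectrum()] (`kind = "incident"`).
#' @param geometry A [detector_geometry()].
#' @param n_photons Number of photons to sample.
#' @param seed RNG seed.
#' @param bin_width Histogram bin width, keV.
#' @param min_deposit Registration floor: lower edge of the first bin, keV.
#' @return An [energy_spectrum()] (`kind = "deposited"`) with attributes
#'   `n_photons`, `n_interactions`, `n_dead_layer`.
#' @export
detector_response <- function(incident, geometry = detector_geometry(),
                              n_photons = 1e5, seed = NULL, bin_width = 0.5,
                              min_deposit = 0.75) {
  stopifnot(inherits(incident, "energy_spectrum"))
  if (sum(incident$values) <= 0) stop_pcd("empty spectrum", "empty_error")
  with_seed(seed, {
    bw_in <- if (length(incident$energies) > 1) diff(incident$energies[1:2]) else 0
    idx <- sample.int(length(incident$energies), n_photons, replace = TRUE,
                      prob = incident$values)
    E <- incident$energies[idx] + stats::runif(n_photons, -bw_in / 2, bw_in / 2)
    E <- pmax(E, 1)
    mu <- si_interaction_mu(E)
    mu_tot <- mu$photo + mu$incoh
    # dead layer at the pixel top
    p_dead <- 1 - exp(-mu_tot * geometry$dead_layer / 10)
    u <- stats::runif(n_photons)
    dead <- u < p_dead
    # interaction in the active strip length
    p_int <- 1 - exp(-mu_tot * geometry$strip_length / 10)
    interact <- !dead & (stats::runif(n_photons) < p_int)
    Ei <- E[interact]
    mui <- lapply(mu, `[`, interact)
    photo <- stats::runif(length(Ei)) < mui$photo / (mui$photo + mui$incoh)
    dep <- numeric(length(Ei))
    dep[photo] <- Ei[photo]
    if (any(!photo)) dep[!photo] <- sample_kn_deposit(Ei[!photo])
    dep <- dep[dep >= min_deposit]
    emax <- max(incident$energies) + bin_width
    breaks <- seq(min_deposit, emax + bin_width, by = bin_width)
    h <- graphics::hist(pmin(dep, emax), breaks = breaks, plot = FALSE)
    structure(
      energy_spectrum(h$mids, h$counts, "deposited"),
      n_photons = n_photons, n_interactions = length(dep),
      n_dead_layer = sum(dead))
  })
}

#' Dose efficiency at a counting threshold
#'
#' The fraction of deposited-energy counts above the threshold, relative to
#' all counts in the spectrum (the registered fraction of interacting
#' photons for a purely photon-counting detector). The bin containing the
#' threshold contributes fractionally.
#'
#' @param deposited A deposited-energy [energy_spectrum()].
#' @param threshold Lowest counting threshold, keV (>= 0).
#' @return Fraction in `[0, 1]`.
#' @export
dose_efficiency <- function(deposited, threshold) {
  stopifnot(inherits(deposited, "energy_spectrum"))
  if (threshold < 0) stop_pcd("threshold must be non-negative", "domain_error")
  tot <- sum(deposited$values)
  if (tot <= 0) stop_pcd("empty spectrum", "empty_error")
  bw <- diff(deposited$energies[1:2])
  lo <- deposited$energies - bw / 2
  hi <- deposited$energies + bw / 2
  fr <- pmin(pmax((hi - threshold) / bw, 0), 1)
  sum(deposited$values * fr) / tot
}
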