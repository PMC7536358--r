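#' Edge-on silicon strip detector geometry
#'
#' Geometry and operating point of one detector pixel. The wafer thickness
#' is the drift distance between the collecting strip (at x = 0, held at
#' 0 V) and the backside (at the bias voltage). X-rays enter edge-on along
#' the strip, which is segmented in depth; a dead layer at the pixel top
#' attenuates the beam before the active volume.
#'
#' @param pixel_pitch_x,pixel_pitch_y Pixel pitch, mm (0.4 x 0.5 default;
#'   the y pitch equals the wafer thickness in the edge-on layout).
#' @param wafer_thickness Drift distance, um.
#' @param bias_voltage Reverse bias applied at the backside, V.
#' @param doping Net doping concentration, cm^-3.
#' @param temperature Absolute temperature, K.
#' @param strip_length Active strip length along the beam, mm.
#' @param n_segments Number of depth segments.
#' @param dead_layer Dead layer at the pixel top, mm.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(pixel_pitch_x = 0.4, pixel_pitch_y = 0.5,
                              wafer_thickness = 500, bias_voltage = 400,
                              doping = 4.6e11, temperature = 300,
                              strip_length = 30, n_segments = 9,
                              dead_layer = 0.6) {
  g <- list(pixel_pitch_x = pixel_pitch_x, pixel_pitch_y = pixel_pitch_y,
            wafer_thickness = wafer_thickness, bias_voltage = bias_voltage,
            doping = doping, temperature = temperature,
            strip_length = strip_length, n_segments = n_segments,
            dead_layer = dead_layer)
  if (any(unlist(g[c("pixel_pitch_x", "pixel_pitch_y", "wafer_thickness",
                     "bias_voltage", "temperature", "strip_length")]) <= 0))
    stop_pcd("all dimensions must be positive", "invalid_geometry")
  class(g) <- "detector_geometry"
  if (depletion_voltage(g) > bias_voltage)
    stop_pcd(sprintf(
      "detector not fully depleted: depletion voltage %.1f V > bias %.1f V",
      depletion_voltage(g), bias_voltage), "depletion_error")
  g
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry: %g x %g mm pixel, d = %g um, %g V bias (depletion %.1f V)>\n",
    x$pixel_pitch_x, x$pixel_pitch_y, x$wafer_thickness, x$bias_voltage,
    depletion_voltage(x)))
  invisible(x)
}

#' Full-depletion voltage of the planar diode
#'
#' `V_dep = e * N * d^2 / (2 * eps)` for uniform net doping `N` and drift
#' distance `d`.
#' @param geometry A [detector_geometry()].
#' @return Depletion voltage, V.
#' @export
depletion_voltage <- function(geometry) {
  d_cm <- geometry$wafer_thickness * 1e-4
  .const$e_C * geometry$doping * d_cm^2 / (2 * .const$eps_si)
}

#' Electric field across the wafer from the Poisson equation
#'
#' Solves the 1-D Poisson equation `-phi'' = rho/eps` with `phi(0) = 0` at
#' the collecting strip and `phi(d) = V` at the backside, for uniform space
#' charge given by the net doping. The default second-order finite-difference
#' solve matches the closed-form over-depleted planar solution
#' `E(x) = V/d + (e N / eps) (d/2 - x)` to well below 0.1%;
#' `method = "analytic"` returns the closed form directly.
#'
#' @param geometry A [detector_geometry()].
#' @param n_nodes Number of finite-difference nodes.
#' @param method `"fd"` or `"analytic"`.
#' @return A list of class `drift_field` with `x` (um, from the strip),
#'   `E` (field magnitude, V/cm) and `phi` (potential, V).
#' @export
solve_field <- function(geometry, n_nodes = 501,
                        method = c("fd", "analytic")) {
  method <- match.arg(method)
  stopifnot(inherits(geometry, "detector_geometry"))
  if (depletion_voltage(geometry) > geometry$bias_voltage)
    stop_pcd("under-depleted configuration", "depletion_error")
  d_cm <- geometry$wafer_thickness * 1e-4
  V <- geometry$bias_voltage
  rho_eps <- .const$e_C * geometry$doping / .const$eps_si  # V/cm^2
  x_cm <- seq(0, d_cm, length.out = n_nodes)
  if (method == "analytic") {
    phi <- V * x_cm / d_cm + rho_eps / 2 * (d_cm * x_cm - x_cm^2)
    E <- V / d_cm + rho_eps * (d_cm / 2 - x_cm)
  } else {
    # phi'' = -rho/eps on interior nodes, Dirichlet ends; tridiagonal solve
    # via the Thomas algorithm.
    h <- x_cm[2] - x_cm[1]
    m <- n_nodes - 2L
    b <- rep(-rho_eps * h^2, m)
    b[1] <- b[1] - 0        # phi(0) = 0
    b[m] <- b[m] - V        # phi(d) = V
    diag_main <- rep(-2, m); diag_off <- rep(1, m - 1)
    cp <- numeric(m); dp <- numeric(m)
    cp[1] <- diag_off[1] / diag_main[1]
    dp[1] <- b[1] / diag_main[1]
    for (i in 2:m) {
      denom <- diag_main[i] - diag_off[i - 1] * cp[i - 1]
      if (i < m) cp[i] <- diag_off[i] / denom
      dp[i] <- (b[i] - diag_off[i - 1] * dp[i - 1]) / denom
    }
    phi_int <- numeric(m)
    phi_int[m] <- dp[m]
    for (i in (m - 1):1) phi_int[i] <- dp[i] - cp[i] * phi_int[i + 1]
    phi <- c(0, phi_int, V)
    # field magnitude from centered differences, one-sided at the ends
    E <- numeric(n_nodes)
    E[2:(n_nodes - 1)] <- (phi[3:n_nodes] - phi[1:(n_nodes - 2)]) / (2 * h)
    E[1] <- (-3 * phi[1] + 4 * phi[2] - phi[3]) / (2 * h)
    E[n_nodes] <- (3 * phi[n_nodes] - 4 * phi[n_nodes - 1] + phi[n_nodes - 2]) / (2 * h)
  }
  structure(list(x = x_cm * 1e4, E = E, phi = phi, geometry = geometry),
            class = "drift_field")
}

# field magnitude (V/cm) at drift positions x_um, linear interpolation
field_at <- function(field, x_um) {
  stats::approx(field$x, field$E, xout = pmin(pmax(x_um, field$x[1]),
                                              field$x[length(field$x)]),
                rule = 2)$y
}

#' Sample a photon interaction in the silicon strip
#'
#' A simplified interaction model standing in for full Monte-Carlo
#' transport: the interaction type is chosen between photoelectric
#' absorption (full energy deposit) and Compton scattering (electron energy
#' sampled from the Klein-Nishina distribution) with probabilities from the
#' silicon cross sections at the given energy; coherent scattering is
#' treated as no interaction. The deposit is point-like: a cloud of
#' `n_carriers` representative electron-hole pairs with charge weights, at a
#' drift-axis position drawn uniformly across the wafer thickness (the beam
#' illuminates the pixel center, so lateral spread is irrelevant for the
#' planar weighting field) and a depth along the strip drawn from
#' exponential attenuation over the active length.
#'
#' @param energy Incident photon energy, keV (1-150).
#' @param geometry A [detector_geometry()].
#' @param seed Optional RNG seed.
#' @param n_carriers Number of representative carriers per sign.
#' @param cloud_sigma Optional isotropic Gaussian spread of the initial
#'   cloud, um.
#' @param force Force an interaction type: `"photo"`, `"compton"`, or
#'   `NA` (sample).
#' @return A list of class `carrier_cloud` with positions (um), per-carrier
#'   charge weight (fC), deposited energy (keV) and interaction metadata.
#' @export
sample_interaction <- function(energy, geometry, seed = NULL,
                               n_carriers = 1000, cloud_sigma = 0,
                               force = NA_character_) {
  if (!is.finite(energy) || energy < 1 || energy > 150)
    stop_pcd("energy must lie in [1, 150] keV", "domain_error")
  stopifnot(inherits(geometry, "detector_geometry"))
  with_seed(seed, {
    mu <- si_interaction_mu(energy)          # photo, incoh in cm^-1
    type <- if (!is.na(force)) force else
      if (stats::runif(1) < mu$photo / (mu$photo + mu$incoh)) "photo" else "compton"
    deposit <- if (type == "photo") energy else sample_kn_deposit(energy)
    d_um <- geometry$wafer_thickness
    x0 <- stats::runif(1, 0, d_um)
    # depth along the strip: truncated exponential over the active length
    mu_tot <- mu$photo + mu$incoh
    L_cm <- geometry$strip_length / 10
    u <- stats::runif(1)
    y0_mm <- -log(1 - u * (1 - exp(-mu_tot * L_cm))) / mu_tot * 10
    xs <- rep(x0, n_carriers)
    ys <- rep(0, n_carriers)
    if (cloud_sigma > 0) {
      xs <- xs + stats::rnorm(n_carriers, 0, cloud_sigma)
      ys <- ys + stats::rnorm(n_carriers, 0, cloud_sigma)
      xs <- pmin(pmax(xs, 0), d_um)
    }
    w <- energy_to_charge_fC(deposit) / n_carriers
    structure(list(x = xs, y = ys, weight_fC = rep(w, n_carriers),
                   energy = deposit, incident_energy = energy,
                   type = type, depth_mm = y0_mm, creation_time = 0,
                   geometry = geometry),
              class = "carrier_cloud")
  })
}

# carrier drift velocity magnitude, cm/s
carrier_velocity <- function(E_Vcm, mobility, vsat = NULL) {
  v <- mobility * E_Vcm
  if (!is.null(vsat)) v <- v / (1 + mobility * E_Vcm / vsat)
  v
}

#' Advance a carrier ensemble by one transport step
#'
#' Each carrier moves by its drift velocity (`v = mu * E`, or the
#' velocity-saturation form when `saturate = TRUE`) times `dt`, plus
#' independent Gaussian diffusion displacements in the drift (x) and lateral
#' (y) directions with variance `2 * D * dt`, `D = kT mu / e`. Electrons
#' drift towards the backside, holes towards the strip; carriers reaching an
#' electrode are absorbed and flagged. Lateral positions are reflected at
#' the pixel boundaries.
#'
#' @param positions Matrix-like list with `x`, `y` (um) for one carrier
#'   species.
#' @param species `"electron"` or `"hole"`.
#' @param field A `drift_field` from [solve_field()].
#' @param dt Time step, ns.
#' @param geometry A [detector_geometry()].
#' @param diffuse Include diffusion (TRUE) or drift only.
#' @param saturate Use the velocity-saturation mobility model.
#' @return List with updated `x`, `y`, logical `collected`, and the signed
#'   drift displacement `dx_drift` (um) actually moved this step (used for
#'   induced-current bookkeeping).
#' @export
transport_step <- function(positions, species = c("electron", "hole"),
                           field, dt = 2, geometry,
                           diffuse = TRUE, saturate = FALSE) {
  species <- match.arg(species)
  if (dt <= 0) stop_pcd("dt must be positive", "domain_error")
  d_um <- geometry$wafer_thickness
  x <- positions$x
  y <- positions$y
  live <- !(if (species == "electron") x >= d_um else x <= 0)
  mobility <- if (species == "electron") .const$mu_e else .const$mu_h
  vsat <- if (!saturate) NULL else
    if (species == "electron") .const$vsat_e else .const$vsat_h
  E_here <- field_at(field, x)
  v <- carrier_velocity(E_here, mobility, vsat)      # cm/s
  step_um <- v * dt * 1e-9 * 1e4                     # um per step
  sgn <- if (species == "electron") +1 else -1
  dx <- ifelse(live, sgn * step_um, 0)
  if (diffuse) {
    D <- .const$kB_JK * geometry$temperature * mobility / .const$e_C  # cm^2/s
    sd_um <- sqrt(2 * D * dt * 1e-9) * 1e4
    n <- length(x)
    dx <- dx + ifelse(live, stats::rnorm(n, 0, sd_um), 0)
    y <- y + ifelse(live, stats::rnorm(n, 0, sd_um), 0)
    # reflect at lateral pixel boundaries
    half <- geometry$pixel_pitch_x * 1000 / 2
    y <- ifelse(y > half, 2 * half - y, y)
    y <- ifelse(y < -half, -2 * half - y, y)
  }
  x_new <- x + dx
  # clamp at the electrodes; record the displacement actually travelled
  x_clamped <- pmin(pmax(x_new, 0), d_um)
  dx_eff <- x_clamped - x
  collected <- if (species == "electron") x_clamped >= d_um else x_clamped <= 0
  list(x = x_clamped, y = y, collected = collected, dx_drift = dx_eff)
}

#' Drift a carrier cloud to collection, recording the trajectory
#'
#' Runs [transport_step()] for electrons and holes on the 2-ns grid until
#' both species are fully collected (or `max_steps` is reached), recording
#' the summed signed drift displacement of each species at every step.
#'
#' @param cloud A `carrier_cloud` from [sample_interaction()].
#' @param field A `drift_field`; defaults to solving the cloud's geometry.
#' @param dt Time step, ns.
#' @param seed Optional RNG seed.
#' @param diffuse,saturate Passed to [transport_step()].
#' @param max_steps Safety limit on the number of steps.
#' @return An object of class `carrier_trajectory`: per-step summed
#'   charge-weighted displacements (fC um) for each species, plus grid info.
#' @export
drift_cloud <- function(cloud, field = NULL, dt = 2, seed = NULL,
                        diffuse = TRUE, saturate = FALSE, max_steps = 5000) {
  stopifnot(inherits(cloud, "carrier_cloud"))
  geometry <- cloud$geometry
  if (is.null(field)) field <- solve_field(geometry)
  with_seed(seed, {
    el <- list(x = cloud$x, y = cloud$y)
    ho <- list(x = cloud$x, y = cloud$y)
    w <- cloud$weight_fC
    qx_e <- numeric(0)
    qx_h <- numeric(0)
    for (k in seq_len(max_steps)) {
      se <- transport_step(el, "electron", field, dt, geometry,
                           diffuse = diffuse, saturate = saturate)
      sh <- transport_step(ho, "hole", field, dt, geometry,
                           diffuse = diffuse, saturate = saturate)
      qx_e[k] <- sum(w * se$dx_drift)    # fC um (signed, towards backside > 0)
      qx_h[k] <- sum(w * sh$dx_drift)    # fC um (towards strip < 0)
      el <- se; ho <- sh
      if (all(se$collected) && all(sh$collected)) break
    }
    structure(list(dqx_electron = qx_e, dqx_hole = qx_h, dt = dt,
                   weight_total_fC = sum(w), energy = cloud$energy,
                   geometry = geometry),
              class = "carrier_trajectory")
  })
}

#' Induced current from a recorded trajectory (Shockley-Ramo)
#'
#' For the planar weighting field `E_w = 1/d` of a fully covering pixel
#' electrode, the instantaneous induced current is
#' `i(t) = sum_k q_k v_k / d`; integrated over a complete trajectory it
#' equals the total generated charge. Electron motion towards the backside
#' and hole motion towards the strip induce current of the same sign on the
#' strip.
#'
#' @param trajectory A `carrier_trajectory` from [drift_cloud()].
#' @param geometry A [detector_geometry()]; defaults to the trajectory's.
#' @return A [current_pulse()] (uA on the trajectory's time grid).
#' @export
induced_current <- function(trajectory, geometry = NULL) {
  stopifnot(inherits(trajectory, "carrier_trajectory"))
  if (is.null(geometry)) geometry <- trajectory$geometry
  d_um <- geometry$wafer_thickness
  dt <- trajectory$dt
  # electrons move to +x with charge -e inducing +|q| v/d on the strip;
  # holes move to -x with +e inducing the same sign. fC um / (um ns) = uA.
  i_uA <- (trajectory$dqx_electron - trajectory$dqx_hole) / (d_um * dt)
  current_pulse(i_uA, dt = dt, energy = trajectory$energy,
                metadata = list(weight_total_fC = trajectory$weight_total_fC))
}

#' Simulate a complete induced-current pulse for one interaction
#'
#' Convenience wrapper: [sample_interaction()] (optionally forcing a
#' full-energy photoelectric deposit, as appropriate for monochromatic
#' calibration beams), [drift_cloud()] and [induced_current()].
#'
#' @param energy Photon energy, keV.
#' @param geometry A [detector_geometry()].
#' @param seed Optional RNG seed.
#' @param field Optional pre-solved `drift_field`.
#' @param full_deposit Force photoelectric full-energy deposit (default
#'   TRUE, the calibration-beam photo-peak condition).
#' @param n_carriers,diffuse,saturate Passed through.
#' @return A [current_pulse()].
#' @export
simulate_current_pulse <- function(energy, geometry = detector_geometry(),
                                   seed = NULL, field = NULL,
                                   full_deposit = TRUE, n_carriers = 1000,
                                   diffuse = TRUE, saturate = FALSE) {
  if (is.null(field)) field <- solve_field(geometry)
  with_seed(seed, {
    cloud <- sample_interaction(energy, geometry, n_carriers = n_carriers,
                                force = if (full_deposit) "photo" else NA_character_)
    traj <- drift_cloud(cloud, field, diffuse = diffuse, saturate = saturate)
    induced_current(traj, geometry)
  })
}

#' Ensemble of induced-current pulses over interaction positions
#'
#' Simulates `n_positions` full-energy pulses per requested energy, with
#' interaction positions drawn uniformly across the wafer thickness. Used
#' for gain determination and as the standard pulse fixture for noise
#' calibration (seed 0).
#'
#' @param energies Photon energies, keV.
#' @param geometry A [detector_geometry()].
#' @param n_positions Pulses per energy.
#' @param seed RNG seed for the ensemble.
#' @param ... Passed to [simulate_current_pulse()].
#' @return A list of [current_pulse()] objects.
#' @export
simulate_pulse_ensemble <- function(energies, geometry = detector_geometry(),
                                    n_positions = 20, seed = 0, ...) {
  field <- solve_field(geometry)
  with_seed(seed, {
    out <- list()
    for (E in energies) {
      for (j in seq_len(n_positions)) {
        out[[length(out) + 1L]] <-
          simulate_current_pulse(E, geometry, field = field, ...)
      }
    }
    out
  })
}

#' Channel gain for a configuration (simulated calibration)
#'
#' Computes the gain in mV/keV from a seeded ensemble of full-energy pulses
#' at the calibration energies, memoised per configuration and geometry.
#' This is the simulated analogue of the threshold-scan gain calibration.
#'
#' @param config A [shaper_config()].
#' @param geometry A [detector_geometry()].
#' @param energies Calibration energies, keV.
#' @param n_positions Interaction positions per energy.
#' @param seed Ensemble seed (the standard fixture uses 0).
#' @return Gain, mV/keV.
#' @export
channel_gain <- function(config, geometry = detector_geometry(),
                         energies = c(40, 60, 70, 80), n_positions = 20,
                         seed = 0) {
  key <- paste("gain", config$variant, config$tau0, config$B, config$tau_s,
               config$Cf, config$Cpz, config$Cs,
               geometry$wafer_thickness, geometry$bias_voltage,
               geometry$doping, geometry$temperature,
               paste(energies, collapse = ","), n_positions, seed, sep = "|")
  cache_get_or(key, function() {
    pulses <- simulate_pulse_ensemble(energies, geometry,
                                      n_positions = n_positions, seed = seed)
    as.numeric(gain(config, pulses))
  })
}

# standard mean current pulse (normalised shape) used by the counting and
# fitting modules: mean of a seeded full-energy ensemble at 60 keV
standard_mean_current <- function(geometry = detector_geometry(), seed = 0,
                                  n_positions = 32) {
  key <- paste("meanpulse", geometry$wafer_thickness, geometry$bias_voltage,
               geometry$doping, geometry$temperature, seed, n_positions,
               sep = "|")
  cache_get_or(key, function() {
    pulses <- simulate_pulse_ensemble(60, geometry, n_positions = n_positions,
                                      seed = seed)
    nmax <- max(vapply(pulses, function(p) length(p$samples), integer(1)))
    acc <- numeric(nmax)
    for (p in pulses) acc[seq_along(p$samples)] <-
      acc[seq_along(p$samples)] + p$samples
    current_pulse(acc / length(pulses), dt = pulses[[1]]$dt, energy = 60)
  })
}

# keV-calibrated normalized pulse shape (peak = 1) for a configuration;
# scaling by E gives the shaped pulse of an E-keV deposit in keV units.
standard_shape <- function(config, geometry = detector_geometry(), seed = 0) {
  key <- paste("shape", config$variant, config$tau0, config$B, config$tau_s,
               geometry$wafer_thickness, geometry$bias_voltage,
               geometry$doping, seed, sep = "|")
  cache_get_or(key, function() {
    cp <- standard_mean_current(geometry, seed = seed)
    v <- shape_pulse(cp, config)
    list(shape = v$samples / v$peak, dt = v$dt)
  })
}
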