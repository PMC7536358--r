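# Shared fixtures. Expensive reference calibrations (channel gains, the
# standard pulse shape, noise normalization) are memoised inside the package,
# so repeated use across test files is cheap.

geom_std <- detector_geometry()
field_std <- solve_field(geom_std)
src_std <- noise_sources()

cfg_ideal40 <- shaper_config("ideal", tau0 = 20)
cfg_proto_long <- shaper_config("prototype", tau0 = 19.6, B = 1)
cfg_proto_short <- shaper_config("prototype", tau0 = 19.6, B = 27.8 / 39.2)

# a point-like carrier cloud at a chosen drift-axis position (um), bypassing
# the interaction sampler
make_cloud <- function(x0_um, energy = 60, n = 500, geometry = geom_std) {
  cl <- sample_interaction(energy, geometry, seed = 1, n_carriers = n,
                           force = "photo")
  cl$x[] <- x0_um
  cl$y[] <- 0
  cl
}

# deterministic delta-like current pulse carrying the full charge of an
# energy deposit in one 2-ns bin
delta_current <- function(energy = 60, dt = 2) {
  q_fC <- energy * 1e3 / 3.6 * 1.602176634e-19 * 1e15
  current_pulse(c(q_fC / dt), dt = dt, energy = energy)
}

# monochromatic single-bin spectrum
mono_spectrum <- function(energy, kind = "incident") {
  energy_spectrum(energy, 1, kind)
}

# deadtimes that place the 2->1 transition inside the usable threshold
# window for a given configuration and beam energy, chosen from the model
# pulse shape (mirrors how the measurement campaign picked its deadtimes)
usable_deadtimes <- function(config, energy, fracs = c(0.35, 0.6),
                             clock = 10, geometry = geom_std) {
  sh <- pcdsim:::standard_shape(config, geometry)
  L <- pcdsim:::shape_lengths_at(sh$shape, fracs, sh$dt)
  td <- floor((L - clock / 2) / clock) * clock
  unique(td[td >= 20 & fracs * energy > 16])
}
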