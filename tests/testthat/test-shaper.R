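test_that("transfer function has the analytic DC gain and low-pass rolloff", {
  # DC: (1/Cf)(Cpz/Cs) * tau_s * 4  -> 3200 mV/uA for the ideal 20-ns config
  expect_equal(Mod(transfer_function(cfg_ideal40, 0)), 3200, tolerance = 1e-12)
  # prototype DC uses tau_s = 14 ns
  expect_equal(Mod(transfer_function(cfg_proto_long, 0)),
               (1 / 200e-15) * 8 * 14e-9 * 4 / 1e3, tolerance = 1e-12)
  # rolloff: three poles -> magnitude falls ~ f^-3 at high frequency
  hi <- Mod(transfer_function(cfg_proto_long, c(1e9, 1e10)))
  expect_lt(hi[2], hi[1] * 1e-2)
  expect_lt(hi[2] / Mod(transfer_function(cfg_proto_long, 0)), 1e-8)
  expect_error(shaper_config("ideal", tau0 = -5), class = "invalid_config")
  expect_error(shaper_config("prototype", 20, B = 0.3), class = "invalid_config")
})

test_that("CSA noise-shape integral matches the closed-form rational integral", {
  # int u^2/(1+u^2)^3 du = pi/16, checked against adaptive quadrature
  quad <- integrate(function(u) u^2 / (1 + u^2)^3, 0, Inf)$value
  expect_equal(quad, pi / 16, tolerance = 1e-8)
  # the white-noise CSA output variance of the ideal config then has the
  # closed form pref^2 * S_I / (2 tau0)
  src <- src_std
  tau0 <- 20e-9
  pref <- (1 / (src$Gf * 1e-3)) * (src$Cdet * 1e-12) / 200e-15 * 8
  S_I <- (src$i_csa_rms * 1e-6)^2 * 2 * 2e-9
  S_V <- (src$v_filter_rms * 1e-3)^2 * 2 * 2e-9
  raw <- pcdsim:::raw_component_variances(cfg_ideal40, src)
  expect_equal(raw[["csa"]], pref^2 * S_I / (2 * tau0), tolerance = 1e-3)
  # filter: int 16/(1+u^2)^2 du -> variance 2 S_V / tau0
  expect_equal(raw[["filter"]], 2 * S_V / tau0, tolerance = 1e-3)
})

test_that("pulse shaping is linear and maps zero to zero", {
  p1 <- simulate_current_pulse(60, geom_std, seed = 11, field = field_std)
  p2 <- simulate_current_pulse(40, geom_std, seed = 12, field = field_std)
  n <- max(length(p1$samples), length(p2$samples))
  pad <- function(p) c(p$samples, numeric(n - length(p$samples)))
  mix <- current_pulse(3 * pad(p1) - 0.5 * pad(p2), dt = 2)
  v_mix <- shape_pulse(mix, cfg_proto_long)$samples
  v1 <- shape_pulse(current_pulse(pad(p1), dt = 2), cfg_proto_long)$samples
  v2 <- shape_pulse(current_pulse(pad(p2), dt = 2), cfg_proto_long)$samples
  expect_equal(v_mix, 3 * v1 - 0.5 * v2, tolerance = 1e-10)
  zero <- shape_pulse(current_pulse(numeric(16), dt = 2), cfg_ideal40)
  expect_true(all(zero$samples == 0))
})

test_that("ideal-model impulse peak is invariant under the shaping time", {
  peaks <- vapply(c(20, 50, 100), function(t0) {
    shape_pulse(delta_current(60), shaper_config("ideal", t0))$peak
  }, numeric(1))
  expect_lt(diff(range(peaks)) / mean(peaks), 0.05)
})

test_that("transfer function matches its closed formula and pole structure", {
  # prototype: tau1 = B tau0, tau2 = 2 B tau0, tau_s fixed; the comparator
  # load keeps the second stage twice as slow even at B = 1, so the long
  # setting does not collapse onto the ideal channel
  proto <- shaper_config("prototype", 20, B = 0.7, tau_s = 14)
  expect_equal(proto$tau1, 14)
  expect_equal(proto$tau2, 28)
  f <- 10^seq(4, 9, 0.5)
  s <- 2i * pi * f
  href <- function(ts, t1, t2)
    (1 / 200e-15) * 8 * (ts / (1 + s * ts)) * (2 / (1 + s * t1)) *
      (2 / (1 + s * t2)) / 1e3
  expect_equal(transfer_function(proto, f),
               href(14e-9, 14e-9, 28e-9), tolerance = 1e-12)
  expect_equal(transfer_function(cfg_ideal40, f),
               href(20e-9, 20e-9, 20e-9), tolerance = 1e-12)
})

test_that("gain is the peak-vs-energy slope, linear in amplitude", {
  pulses <- simulate_pulse_ensemble(c(40, 60, 80), geom_std,
                                    n_positions = 6, seed = 2)
  g1 <- gain(cfg_ideal40, pulses)
  doubled <- lapply(pulses, function(p)
    current_pulse(2 * p$samples, p$dt, p$energy))
  g2 <- gain(cfg_ideal40, doubled)
  expect_equal(as.numeric(g2), 2 * as.numeric(g1), tolerance = 1e-6)
  expect_gt(as.numeric(g1), 0)
  # singular fit: a single energy
  expect_error(gain(cfg_ideal40, pulses[1:6]), class = "fit_error")
  # prototype long setting has lower gain than short
  expect_lt(channel_gain(cfg_proto_long, geom_std),
            channel_gain(cfg_proto_short, geom_std))
})

test_that("pulse length interpolates crossings and is monotone", {
  v <- shape_pulse(delta_current(100), cfg_ideal40)
  # threshold at/above peak -> 0 with flag
  l0 <- pulse_length(v, v$peak)
  expect_equal(as.numeric(l0), 0)
  expect_false(attr(l0, "crossed"))
  thr <- seq(0.05, 0.95, 0.05) * v$peak
  L <- vapply(thr, function(t) as.numeric(pulse_length(v, t)), numeric(1))
  expect_true(all(diff(L) < 0))         # decreasing in threshold
  # increasing in shaping time at fixed relative threshold
  L_tau <- vapply(c(40, 100, 200), function(tau) {
    vv <- shape_pulse(delta_current(100), shaper_config("ideal", tau / 2))
    as.numeric(pulse_length(vv, 0.08 * vv$peak))
  }, numeric(1))
  expect_true(all(diff(L_tau) > 0))
})

test_that("shaped pulses decay below 1% of peak inside the padded window", {
  for (tau in c(40, 200, 500)) {
    v <- shape_pulse(delta_current(60), shaper_config("ideal", tau / 2))
    expect_lt(abs(v$samples[length(v$samples)]), 0.01 * v$peak)
  }
})

test_that("bandpass numerator flag AC-couples the response", {
  f <- 10^seq(4, 9, 0.25)
  lp <- transfer_function(cfg_ideal40, c(0, f))
  bp <- transfer_function(cfg_ideal40, c(0, f), numerator = "bandpass")
  expect_equal(Mod(bp[1]), 0)           # no DC transmission
  expect_gt(Mod(lp[1]), 0)
})
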