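test_that("comparator bank validates its invariants", {
  expect_error(comparator_bank(c(10, 5), deadtime_ns = 40),
               class = "invalid_config")
  expect_error(comparator_bank(5, clock_ns = 10, deadtime_ns = 45),
               class = "invalid_config")
  expect_error(comparator_bank(1:9, deadtime_ns = 40),
               class = "invalid_config")
})

test_that("an empty frame registers nothing; a single pulse lands in its bin", {
  bank <- comparator_bank(c(5, 30, 50, 70), deadtime_ns = 300)
  expect_equal(sum(count_frame(numeric(5000), bank, seed = 1)), 0)
  sh <- pcdsim:::standard_shape(cfg_ideal40, geom_std)
  wav <- c(numeric(100), 60 * sh$shape, numeric(400))
  cts <- count_frame(wav, bank, dt = sh$dt, seed = 2)
  expect_equal(as.integer(cts), c(0L, 0L, 1L, 0L))
})

test_that("a pulse longer than the deadtime is double counted", {
  sh <- pcdsim:::standard_shape(cfg_ideal40, geom_std)
  v <- 60 * sh$shape
  L <- as.numeric(pulse_length(v, 30, dt = sh$dt))
  expect_gt(L, 50)                       # ~76 ns at half the peak
  bank <- comparator_bank(30, deadtime_ns = 40)   # tau_d + tau_c < L < 2 tau_d
  for (ph in c(0, 3, 7)) {
    cts <- count_frame(c(numeric(50), v, numeric(200)), bank, dt = sh$dt,
                       phase = ph)
    expect_equal(sum(cts), 2)
  }
})

test_that("threshold scans plateau at 1 for long deadtimes and match the pulse-length oracle", {
  scan <- simulate_threshold_scan(60, 300, cfg_ideal40, n_pulses = 400,
                                  seed = 4)[[1]]
  nn <- normalized_counts(scan)
  mid <- scan$threshold_keV >= 16 & scan$threshold_keV <= 50
  expect_true(all(nn[mid] == 1))
  # counts -> 0 above the beam energy
  expect_true(all(nn[scan$threshold_keV > 62] == 0))
  # 2 vs 1 structure against the waveform oracle (away from the transition)
  td <- 70
  scan2 <- simulate_threshold_scan(60, td, cfg_ideal40, n_pulses = 600,
                                   seed = 5)[[1]]
  sh <- pcdsim:::standard_shape(cfg_ideal40, geom_std)
  nn2 <- normalized_counts(scan2)
  for (i in which(scan2$threshold_keV >= 16 & scan2$threshold_keV <= 55)) {
    L <- as.numeric(pulse_length(60 * sh$shape, scan2$threshold_keV[i],
                                 dt = sh$dt))
    if (L > td + 12) expect_equal(nn2[i], 2)
    if (L < td - 2 && L > 0) expect_equal(nn2[i], 1)
  }
})

test_that("fast and frame scan backends agree", {
  thr <- seq(16, 60, 1)
  a <- simulate_threshold_scan(60, 70, cfg_ideal40, thresholds = thr,
                               n_pulses = 1500, seed = 9)[[1]]
  b <- simulate_threshold_scan(60, 70, cfg_ideal40, thresholds = thr,
                               n_pulses = 1500, seed = 9,
                               method = "frame")[[1]]
  expect_lt(max(abs(normalized_counts(a) - normalized_counts(b))), 0.2)
  expect_lt(abs(extract_e_half(a) - extract_e_half(b)), 1)
})

test_that("thresholds in the noise floor trigger far more than twice", {
  scan <- simulate_threshold_scan(60, 70, cfg_ideal40,
                                  thresholds = seq(2, 30, 1), n_pulses = 300,
                                  seed = 3, method = "frame",
                                  sources = src_std)[[1]]
  nn <- normalized_counts(scan)
  expect_gt(nn[scan$threshold_keV == 3], 2)
})

test_that("E1/2 extraction is exact on a synthetic step and monotone in deadtime", {
  thr <- seq(16, 50, 0.5)
  counts <- ifelse(thr < 30, 2, ifelse(thr > 30, 1, 1.5)) * 500
  step <- structure(data.frame(threshold_keV = thr, counts = counts),
                    n_pulses = 500, class = c("threshold_scan", "data.frame"))
  expect_equal(extract_e_half(step), 30, tolerance = 1e-9)
  # no transition -> extraction error
  flat <- structure(data.frame(threshold_keV = thr, counts = rep(500, length(thr))),
                    n_pulses = 500, class = c("threshold_scan", "data.frame"))
  expect_error(extract_e_half(flat), class = "extraction_error")
  scans <- simulate_threshold_scan(60, c(80, 60), cfg_ideal40,
                                   n_pulses = 2000, seed = 6)
  e80 <- extract_e_half(scans[[1]])
  e60 <- extract_e_half(scans[[2]])
  expect_gt(e60, e80)                    # shorter deadtime -> higher E1/2
})

test_that("E1/2 identity: pulse length at E1/2 equals deadtime + half a clock", {
  sh <- pcdsim:::standard_shape(cfg_ideal40, geom_std)
  for (td in c(60, 80)) {
    scan <- simulate_threshold_scan(60, td, cfg_ideal40, n_pulses = 4000,
                                    seed = td)[[1]]
    eh <- extract_e_half(scan)
    L <- as.numeric(pulse_length(60 * sh$shape, eh, dt = sh$dt))
    expect_lt(abs(L - (td + 5)), 5)
  }
})

test_that("registered spectrum equals the input histogram for separated pulses", {
  energies <- rep(c(20, 40, 60, 90, 35, 75), 3)
  bank <- comparator_bank(c(5, 30, 50, 70), deadtime_ns = 500)
  sh <- pcdsim:::standard_shape(cfg_ideal40, geom_std)
  gap <- 5000                            # samples between pulse starts: 10 us
  wav <- numeric(gap * (length(energies) + 1))
  for (j in seq_along(energies)) {
    rng <- ((j - 1) * gap + 1):((j - 1) * gap + length(sh$shape))
    wav[rng] <- wav[rng] + energies[j] * sh$shape
  }
  cts <- count_frame(wav, bank, dt = sh$dt, seed = 13)
  expected <- tabulate(findInterval(energies, c(5, 30, 50, 70)), 4)
  expect_equal(as.integer(cts), expected)
})

test_that("hard deadtime bound limits counts per frame", {
  # saturated channel: waveform always above threshold
  bank <- comparator_bank(5, deadtime_ns = 100)
  wav <- rep(50, 75000)                  # 150 us at 2 ns
  cts <- sum(count_frame(wav, bank, dt = 2, seed = 14))
  expect_lte(cts, ceiling(150e3 / 100) + 1)
  expect_gte(cts, floor(150e3 / 100) - 1)
})

test_that("count-rate curves rise, saturate below the deadtime bound, and start at the dose efficiency", {
  dep <- detector_response(tube_spectrum(beam_config()), geom_std,
                           n_photons = 2e5, seed = 21)
  setup <- deadtime_for(40, src_std, geom_std)
  crc <- count_rate_curve(c(5e5, 5e6, 2e7, 6e7), 40, dep, n_frames = 12,
                          seed = 22, sources = src_std, geometry = geom_std)
  expect_true(all(diff(crc$output_rate) > 0))
  expect_lt(max(crc$output_rate), 1 / (setup$deadtime_ns * 1e-9))
  eff <- dose_efficiency(dep, setup$threshold_keV)
  expect_lt(abs(crc$output_rate[1] / crc$input_rate[1] - eff), 0.06)
})

test_that("the 40-ns channel saturates at a higher rate than 200 ns", {
  dep <- detector_response(tube_spectrum(beam_config()), geom_std,
                           n_photons = 1e5, seed = 23)
  hi <- 4e7
  r40 <- count_rate_curve(hi, 40, dep, n_frames = 6, seed = 24,
                          geometry = geom_std)
  r200 <- count_rate_curve(hi, 200, dep, n_frames = 6, seed = 24,
                           geometry = geom_std)
  expect_gt(r40$output_rate, r200$output_rate)
})

test_that("deadtime_for reproduces the threshold scaling", {
  s40 <- deadtime_for(40, src_std, geom_std)
  expect_equal(s40$threshold_keV, 8, tolerance = 1e-6)
  sig100 <- sigma_total(ideal_config_at_test <- shaper_config("ideal", 50),
                        src_std, geometry = geom_std)[["sigma_keV"]]
  s100 <- deadtime_for(100, src_std, geom_std)
  expect_equal(s100$threshold_keV, 4 * sig100, tolerance = 1e-9)
  expect_equal(s40$deadtime_ns %% 10, 0)
  expect_gte(s40$deadtime_ns, s40$pulse_length_ns)
})
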