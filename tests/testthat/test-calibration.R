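erfc_counts <- function(x, mu, sigma, amp = 1) {
  amp * 0.5 * (2 * pnorm(-sqrt(2) * (x - mu) / (sqrt(2) * sigma)))
}

test_that("erfc fit recovers a noise-free S-curve to < 0.1%", {
  x <- seq(10, 50, 0.5)
  d <- data.frame(threshold_keV = x, counts = erfc_counts(x, 30, 2))
  f <- fit_erfc(d, exclude_below = 0)
  expect_lt(abs(coef(f)[["mu"]] / 30 - 1), 1e-3)
  expect_lt(abs(coef(f)[["sigma"]] / 2 - 1), 1e-3)
  expect_equal(predict(f, 30), erfc_counts(30, 30, 2), tolerance = 1e-3)
})

test_that("erfc fit recovers parameters from Poisson-noisy scans within 3 SE", {
  x <- seq(20, 100, 1)
  n <- 1e4
  for (s in 0:2) {
    set.seed(s)
    y <- rpois(length(x), n * erfc_counts(x, 60, 2.3)) / n
    f <- fit_erfc(data.frame(threshold_keV = x, counts = y),
                  exclude_below = 0)
    se <- sqrt(diag(vcov(f)))
    expect_lt(abs(coef(f)[["mu"]] - 60), 3 * se[["mu"]] + 1e-6)
    expect_lt(abs(coef(f)[["sigma"]] - 2.3), 3 * se[["sigma"]] + 1e-6)
  }
})

test_that("degenerate erfc inputs error", {
  x <- seq(10, 50, 1)
  expect_error(fit_erfc(data.frame(threshold_keV = x,
                                   counts = rep(0, length(x))),
                        exclude_below = 0), class = "fit_error")
  expect_error(fit_erfc(data.frame(threshold_keV = 1:5, counts = 1:5),
                        exclude_below = 0), class = "fit_error")
})

test_that("gain calibration is the mu-vs-energy slope with unit invariance", {
  en <- c(0, 40, 60, 70, 80)
  mus <- 1.45 * en
  mus[1] <- 0
  d <- data.frame(mu = mus, sigma = c(3.99, 2, 2, 2, 2))
  cal <- calibrate_gain(d, en)
  expect_equal(cal$gain, 1.45, tolerance = 1e-9)
  expect_equal(cal$sigma_mV, 3.99)
  expect_equal(cal$sigma_keV, 3.99 / 1.45, tolerance = 1e-9)
  # scaling mu and sigma by 2 doubles the gain, sigma_keV unchanged
  d2 <- data.frame(mu = 2 * mus, sigma = 2 * d$sigma)
  cal2 <- calibrate_gain(d2, en)
  expect_equal(cal2$gain, 2.9, tolerance = 1e-9)
  expect_equal(cal2$sigma_keV, cal$sigma_keV, tolerance = 1e-9)
  expect_error(calibrate_gain(d[1:2, ], en[1:2]), class = "fit_error")
})

test_that("shape-parameter grid search round-trips and equals the brute-force minimum", {
  tau0_true <- 22.3
  B_true <- 0.66
  rows <- list()
  set.seed(40)
  for (setting in c("long", "short")) {
    cc <- shaper_config("prototype", tau0_true,
                        B = if (setting == "long") 1 else B_true)
    for (E in c(40, 60, 70, 80)) {
      for (td in usable_deadtimes(cc, E)) {
        sc <- simulate_threshold_scan(E, td, cc, n_pulses = 2000,
                                      seed = round(E + td))[[1]]
        eh <- tryCatch(extract_e_half(sc), error = function(e) NA_real_)
        if (is.finite(eh))
          rows[[length(rows) + 1L]] <- data.frame(
            energy = E, deadtime_ns = td, e_half_keV = eh, setting = setting)
      }
    }
  }
  meas <- do.call(rbind, rows)
  expect_gte(nrow(meas), 8)
  fit <- fit_shape_params(meas, keep_surface = TRUE)
  expect_lte(abs(fit$tau0 - tau0_true), 0.1 + 1e-9)
  expect_lte(abs(fit$B_short - B_true), 0.01 + 1e-9)
  # reported minimum is the brute-force minimum of the full surface
  expect_equal(fit$mse, min(fit$mse_surface))
  ij <- which(fit$mse_surface == fit$mse, arr.ind = TRUE)[1, ]
  expect_equal(fit$tau0_grid[ij[1]], fit$tau0)
  expect_equal(fit$B_grid[ij[2]], fit$B_short)
  expect_equal(fit$tau_long, 2 * fit$tau0)
  expect_equal(fit$tau_short, 2 * fit$B_short * fit$tau0)
})

test_that("shape fit validates its inputs", {
  expect_error(fit_shape_params(data.frame()), class = "fit_error")
  few <- data.frame(energy = 60, deadtime_ns = 70, e_half_keV = 25,
                    setting = "long")
  expect_error(fit_shape_params(few), class = "fit_error")
})
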