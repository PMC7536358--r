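#' Modified complementary error-function fit to a threshold scan
#'
#' Fits the six-parameter model
#' \deqn{f(x) = \tfrac12\,\mathrm{erfc}\!\left(\frac{x-\mu}{\sqrt2\,\sigma}\right)
#'   \left(A_1 (x-\mu) + A_2\right) + A_3 (x-\mu) + A_4}
#' to counts versus threshold by least squares
#' (Levenberg-Marquardt, multi-start). `mu` locates the S-curve transition
#' (the pulse height) and `sigma` its width (the noise); `A1`-`A4` absorb
#' slope and background. Thresholds below the noise/triple-count exclusion
#' region are dropped before fitting.
#'
#' @param scan A `threshold_scan`, or a data.frame with columns
#'   `threshold_keV` (or `x`) and `counts` (raw or normalized).
#' @param initial Optional named list/vector of starting values
#'   (`mu`, `sigma`, `A1`..`A4`).
#' @param exclude_below Exclusion threshold in the x units (default 15; use
#'   0 for noise-only scans).
#' @param normalize Divide counts by the `n_pulses` attribute when present.
#' @return An object of class `erfc_fit` with `coefficients`, `vcov`,
#'   `fitted`, `residuals`, `data`.
#' @export
fit_erfc <- function(scan, initial = NULL, exclude_below = 15,
                     normalize = TRUE) {
  x <- if (!is.null(scan$threshold_keV)) scan$threshold_keV else scan$x
  y <- scan$counts
  if (normalize && !is.null(attr(scan, "n_pulses")))
    y <- y / attr(scan, "n_pulses")
  keep <- x >= exclude_below & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10L)
    stop_pcd("scan must have at least 10 points spanning the transition",
             "fit_error")
  if (all(y == 0))
    stop_pcd("all-zero counts: nothing to fit", "fit_error")
  erfc <- function(z) 2 * stats::pnorm(-sqrt(2) * z)
  model <- function(x, mu, sigma, A1, A2, A3, A4)
    0.5 * erfc((x - mu) / (sqrt(2) * sigma)) * (A1 * (x - mu) + A2) +
      A3 * (x - mu) + A4
  # data-driven start: mu where y first drops below half its early plateau
  plateau <- stats::median(y[seq_len(max(3L, length(y) %/% 4L))])
  half_idx <- which(y < plateau / 2)
  mu0 <- if (length(half_idx)) x[half_idx[1]] else stats::median(x)
  starts <- list(
    c(mu = mu0, sigma = 2, A1 = 0, A2 = plateau, A3 = 0, A4 = 0),
    c(mu = stats::median(x), sigma = 3, A1 = 0, A2 = max(y), A3 = 0, A4 = 0))
  if (!is.null(initial)) starts <- c(list(unlist(initial)), starts)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model(x, mu, sigma, A1, A2, A3, A4),
        start = as.list(st),
        lower = c(mu = min(x), sigma = 1e-3, A1 = -Inf, A2 = -Inf,
                  A3 = -Inf, A4 = -Inf),
        upper = c(mu = max(x), sigma = diff(range(x)), A1 = Inf, A2 = Inf,
                  A3 = Inf, A4 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop_pcd("erfc fit did not converge from any start", "fit_error")
  fit <- best$fit
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 6, 6))
  structure(list(coefficients = co, vcov = vc,
                 fitted = stats::fitted(fit), residuals = stats::residuals(fit),
                 data = data.frame(x = x, y = y), rss = best$rss),
            class = "erfc_fit")
}

#' @export
coef.erfc_fit <- function(object, ...) object$coefficients

#' @export
vcov.erfc_fit <- function(object, ...) object$vcov

#' @export
residuals.erfc_fit <- function(object, ...) object$residuals

#' @export
print.erfc_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<erfc_fit: mu = %.3f, sigma = %.3f (rss %.4g)>\n",
              co[["mu"]], co[["sigma"]], x$rss))
  invisible(x)
}

#' @export
summary.erfc_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  out <- data.frame(estimate = object$coefficients, std_error = se)
  cat("Modified complementary error-function fit\n")
  print(out)
  invisible(out)
}

#' @export
predict.erfc_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  co <- as.list(object$coefficients)
  erfc <- function(z) 2 * stats::pnorm(-sqrt(2) * z)
  0.5 * erfc((x - co$mu) / (sqrt(2) * co$sigma)) *
    (co$A1 * (x - co$mu) + co$A2) + co$A3 * (x - co$mu) + co$A4
}

#' Gain and noise calibration from erfc fits
#'
#' The channel gain is the slope of a linear regression of the fitted
#' transition centers `mu` (mV or DAC) on the beam energies; the calibrated
#' noise is the `sigma` of the noise-only fit (energy 0) divided by the
#' gain.
#'
#' @param fits List of [fit_erfc()] results (or a data.frame with columns
#'   `mu` and `sigma`).
#' @param energies Beam energy per fit, keV; 0 marks the noise-only scan.
#' @return List of class `gain_calibration`: `gain` (mV/keV), `sigma_mV`,
#'   `sigma_keV`, and the regression `fit`.
#' @export
calibrate_gain <- function(fits, energies) {
  if (is.data.frame(fits)) {
    mu <- fits$mu; sg <- fits$sigma
  } else {
    mu <- vapply(fits, function(f) coef(f)[["mu"]], numeric(1))
    sg <- vapply(fits, function(f) coef(f)[["sigma"]], numeric(1))
  }
  if (length(mu) != length(energies))
    stop_pcd("one energy per fit required", "fit_error")
  beam <- energies > 0
  if (length(unique(energies[beam])) < 2L)
    stop_pcd("gain calibration needs at least two distinct beam energies",
             "fit_error")
  reg <- stats::lm(mu[beam] ~ energies[beam])
  g <- unname(stats::coef(reg)[2])
  sigma_mV <- if (any(!beam)) mean(sg[!beam]) else NA_real_
  structure(list(gain = g, sigma_mV = sigma_mV,
                 sigma_keV = sigma_mV / g, fit = reg),
            class = "gain_calibration")
}

#' @export
print.gain_calibration <- function(x, ...) {
  cat(sprintf("<gain_calibration: gain %.3f mV/keV, sigma %.3f mV = %.3f keV>\n",
              x$gain, x$sigma_mV, x$sigma_keV))
  invisible(x)
}

#' Grid-search recovery of shaper time constants from pulse lengths
#'
#' Recovers the prototype filter time constant `tau0` and the short-setting
#' scale factor `B_short` from measured pulse lengths. Each measurement is
#' one (energy, deadtime, E1/2, setting) record: at threshold E1/2 the
#' pulse length equals `deadtime + clock/2`. For every candidate
#' `(tau0, B_short)` on the exhaustive grid, the shaped pulse of the fixed
#' seeded charge-transport ensemble is computed for the long (`B = 1`) and
#' short (`B = B_short`) settings and its length at each record's E1/2
#' threshold is compared to the measured length; the candidate minimizing
#' the unweighted mean squared error wins (ties towards smaller `tau0`).
#'
#' @param measured data.frame with columns `energy` (keV), `deadtime_ns`,
#'   `e_half_keV`, `setting` (`"long"` or `"short"`).
#' @param config_template A prototype [shaper_config()] supplying `tau_s`
#'   and the capacitances.
#' @param tau0_grid,B_grid Search grids, ns / dimensionless.
#' @param geometry A [detector_geometry()] for the pulse ensemble.
#' @param seed Ensemble seed (shared across candidates and modules).
#' @param clock_ns Clock period, ns.
#' @param keep_surface Return the full MSE matrix.
#' @return An object of class `shape_fit`: `tau0`, `B_short`, `tau_long`,
#'   `tau_short`, `mse`, grids, optionally `mse_surface`.
#' @export
fit_shape_params <- function(measured,
                             config_template = shaper_config("prototype", 20),
                             tau0_grid = seq(10, 30, by = 0.1),
                             B_grid = seq(0.5, 0.99, by = 0.01),
                             geometry = detector_geometry(), seed = 0,
                             clock_ns = 10, keep_surface = FALSE) {
  req <- c("energy", "deadtime_ns", "e_half_keV", "setting")
  if (!is.data.frame(measured) || !all(req %in% names(measured)) ||
      nrow(measured) == 0L)
    stop_pcd("measured must be a non-empty data.frame with energy, deadtime_ns, e_half_keV, setting",
             "fit_error")
  if (nrow(measured) < 4L)
    stop_pcd("at least 4 (energy, deadtime) pairs are required", "fit_error")
  cp <- standard_mean_current(geometry, seed = seed)
  dt <- cp$dt
  # one FFT of the input current, reused for every candidate
  tau_max <- 2 * max(tau0_grid)
  n <- 2^ceiling(log2(length(cp$samples) + 25 * tau_max / dt))
  x <- numeric(n); x[seq_along(cp$samples)] <- cp$samples
  Xf <- stats::fft(x)
  f <- c(0:(n / 2), -(n / 2 - 1):-1) / (n * dt * 1e-9)
  L_meas <- measured$deadtime_ns + clock_ns / 2
  frac <- measured$e_half_keV / measured$energy   # threshold as peak fraction
  is_long <- measured$setting == "long"
  lengths_for <- function(tau0, B) {
    cfg <- shaper_config("prototype", tau0, B = B,
                         tau_s = config_template$tau_s,
                         Cf = config_template$Cf, Cpz = config_template$Cpz,
                         Cs = config_template$Cs)
    H <- transfer_function(cfg, f)
    v <- Re(stats::fft(Xf * H, inverse = TRUE)) / n
    shape_lengths_at(v, frac, dt)
  }
  mse_surface <- matrix(NA_real_, length(tau0_grid), length(B_grid))
  for (i in seq_along(tau0_grid)) {
    Ll <- if (any(is_long)) lengths_for(tau0_grid[i], 1) else NULL
    for (j in seq_along(B_grid)) {
      Ls <- if (any(!is_long)) lengths_for(tau0_grid[i], B_grid[j]) else NULL
      sim <- numeric(nrow(measured))
      if (any(is_long)) sim[is_long] <- Ll[is_long]
      if (any(!is_long)) sim[!is_long] <- Ls[!is_long]
      mse_surface[i, j] <- mean((sim - L_meas)^2)
    }
  }
  # ties broken towards smaller tau0 (row-major scan order guarantees it)
  best <- which(mse_surface == min(mse_surface), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  tau0 <- tau0_grid[best[1]]
  Bs <- B_grid[best[2]]
  structure(list(tau0 = tau0, B_short = Bs,
                 tau_long = 2 * tau0, tau_short = 2 * Bs * tau0,
                 mse = min(mse_surface),
                 tau0_grid = tau0_grid, B_grid = B_grid,
                 mse_surface = if (keep_surface) mse_surface else NULL,
                 n_records = nrow(measured)),
            class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf(
    "<shape_fit: tau0 = %.1f ns, B_short = %.2f  (tau_long %.1f / tau_short %.1f ns), mse %.3g ns^2>\n",
    x$tau0, x$B_short, x$tau_long, x$tau_short, x$mse))
  invisible(x)
}

#' @export
coef.shape_fit <- function(object, ...) {
  c(tau0 = object$tau0, B_short = object$B_short)
}
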