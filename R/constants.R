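# Physical constants (CGS-ish mixed units used internally; user-facing units
# are keV, ns, mV, uA, fF, pF, mS, cm^-3 throughout the package).

.const <- list(
  e_C        = 1.602176634e-19,  # elementary charge, C
  kB_JK      = 1.380649e-23,     # Boltzmann constant, J/K
  eps_si     = 11.7 * 8.8541878128e-14,  # permittivity of silicon, F/cm
  w_pair_eV  = 3.6,              # mean energy per electron-hole pair in Si, eV
  mec2_keV   = 510.99895,        # electron rest energy, keV
  mu_e       = 1350,             # electron low-field mobility, cm^2/Vs (300 K)
  mu_h       = 480,              # hole low-field mobility, cm^2/Vs (300 K)
  vsat_e     = 1.02e7,           # electron saturation velocity, cm/s
  vsat_h     = 8.37e6            # hole saturation velocity, cm/s
)

# charge generated by a deposit, in fC (1 uA * 1 ns = 1 fC)
energy_to_charge_fC <- function(energy_keV) {
  energy_keV * 1e3 / .const$w_pair_eV * .const$e_C * 1e15
}

# Run an expression with a local RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# package-local cache for expensive deterministic intermediates
# (reference gains, noise normalization constants)
.pcd_cache <- new.env(parent = emptyenv())

#' Clear cached reference calibrations
#'
#' Reference channel gains and noise-normalization constants are computed on
#' first use (from seeded pulse ensembles) and memoised. Clearing is only
#' needed after changing code or when benchmarking cold starts.
#' @return Invisibly, the number of entries removed.
#' @export
pcd_cache_clear <- function() {
  n <- length(ls(.pcd_cache))
  rm(list = ls(.pcd_cache), envir = .pcd_cache)
  invisible(n)
}

cache_get_or <- function(key, compute) {
  if (!exists(key, envir = .pcd_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .pcd_cache)
  }
  get(key, envir = .pcd_cache, inherits = FALSE)
}

stop_pcd <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pcdsim_error")))
}
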