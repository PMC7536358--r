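test_that("field solver reproduces the closed-form over-depleted solution", {
  fd <- solve_field(geom_std, n_nodes = 501)
  an <- solve_field(geom_std, method = "analytic", n_nodes = 501)
  expect_lt(max(abs(fd$E - an$E) / an$E), 1e-3)
  expect_lt(max(abs(fd$phi - an$phi)) / 400, 1e-3)
  # exact boundary potentials
  expect_equal(fd$phi[1], 0)
  expect_equal(fd$phi[length(fd$phi)], 400)
  # junction-side collection: field at the strip exceeds the backside field
  expect_gt(fd$E[1], fd$E[length(fd$E)])
  # Laplace limit: doping -> 0 gives the uniform field V/d
  g0 <- detector_geometry(doping = 1)
  f0 <- solve_field(g0)
  expect_equal(f0$E, rep(400 / 0.05, length(f0$E)), tolerance = 1e-6)
})

test_that("depletion is enforced", {
  expect_gt(depletion_voltage(geom_std), 80)
  expect_lt(depletion_voltage(geom_std), 95)
  expect_error(detector_geometry(bias_voltage = 50), class = "depletion_error")
})

test_that("zero mobility-equivalent and zero diffusion leave positions unchanged", {
  zero_field <- list(x = field_std$x, E = rep(0, length(field_std$x)))
  pos <- list(x = rep(250, 100), y = rep(0, 100))
  st <- transport_step(pos, "electron", zero_field, dt = 2, geom_std,
                       diffuse = FALSE)
  expect_equal(st$x, pos$x)
  expect_equal(st$y, pos$y)
})

test_that("diffusion displacements have the analytic variance and are Gaussian", {
  set.seed(7)
  zero_field <- list(x = field_std$x, E = rep(0, length(field_std$x)))
  n <- 1e4
  pos <- list(x = rep(250, n), y = rep(0, n))
  nstep <- 5
  dt <- 2
  for (k in seq_len(nstep))
    pos <- transport_step(pos, "electron", zero_field, dt = dt, geom_std)
  D <- 1.380649e-23 * 300 * 1350 / 1.602176634e-19        # cm^2/s
  var_exp <- 2 * D * nstep * dt * 1e-9 * 1e8              # um^2
  expect_lt(abs(var(pos$x - 250) / var_exp - 1), 0.05)
  expect_lt(abs(var(pos$y) / var_exp - 1), 0.05)
  # normality at ensemble size 1e4 (null fully specified)
  ks <- ks.test(pos$y, "pnorm", 0, sqrt(var_exp))
  expect_gt(ks$p.value, 0.01)
})

test_that("drift collection time matches the constant-field estimate", {
  # electron from mid-thickness, fine time step to resolve the transit
  cl <- make_cloud(250, n = 1)
  dt <- 0.05
  pos <- list(x = cl$x, y = cl$y)
  t_c <- 0
  repeat {
    st <- transport_step(pos, "electron", field_std, dt = dt, geom_std,
                         diffuse = FALSE)
    t_c <- t_c + dt
    pos <- st
    if (all(st$collected)) break
  }
  Ebar <- mean(pcdsim:::field_at(field_std, seq(250, 500, 5)))
  t_analytic <- (250e-4 / (1350 * Ebar)) * 1e9            # ns
  expect_lt(abs(t_c / t_analytic - 1), 0.10)
})

test_that("Ramo charge conservation holds exactly for completed trajectories", {
  for (x0 in c(50, 250, 450)) {
    cl <- make_cloud(x0)
    tr <- drift_cloud(cl, field_std, seed = 3)
    ip <- induced_current(tr)
    q_tot <- sum(cl$weight_fC)
    expect_equal(sum(ip$samples) * ip$dt, q_tot, tolerance = 1e-9)
  }
})

test_that("stationary carriers induce no current; a full-thickness electron induces e", {
  zero_field <- list(x = field_std$x, E = rep(0, length(field_std$x)))
  cl <- make_cloud(250, n = 10)
  tr <- drift_cloud(cl, structure(list(x = zero_field$x, E = zero_field$E),
                                  class = "drift_field"),
                    diffuse = FALSE, max_steps = 20)
  expect_true(all(abs(induced_current(tr, geom_std)$samples) < 1e-12))
  # cloud at the strip: holes collected instantly, electrons drift the full
  # thickness; the induced charge equals the whole generated charge once
  cl0 <- make_cloud(0)
  tr0 <- drift_cloud(cl0, field_std, diffuse = FALSE)
  expect_equal(sum(induced_current(tr0)$samples) * 2, sum(cl0$weight_fC),
               tolerance = 1e-9)
})

test_that("current pulse durations are bounded by the analytic drift times", {
  # slowest carrier: a hole crossing the full thickness at the weakest field
  E_min <- min(field_std$E)
  t_hole_max <- (500e-4 / (480 * E_min)) * 1e9            # ns
  for (s in 1:5) {
    ip <- simulate_current_pulse(60, geom_std, seed = 20 + s, field = field_std)
    dur <- sum(ip$samples > 0.01 * max(ip$samples)) * ip$dt
    expect_gte(dur, 2)
    expect_lte(dur, t_hole_max + 3 * ip$dt)
  }
})

test_that("pulse duration decreases with bias voltage", {
  durs <- vapply(c(200, 400, 600), function(V) {
    g <- detector_geometry(bias_voltage = V)
    f <- solve_field(g)
    cl <- make_cloud(400, geometry = g)
    tr <- drift_cloud(cl, f, dt = 0.5, diffuse = FALSE)
    ip <- induced_current(tr)
    sum(ip$samples > 0.01 * max(ip$samples)) * ip$dt
  }, numeric(1))
  expect_true(all(diff(durs) < 0))
})

test_that("interaction sampling respects cross sections and kinematics", {
  expect_error(sample_interaction(0.5, geom_std), class = "domain_error")
  expect_error(sample_interaction(200, geom_std), class = "domain_error")
  # Compton fraction at 120 keV from the cross-section tables
  mu <- pcdsim:::si_interaction_mu(120)
  frac_table <- mu$incoh / (mu$photo + mu$incoh)
  expect_gt(frac_table, 0.5)
  set.seed(5)
  types <- replicate(400, sample_interaction(120, geom_std)$type)
  expect_lt(abs(mean(types == "compton") - frac_table), 0.08)
  # deposits never exceed the incident energy; Compton deposits are capped
  # by the Compton edge
  set.seed(6)
  dep <- pcdsim:::sample_kn_deposit(rep(120, 2e4))
  edge <- compton_edge(120)
  expect_lt(max(dep), edge + 1e-9)
  expect_gt(max(dep), edge - 1.5)       # the edge is approached
  expect_equal(edge, 2 * 120^2 / (510.99895 + 2 * 120), tolerance = 1e-12)
  cl <- sample_interaction(80, geom_std, seed = 8)
  expect_lte(cl$energy, 80)
})
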