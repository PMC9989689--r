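test_that("gastric emptying vanishes at t = 0, scales with dose, and conserves mass", {
  meal <- meal_spec(75000)
  expect_equal(gastric_emptying_rate(0, meal, 0.0105, 1.34), 0)
  expect_equal(gastric_emptying_rate(c(0, 30, 90), meal_spec(0), 0.0105, 1.34),
               c(0, 0, 0))
  expect_error(gastric_emptying_rate(-1, meal, 0.0105, 1.34), "negative")
  expect_error(gastric_emptying_rate(10, meal, 0.0105, 0.9), "sigma")
  # quadrature oracle: the Weibull density integrates to 1, so the
  # emptied mass over a long horizon equals the dose
  for (ks in list(c(0.0105, 1.34), c(0.02, 1.5))) {
    emptied <- stats::integrate(function(t)
      gastric_emptying_rate(t, meal, ks[1], ks[2]),
      0, 2000, rel.tol = 1e-9)$value
    expect_lt(abs(emptied / 75000 - 1), 1e-3)
  }
})

test_that("hepatic glucose production follows the extended liver equation", {
  p <- population_params()
  # basal point: all deviation terms vanish
  expect_equal(hepatic_glucose_flux(p$G_b_pl, 0, p$AA_b_pl, p), p$g_b_liv)
  # k11 = 0 removes the AA dependence entirely
  p0 <- population_params(k11 = 0)
  expect_equal(hepatic_glucose_flux(6, 10, 99, p0),
               hepatic_glucose_flux(6, 10, 1, p0))
  # linearity in the AA excursion
  expect_equal(hepatic_glucose_flux(p$G_b_pl, 0, p$AA_b_pl + 1, p),
               p$g_b_liv + p$k11)
})

test_that("pancreatic secretion follows the extended PID controller", {
  p <- population_params()
  cn <- p$constants
  basal <- (p$k7 / cn$tau_i) * p$G_b_pl / cn$beta_conv
  expect_equal(
    pancreatic_secretion_flux(p$G_b_pl, 0, 0, p$AA_b_pl, 0, p), basal)
  # k12 = k13 = 0 removes the AA arguments
  p0 <- population_params(k12 = 0, k13 = 0)
  expect_equal(pancreatic_secretion_flux(6, 2, 0.1, 9, 0.5, p0),
               pancreatic_secretion_flux(6, 2, 0.1, 1, -2, p0))
  # derivative term is linear: a dAA/dt step of x adds beta^-1 * k12 * x
  x <- 0.07
  expect_equal(
    pancreatic_secretion_flux(p$G_b_pl, 0, 0, p$AA_b_pl, x, p) - basal,
    p$k12 * x / cn$beta_conv)
})

test_that("the basal state is a fixed point of the rhs and stays fixed over 300 min", {
  p <- population_params()
  aa <- aa_forcing_constant(p$AA_b_pl)
  d <- edes_rhs(0, basal_state(p), p, meal_spec(0), aa)
  expect_equal(unname(d), rep(0, 5))
  tr <- simulate_edes(p, meal_spec(0), aa, seq(0, 300, 5))
  dev <- abs(sweep(as.matrix(as.data.frame(tr)[, -1]), 2, basal_state(p)))
  expect_lt(max(dev), 1e-6)
})

test_that("a small glucose perturbation decays back toward basal", {
  p <- population_params()
  aa <- aa_forcing_constant(p$AA_b_pl)
  st <- basal_state(p)
  st["G_pl"] <- st["G_pl"] + 0.1
  d <- edes_rhs(0, st, p, meal_spec(0), aa)
  expect_lt(d[["G_pl"]], 0)
})

test_that("with k11 = k12 = k13 = 0 trajectories match the independent base-model code", {
  p <- population_params(k11 = 0, k12 = 0, k13 = 0)
  tg <- seq(0, 180, 2)
  ref_par <- ref_env$reference_par_from_params(p)
  for (dose in c(25000, 75000)) {
    mine <- simulate_edes(p, meal_spec(dose), test_aa_forcing(), tg,
                          rtol = 1e-8, atol = 1e-10)
    ref <- ref_env$simulate_base_edes_reference(ref_par, dose, tg)
    expect_lt(max(abs(mine$G_pl - ref$G_pl)), 1e-5)
    expect_lt(max(abs(mine$I_pl - ref$I_pl)), 1e-4)
  }
})

test_that("compiled and interpreted right-hand sides integrate to the same trajectories", {
  p <- population_params()
  aa <- test_aa_forcing()
  tg <- seq(0, 150, 2)
  for (dose in c(0, 25000)) {
    comp <- simulate_edes(p, meal_spec(dose), aa, tg, use_compiled = TRUE)
    interp <- simulate_edes(p, meal_spec(dose), aa, tg, use_compiled = FALSE)
    expect_lt(max(abs(comp$G_pl - interp$G_pl)), 1e-5)
    expect_lt(max(abs(comp$I_pl - interp$I_pl)), 1e-4)
  }
})

test_that("simulation is deterministic and converges under tolerance tightening", {
  p <- population_params()
  aa <- test_aa_forcing()
  tg <- seq(0, 150, 5)
  a <- simulate_edes(p, meal_spec(25000), aa, tg)
  b <- simulate_edes(p, meal_spec(25000), aa, tg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  tight <- simulate_edes(p, meal_spec(25000), aa, tg,
                         rtol = 1e-7, atol = 1e-9)
  expect_lt(max(abs(a$G_pl - tight$G_pl)), 1e-5)  # below the coarser rtol scale
})

test_that("gut glucose mass stays non-negative and empties completely", {
  p <- population_params()
  tr <- simulate_edes(p, meal_spec(75000), test_aa_forcing(),
                      seq(0, 600, 5))
  expect_true(all(tr$M_gut >= -1e-9))
  # absorbed mass = dose - residual gut content at the horizon
  expect_lt(abs(tr$M_gut[nrow(tr)]) / 75000, 1e-3)
})

test_that("peak insulin responds monotonically to the proportional AA term k13", {
  aa <- test_aa_forcing()
  peaks <- vapply(c(0, 0.25, 0.5, 1), function(k13) {
    p <- population_params(k13 = k13)
    max(simulate_edes(p, meal_spec(0), aa, seq(0, 150, 2))$I_pl)
  }, 0)
  expect_true(all(diff(peaks) >= 0))
})

test_that("trajectory structure honours grid and initial condition", {
  p <- population_params()
  tr <- simulate_edes(p, meal_spec(0), aa_forcing_constant(p$AA_b_pl),
                      c(0, 1, 5, 20))
  expect_equal(tr$time, c(0, 1, 5, 20))
  expect_equal(unlist(tr[1, -1]), basal_state(p))
  expect_error(simulate_edes(p, meal_spec(0),
                             aa_forcing_constant(p$AA_b_pl), c(5, 10)),
               "start at 0")
  expect_error(simulate_edes(p, meal_spec(0),
                             aa_forcing_constant(p$AA_b_pl), c(0, 10, 10)),
               "increasing")
})
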