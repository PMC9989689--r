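test_that("a basal trajectory has constant basal fluxes", {
  p <- population_params()
  tr <- simulate_edes(p, meal_spec(0), aa_forcing_constant(p$AA_b_pl),
                      seq(0, 120, 10))
  fx <- compute_fluxes(tr)
  expect_equal(fx$endogenous_glucose_production, rep(p$g_b_liv, nrow(fx)))
  basal_sec <- p$k7 / p$constants$tau_i * p$G_b_pl / p$constants$beta_conv
  expect_equal(fx$insulin_secretion, rep(basal_sec, nrow(fx)),
               tolerance = 1e-8)
  expect_equal(fx$renal_excretion, rep(0, nrow(fx)))
  expect_equal(fx$glucose_gut_appearance, rep(0, nrow(fx)))
})

test_that("plasma balances close at every sampled time", {
  des <- quiet_design("AA_PLUS_GLUCOSE", seed = 2)
  ds <- generate_dataset(des)
  tr <- simulate_edes(attr(ds, "true_params"), ds$meal, aa_forcing(ds$aa),
                      seq(0, 150, 2))
  fx <- compute_fluxes(tr)
  g_sum <- fx$glucose_gut_appearance + fx$endogenous_glucose_production -
    fx$insulin_independent_uptake - fx$insulin_dependent_uptake -
    fx$renal_excretion
  rel <- abs(fx$dG_dt - g_sum) / pmax(abs(fx$dG_dt), 1e-6)
  expect_lt(max(rel), 1e-8)
  i_sum <- fx$insulin_secretion - fx$insulin_clearance - fx$insulin_transfer
  rel_i <- abs(fx$dI_dt - i_sum) / pmax(abs(fx$dI_dt), 1e-6)
  expect_lt(max(rel_i), 1e-8)
})

test_that("renal excretion activates only above the threshold", {
  # lower the renal threshold so a moderate meal crosses it
  cn <- edes_constants(G_th_ren = 6)
  p <- population_params(constants = cn)
  tr <- simulate_edes(p, meal_spec(75000), test_aa_forcing(), seq(0, 240, 2))
  fx <- compute_fluxes(tr)
  expect_true(all(fx$renal_excretion >= 0))
  expect_true(any(fx$renal_excretion > 0))
  expect_true(all(fx$renal_excretion[tr$G_pl <= 6] == 0))
})

test_that("protein-only meals raise EGP; AA+glucose meals suppress it near the glycemic peak", {
  # protein-only: AA excursion with no glucose dose
  dp <- quiet_design("PROTEIN_INGREDIENT")
  dsp <- generate_dataset(dp)
  trp <- simulate_edes(attr(dsp, "true_params"), dsp$meal,
                       aa_forcing(dsp$aa), seq(0, 300, 2))
  fxp <- compute_fluxes(trp)
  g_b_liv <- attr(dsp, "true_params")$g_b_liv
  expect_gt(max(fxp$endogenous_glucose_production), g_b_liv)
  # AA+glucose: suppression dominates around the glycemic peak
  dg <- quiet_design("AA_PLUS_GLUCOSE")
  dsg <- generate_dataset(dg)
  trg <- simulate_edes(attr(dsg, "true_params"), dsg$meal,
                       aa_forcing(dsg$aa), seq(0, 150, 2))
  fxg <- compute_fluxes(trg)
  ipk <- which.max(trg$G_pl)
  expect_lt(fxg$endogenous_glucose_production[ipk], g_b_liv)
})

test_that("flux comparison reports zero differences for identical inputs and integrates areas", {
  p <- population_params()
  tr <- simulate_edes(p, meal_spec(25000), test_aa_forcing(), seq(0, 150, 5))
  fx <- compute_fluxes(tr)
  cmp <- compare_fluxes(fx, fx)
  expect_true(all(cmp$summary$peak_difference == 0))
  expect_true(all(cmp$summary$incremental_area == 0))
  # constant difference c over [0, T] integrates to c*T
  fx2 <- fx
  fx2$endogenous_glucose_production <-
    fx$endogenous_glucose_production + 0.01
  cmp2 <- compare_fluxes(fx2, fx)
  a <- cmp2$summary$incremental_area[
    cmp2$summary$flux == "endogenous_glucose_production"]
  expect_equal(a, 0.01 * 150, tolerance = 1e-9)
  # mismatched grids refused
  tr3 <- simulate_edes(p, meal_spec(25000), test_aa_forcing(), seq(0, 150, 3))
  expect_error(compare_fluxes(fx, compute_fluxes(tr3)), "grids")
})

test_that("fluxes must be computed with the trajectory's own parameters", {
  p <- population_params()
  tr <- simulate_edes(p, meal_spec(0), aa_forcing_constant(p$AA_b_pl),
                      seq(0, 60, 10))
  other <- population_params(k11 = 0.01)
  expect_error(compute_fluxes(tr, params = other), "do not match")
})
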