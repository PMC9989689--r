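# build a tiny dataset whose observations sit at a chosen offset from the
# model's own prediction, so the weighted cost is known in closed form
offset_dataset <- function(g_offsets = NULL, i_offsets = NULL) {
  p <- population_params()
  des <- quiet_design("AA_ONLY")
  aa <- make_aa_curve(des)
  tg <- c(0, 30, 60)
  tr <- simulate_edes(p, meal_spec(0), aa_forcing(aa), tg,
                      rtol = 1e-10, atol = 1e-12)
  g <- data.frame(time = tg, value = tr$G_pl)
  i <- data.frame(time = tg, value = tr$I_pl)
  if (!is.null(g_offsets)) g$value <- g$value + g_offsets
  if (!is.null(i_offsets)) i$value <- i$value + i_offsets
  challenge_dataset("offset", meal_spec(0), aa, g, i)
}

test_that("cost reproduces the weighted SSR on hand-built residual sets", {
  sc <- scenario_config("EDES_PROT")
  # perfect fit: zero within solver tolerance
  expect_lt(cost(numeric(0), sc, offset_dataset()), 1e-8)
  # a single glucose residual of 2 contributes (1*2)^2 = 4
  expect_equal(cost(numeric(0), sc, offset_dataset(g_offsets = c(0, 2, 0))),
               4, tolerance = 1e-6)
  # a single insulin residual of 10 contributes (0.1*10)^2 = 1
  expect_equal(cost(numeric(0), sc, offset_dataset(i_offsets = c(0, 0, 10))),
               1, tolerance = 1e-6)
})

test_that("cost is invariant to observation ordering", {
  sc <- scenario_config("EDES_PROT")
  ds <- offset_dataset(g_offsets = c(0, 1, -1), i_offsets = c(0, 5, 2))
  shuffled <- challenge_dataset(ds$subject_id, ds$meal, ds$aa,
                                ds$glucose_obs[c(3, 1, 2), ],
                                ds$insulin_obs[c(2, 3, 1), ])
  expect_equal(cost(numeric(0), sc, ds), cost(numeric(0), sc, shuffled))
})

test_that("residual table round-trips with cost and uses simulated-minus-observed", {
  # observed one above simulated -> weighted residual -1
  ds <- offset_dataset(g_offsets = c(0, 1, 0))
  p <- population_params()
  tab <- residuals_table(p, ds)
  expect_equal(nrow(tab), 6)
  r <- tab$weighted_residual[tab$metabolite == "glucose" & tab$time == 30]
  expect_equal(r, -1, tolerance = 1e-6)
  sc <- scenario_config("EDES_PROT")
  expect_equal(sum(tab$weighted_residual^2), cost(numeric(0), sc, ds),
               tolerance = 1e-10)
  # perfect fit: all residuals vanish
  tab0 <- residuals_table(p, offset_dataset())
  expect_lt(max(abs(tab0$weighted_residual)), 1e-5)
})

test_that("an empty free set returns the population evaluation without optimizing", {
  ds <- offset_dataset(g_offsets = c(0, 2, 0))
  fit <- fit_dataset(ds, scenario_config("EDES_PROT"), solver = test_solver)
  expect_equal(fit$k_free, 0)
  expect_equal(nrow(fit$per_start), 0)
  expect_equal(fit$ssr, 4, tolerance = 1e-5)
  expect_equal(fit$best_params$k11, population_params()$k11)
})

test_that("noiseless amino-acid parameters are recovered from a synthetic challenge", {
  tru <- recovery_truth()
  des <- quiet_design("AA_ONLY", seed = 11, true_params = tru)
  ds <- generate_dataset(des)
  sc <- scenario_config("EDES_PROT", c("k11", "k12", "k13"),
                        n_starts = 2, seed = 5)
  fit <- fit_dataset(ds, sc, solver = test_solver,
                     optim_control = test_optim)
  for (nm in c("k11", "k12", "k13"))
    expect_lt(abs(fit$free_values[[nm]] / tru[[nm]] - 1), 0.05)
  # round-trip invariant: stored SSR equals the cost re-evaluated there
  expect_equal(fit$ssr, cost(fit$free_values, sc, ds, solver = test_solver),
               tolerance = 1e-8)
  expect_equal(min(fit$per_start$cost, na.rm = TRUE), fit$ssr,
               tolerance = 1e-6)
})

test_that("fitting is deterministic under a fixed seed", {
  des <- synthetic_design("AA_ONLY", seed = 3)
  ds <- generate_dataset(des)
  sc <- scenario_config("EDES_PROT", "k13", n_starts = 2, seed = 9)
  f1 <- fit_dataset(ds, sc, solver = test_solver, optim_control = test_optim)
  f2 <- fit_dataset(ds, sc, solver = test_solver, optim_control = test_optim)
  expect_identical(f1$free_values, f2$free_values)
  expect_identical(f1$ssr, f2$ssr)
  expect_identical(f1$per_start, f2$per_start)
})

test_that("more starts never worsen the returned cost", {
  des <- synthetic_design("AA_ONLY", seed = 4)
  ds <- generate_dataset(des)
  ssr <- vapply(c(1, 3), function(ns) {
    sc <- scenario_config("EDES_PROT", "k13", n_starts = ns, seed = 2)
    fit_dataset(ds, sc, solver = test_solver, optim_control = test_optim)$ssr
  }, 0)
  expect_lte(ssr[2], ssr[1] + 1e-9)
})

test_that("scenario validation enforces the variant contract", {
  expect_error(scenario_config("EDES", c("k11")), "amino-acid")
  expect_error(scenario_config("EDES_PROT", "k2"), "cannot free")
  expect_error(scenario_config("EDES_PROT", "k13", start_noise = 1), "start_noise")
  expect_error(scenario_config("EDES_PROT", "k13", n_starts = 0), "n_starts")
})
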