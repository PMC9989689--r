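#' Meal-challenge dataset
#'
#' One subject-meal postprandial time series: glucose and insulin
#' observations plus the plasma amino-acid series driving the forcing
#' function and a meal descriptor. The t = 0 observations define the
#' basal values used in fitting (`G_b_pl`, `I_b_pl`, `AA_b_pl`).
#'
#' @param subject_id Identifier.
#' @param meal A [meal_spec()].
#' @param aa An [aa_series()] (total AA or a single AA).
#' @param glucose_obs Data frame with columns `time`, `value` (mmol/L).
#' @param insulin_obs Data frame with columns `time`, `value` (mU/L).
#' @return An object of class `challenge_dataset`.
#' @export
challenge_dataset <- function(subject_id, meal, aa, glucose_obs,
                              insulin_obs) {
  stopifnot(inherits(meal, "meal_spec"), inherits(aa, "aa_series"))
  check_obs <- function(obs, what, t_last) {
    obs <- as.data.frame(obs)[, c("time", "value")]
    obs <- obs[order(obs$time), , drop = FALSE]
    if (any(duplicated(obs$time)))
      stop("duplicated ", what, " observation times")
    if (nrow(obs) == 0L || obs$time[1L] != 0)
      stop(what, " observations must include t = 0 (defines the basal value)")
    if (is.na(obs$value[1L]))
      stop("the t = 0 ", what, " observation must not be missing")
    if (any(obs$time < 0) || any(obs$time > t_last))
      stop(what, " observation times must lie within [0, ", t_last,
           "] of the AA series")
    obs
  }
  t_last <- max(aa$times)
  glucose_obs <- check_obs(glucose_obs, "glucose", t_last)
  insulin_obs <- check_obs(insulin_obs, "insulin", t_last)
  structure(list(subject_id = as.character(subject_id), meal = meal,
                 aa = aa, glucose_obs = glucose_obs,
                 insulin_obs = insulin_obs),
            class = "challenge_dataset")
}

#' @export
print.challenge_dataset <- function(x, ...) {
  cat(sprintf("<challenge_dataset '%s'> %s; %d glucose + %d insulin obs; AA '%s' over [0, %g] min\n",
              x$subject_id,
              if (nzchar(x$meal$description)) x$meal$description
              else sprintf("%g mg glucose", x$meal$D_glucose),
              nrow(x$glucose_obs), nrow(x$insulin_obs),
              x$aa$name, max(x$aa$times)))
  invisible(x)
}

dataset_basals <- function(dataset) {
  list(G_b_pl = dataset$glucose_obs$value[dataset$glucose_obs$time == 0],
       I_b_pl = dataset$insulin_obs$value[dataset$insulin_obs$time == 0],
       AA_b_pl = dataset$aa$concentrations[dataset$aa$times == 0])
}

#' Calibration scenario
#'
#' Which model variant to fit, which parameters to free, and how the
#' multi-start optimization is initialized. Start points are the
#' population value of each free parameter perturbed by an independent
#' multiplicative factor drawn uniformly from
#' `[1 - start_noise, 1 + start_noise]`.
#'
#' @param variant `"EDES"` (base model, k11-k13 pinned to 0) or
#'   `"EDES_PROT"` (amino-acid extension).
#' @param free_params Subset of `k1, k5, k6, k8, k11, k12, k13`; the
#'   `EDES` variant may not free `k11`-`k13`.
#' @param n_starts Number of optimizer initializations (default 25).
#' @param start_noise Fractional start perturbation in `[0, 1)`,
#'   default 0.25.
#' @param seed RNG seed for the start draw (optional).
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   default `[0, 100 x population value]`.
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' scenario_config("EDES_PROT", c("k11", "k12", "k13"), n_starts = 5, seed = 1)
scenario_config <- function(variant = c("EDES_PROT", "EDES"),
                            free_params = character(),
                            n_starts = 25, start_noise = 0.25,
                            seed = NULL, bounds = NULL) {
  variant <- match.arg(variant)
  free_params <- as.character(free_params)
  bad <- setdiff(free_params, FREE_PARAM_NAMES)
  if (length(bad) > 0L)
    stop("cannot free parameter(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(FREE_PARAM_NAMES, collapse = ", "), ")")
  if (variant == "EDES" && any(free_params %in% AA_PARAM_NAMES))
    stop("the EDES variant has no amino-acid parameters to free")
  if (n_starts < 1L) stop("n_starts must be at least 1")
  if (start_noise < 0 || start_noise >= 1)
    stop("start_noise must lie in [0, 1)")
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), free_params)
    if (length(bad) > 0L)
      stop("bounds given for non-free parameter(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(variant = variant, free_params = free_params,
                 n_starts = as.integer(n_starts),
                 start_noise = start_noise, seed = seed, bounds = bounds),
            class = "scenario_config")
}

# Full parameter vector implied by a scenario: population values, basal
# values from the dataset's t = 0 samples, k11-k13 zeroed for the base
# variant, and the free values patched in.
scenario_params <- function(free_values, scenario, dataset,
                            population = population_params()) {
  basals <- dataset_basals(dataset)
  p <- population
  p[names(basals)] <- basals
  if (scenario$variant == "EDES") p[AA_PARAM_NAMES] <- 0
  if (length(free_values) > 0L) {
    stopifnot(!is.null(names(free_values)),
              all(names(free_values) %in% scenario$free_params))
    p[names(free_values)] <- as.list(as.numeric(free_values))
  }
  validate_params(p)
  p
}

# default solver settings used inside the fitting loop: tighter than the
# simulation defaults so that finite-difference Jacobians of the residual
# are not dominated by integration noise
fit_solver_control <- function(rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  list(rtol = rtol, atol = atol, method = method)
}

# Weighted residual vector gamma * (simulated - observed) for all non-NA
# glucose and insulin observations. On solver failure returns a constant
# penalty vector whose sum of squares is `penalty` (1e12), so gradient
# optimizers see a large finite cost instead of an exception.
weighted_residuals <- function(params, dataset, solver = fit_solver_control(),
                               penalty = 1e12, gamma_insulin = 0.1) {
  g <- dataset$glucose_obs[!is.na(dataset$glucose_obs$value), , drop = FALSE]
  i <- dataset$insulin_obs[!is.na(dataset$insulin_obs$value), , drop = FALSE]
  t_out <- sort(unique(c(0, g$time, i$time)))
  n <- nrow(g) + nrow(i)
  sim <- try(simulate_edes(params, dataset$meal, aa_forcing(dataset$aa),
                           t_out, rtol = solver$rtol, atol = solver$atol,
                           method = solver$method),
             silent = TRUE)
  if (inherits(sim, "try-error"))
    return(rep(sqrt(penalty / n), n))
  y_g <- sim$G_pl[match(g$time, sim$time)]
  y_i <- sim$I_pl[match(i$time, sim$time)]
  c(1.0 * (y_g - g$value), gamma_insulin * (y_i - i$value))
}

#' Calibration cost (weighted sum of squared residuals)
#'
#' Simulates the scenario's model variant at the implied full parameter
#' vector, samples glucose and insulin at the observation times, and
#' returns the pooled weighted sum of squared residuals with weight 1 for
#' glucose and `gamma_insulin = 0.1` for insulin (the weight brings the
#' mmol/L and mU/L scales together so neither metabolite dominates).
#' Solver failures yield a large finite penalty (1e12), not an error.
#'
#' @param free_values Named numeric vector of values for the scenario's
#'   free parameters (may be empty).
#' @param scenario A [scenario_config()].
#' @param dataset A [challenge_dataset()].
#' @param population Population parameter set ([edes_params()]).
#' @param solver Solver settings for the embedded simulations.
#' @param gamma_insulin Insulin residual weight (default 0.1).
#' @return The scalar SSR.
#' @export
cost <- function(free_values, scenario, dataset,
                 population = population_params(),
                 solver = fit_solver_control(), gamma_insulin = 0.1) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(dataset, "challenge_dataset"))
  p <- scenario_params(free_values, scenario, dataset, population)
  r <- weighted_residuals(p, dataset, solver, gamma_insulin = gamma_insulin)
  sum(r^2)
}

#' Per-observation weighted residual table
#'
#' Diagnostic table of every fitted observation with its simulated
#' counterpart, weight, and weighted residual (sign convention:
#' simulated minus observed). The sum of squared weighted residuals
#' equals the calibration cost.
#'
#' @param params Full [edes_params()] vector to evaluate.
#' @param dataset A [challenge_dataset()].
#' @param solver Solver settings.
#' @param gamma_insulin Insulin residual weight.
#' @return Data frame with columns `metabolite`, `time`, `observed`,
#'   `simulated`, `gamma`, `weighted_residual`.
#' @export
residuals_table <- function(params, dataset, solver = fit_solver_control(),
                            gamma_insulin = 0.1) {
  stopifnot(inherits(params, "edes_params"),
            inherits(dataset, "challenge_dataset"))
  g <- dataset$glucose_obs[!is.na(dataset$glucose_obs$value), , drop = FALSE]
  i <- dataset$insulin_obs[!is.na(dataset$insulin_obs$value), , drop = FALSE]
  t_out <- sort(unique(c(0, g$time, i$time)))
  sim <- simulate_edes(params, dataset$meal, aa_forcing(dataset$aa), t_out,
                       rtol = solver$rtol, atol = solver$atol,
                       method = solver$method)
  out <- rbind(
    data.frame(metabolite = "glucose", time = g$time, observed = g$value,
               simulated = sim$G_pl[match(g$time, sim$time)], gamma = 1.0),
    data.frame(metabolite = "insulin", time = i$time, observed = i$value,
               simulated = sim$I_pl[match(i$time, sim$time)],
               gamma = gamma_insulin))
  out$weighted_residual <- out$gamma * (out$simulated - out$observed)
  out
}

#' Fit a meal challenge
#'
#' Multi-start bound-constrained least-squares calibration: `n_starts`
#' Levenberg-Marquardt runs (`minpack.lm::nls.lm`) from perturbed
#' population start points. Optimization is carried out in
#' population-multiplier space so all free parameters are O(1); bounds
#' default to `[0, 100 x population value]`. The best converged start is
#' returned with all per-start outcomes retained.
#'
#' @param dataset A [challenge_dataset()].
#' @param scenario A [scenario_config()].
#' @param population Population parameter set.
#' @param solver Solver settings for embedded simulations (tight
#'   tolerances by default; see Details in the package vignette).
#' @param optim_control `minpack.lm::nls.lm.control` list.
#' @param gamma_insulin Insulin residual weight.
#' @return An object of class `edes_fit`: best parameters, SSR, AIC/BIC,
#'   per-start table, and the simulated trajectory at the optimum.
#' @export
#' @examples
#' \donttest{
#' des <- synthetic_design("AA_ONLY", seed = 1)
#' ds <- generate_dataset(des)
#' sc <- scenario_config("EDES_PROT", c("k11", "k13"), n_starts = 2, seed = 1)
#' fit <- fit_dataset(ds, sc)
#' fit$ssr
#' }
fit_dataset <- function(dataset, scenario,
                        population = population_params(),
                        solver = fit_solver_control(),
                        optim_control = minpack.lm::nls.lm.control(
                          epsfcn = 1e-6, maxiter = 100),
                        gamma_insulin = 0.1) {
  stopifnot(inherits(dataset, "challenge_dataset"),
            inherits(scenario, "scenario_config"))
  free <- scenario$free_params
  k_free <- length(free)
  n_obs <- sum(!is.na(dataset$glucose_obs$value)) +
    sum(!is.na(dataset$insulin_obs$value))

  if (k_free == 0L) {
    best_free <- stats::setNames(numeric(0), character(0))
    per_start <- data.frame()
  } else {
    pop_vals <- unlist(population[free])
    if (any(pop_vals <= 0))
      stop("population value of a free parameter is zero; cannot scale")
    lower_m <- rep(0, k_free)
    upper_m <- rep(100, k_free)
    if (!is.null(scenario$bounds)) {
      for (nm in names(scenario$bounds)) {
        j <- match(nm, free)
        lower_m[j] <- scenario$bounds[[nm]][1L] / pop_vals[j]
        upper_m[j] <- scenario$bounds[[nm]][2L] / pop_vals[j]
      }
    }
    resid_fn <- function(m) {
      fv <- stats::setNames(m * pop_vals, free)
      p <- scenario_params(fv, scenario, dataset, population)
      weighted_residuals(p, dataset, solver, gamma_insulin = gamma_insulin)
    }
    if (!is.null(scenario$seed)) set.seed(scenario$seed)
    starts <- matrix(stats::runif(scenario$n_starts * k_free,
                                  1 - scenario$start_noise,
                                  1 + scenario$start_noise),
                     nrow = scenario$n_starts)
    starts <- pmin(pmax(starts, matrix(lower_m, scenario$n_starts, k_free,
                                       byrow = TRUE)),
                   matrix(upper_m, scenario$n_starts, k_free, byrow = TRUE))
    runs <- vector("list", scenario$n_starts)
    for (s in seq_len(scenario$n_starts)) {
      runs[[s]] <- tryCatch(
        minpack.lm::nls.lm(par = starts[s, ], lower = lower_m,
                           upper = upper_m, fn = resid_fn,
                           control = optim_control),
        error = function(e) e)
    }
    ok <- !vapply(runs, inherits, TRUE, "error")
    if (!any(ok)) {
      msgs <- vapply(runs, conditionMessage, "")
      stop("all optimization starts failed:\n  ",
           paste(sprintf("start %d: %s", seq_along(msgs), msgs),
                 collapse = "\n  "))
    }
    per_start <- data.frame(start = seq_len(scenario$n_starts))
    for (j in seq_len(k_free))
      per_start[[paste0("start_", free[j])]] <- starts[, j] * pop_vals[j]
    per_start$cost <- ifelse(ok, vapply(runs, function(r)
      if (inherits(r, "error")) NA_real_ else r$deviance, 0), NA_real_)
    per_start$converged <- ok & per_start$cost < 1e11
    per_start$niter <- vapply(runs, function(r)
      if (inherits(r, "error")) NA_integer_ else r$niter, 0L)
    best_idx <- which.min(ifelse(ok, per_start$cost, Inf))
    best_free <- stats::setNames(runs[[best_idx]]$par * pop_vals, free)
  }

  best_params <- scenario_params(best_free, scenario, dataset, population)
  ssr <- cost(best_free, scenario, dataset, population, solver,
              gamma_insulin)
  t_last <- max(dataset$aa$times)
  traj <- simulate_edes(best_params, dataset$meal, aa_forcing(dataset$aa),
                        seq(0, t_last, by = 1), rtol = solver$rtol,
                        atol = solver$atol, method = solver$method)
  structure(list(best_params = best_params, free_values = best_free,
                 ssr = ssr, n_obs = n_obs, k_free = k_free,
                 aic = if (ssr > 0) aic_ssr(ssr, n_obs, k_free) else NA_real_,
                 bic = if (ssr > 0) bic_ssr(ssr, n_obs, k_free) else NA_real_,
                 per_start = per_start, trajectory = traj,
                 scenario = scenario, dataset = dataset,
                 population = population, gamma_insulin = gamma_insulin),
            class = "edes_fit")
}

#' @export
print.edes_fit <- function(x, ...) {
  cat(sprintf("<edes_fit> %s on '%s': SSR = %.6g (N = %d, K = %d), AIC = %.4g, BIC = %.4g\n",
              x$scenario$variant, x$dataset$subject_id, x$ssr, x$n_obs,
              x$k_free, x$aic, x$bic))
  if (x$k_free > 0L) {
    fv <- paste(sprintf("%s = %.4g", names(x$free_values), x$free_values),
                collapse = ", ")
    cat("  estimates:", fv, "\n")
  }
  invisible(x)
}
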