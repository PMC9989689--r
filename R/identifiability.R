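#' Profile likelihood of one fitted parameter
#'
#' Scans one free parameter over a multiplicative grid around its
#' optimum, re-estimating the remaining free parameters at every grid
#' point (warm-started from the neighboring point, walking outward from
#' the optimum in both directions). A cost profile that rises on both
#' sides of the optimum indicates a reliably estimable parameter; a flat
#' or one-sided profile indicates an identifiability problem.
#'
#' @param fit An [fit_dataset()] result.
#' @param param_name One of the fit's free parameters.
#' @param range Multiplicative scan range around the optimum,
#'   default `c(0.1, 10)`.
#' @param n_grid Number of log-spaced grid points (default 21; the
#'   optimum itself is inserted as an extra point).
#' @param threshold_rule List with `alpha` (chi-square confidence level
#'   for the cost-increase threshold) and `floor` (absolute minimum
#'   threshold guarding the noiseless case); see [classify_profile()].
#' @param optim_control Optimizer control for the re-fits.
#' @return An object of class `profile_result`: `param_name`, `grid`,
#'   `profile_cost` (NA where a re-fit failed), `optimum`,
#'   `classification`, `threshold`, and the re-fitted co-parameters.
#' @export
profile_likelihood <- function(fit, param_name, range = c(0.1, 10),
                               n_grid = 21,
                               threshold_rule = list(alpha = 0.95,
                                                     floor = 1e-6),
                               optim_control = minpack.lm::nls.lm.control(
                                 epsfcn = 1e-6, maxiter = 100)) {
  stopifnot(inherits(fit, "edes_fit"))
  if (!param_name %in% fit$scenario$free_params)
    stop("'", param_name, "' is not a free parameter of this fit")
  scenario <- fit$scenario
  dataset <- fit$dataset
  population <- fit$population
  others <- setdiff(scenario$free_params, param_name)
  opt_value <- fit$free_values[[param_name]]
  opt_others <- fit$free_values[others]

  grid <- sort(unique(c(opt_value,
                        opt_value * exp(seq(log(range[1L]), log(range[2L]),
                                            length.out = n_grid)))))
  opt_idx <- match(opt_value, grid)

  pop_o <- unlist(population[others])
  refit_at <- function(value, warm) {
    fixed <- stats::setNames(value, param_name)
    if (length(others) == 0L)
      return(list(cost = cost(fixed, scenario, dataset, population),
                  co = numeric(0)))
    resid_fn <- function(m) {
      fv <- c(fixed, stats::setNames(m * pop_o, others))
      p <- scenario_params(fv, scenario, dataset, population)
      weighted_residuals(p, dataset, gamma_insulin = fit$gamma_insulin)
    }
    r <- tryCatch(
      minpack.lm::nls.lm(par = warm / pop_o, lower = rep(0, length(others)),
                         upper = rep(100, length(others)), fn = resid_fn,
                         control = optim_control),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    list(cost = r$deviance, co = stats::setNames(r$par * pop_o, others))
  }

  n <- length(grid)
  profile_cost <- rep(NA_real_, n)
  co_params <- matrix(NA_real_, n, length(others),
                      dimnames = list(NULL, others))
  profile_cost[opt_idx] <- fit$ssr
  if (length(others) > 0L) co_params[opt_idx, ] <- opt_others

  walk <- function(idxs) {
    warm <- if (length(others) > 0L) opt_others else numeric(0)
    for (i in idxs) {
      r <- refit_at(grid[i], warm)
      if (is.null(r)) next  # re-fit failure recorded as missing
      profile_cost[i] <<- r$cost
      if (length(others) > 0L) {
        co_params[i, ] <<- r$co
        warm <- r$co
      }
    }
  }
  if (opt_idx < n) walk(seq(opt_idx + 1L, n))
  if (opt_idx > 1L) walk(seq(opt_idx - 1L, 1L))

  threshold <- profile_threshold(fit, threshold_rule)
  cls <- classify_profile(profile_cost, grid, opt_idx, threshold)
  structure(list(param_name = param_name, grid = grid,
                 profile_cost = profile_cost,
                 optimum = c(value = opt_value, cost = fit$ssr),
                 classification = cls, threshold = threshold,
                 co_params = as.data.frame(co_params)),
            class = "profile_result")
}

# Cost-increase threshold: chi-square(1) quantile scaled by the residual
# variance estimated at the optimum, floored for (near-)noiseless fits.
profile_threshold <- function(fit, threshold_rule) {
  s2 <- fit$ssr / max(fit$n_obs - fit$k_free, 1L)
  max(stats::qchisq(threshold_rule$alpha, df = 1L) * s2,
      threshold_rule$floor)
}

#' Classify a cost profile
#'
#' A parameter is `identifiable` when the profile cost rises above the
#' threshold on both sides of the optimum, `practically_unidentifiable`
#' when it rises on one side only, and `structurally_unidentifiable`
#' when the profile is flat (no rise on either side).
#'
#' @param profile_cost Re-optimized cost per grid point (NA allowed).
#' @param grid Parameter values scanned.
#' @param opt_idx Index of the optimum in `grid`.
#' @param threshold Cost-increase threshold.
#' @return One of `"identifiable"`, `"practically_unidentifiable"`,
#'   `"structurally_unidentifiable"`.
#' @export
classify_profile <- function(profile_cost, grid, opt_idx, threshold) {
  stopifnot(length(profile_cost) == length(grid),
            opt_idx >= 1L, opt_idx <= length(grid))
  ref <- min(profile_cost, na.rm = TRUE)
  rise <- profile_cost - ref
  rises_left <- opt_idx > 1L &&
    any(rise[seq_len(opt_idx - 1L)] > threshold, na.rm = TRUE)
  rises_right <- opt_idx < length(grid) &&
    any(rise[seq(opt_idx + 1L, length(grid))] > threshold, na.rm = TRUE)
  if (rises_left && rises_right) "identifiable"
  else if (rises_left || rises_right) "practically_unidentifiable"
  else "structurally_unidentifiable"
}

#' @export
print.profile_result <- function(x, ...) {
  cat(sprintf("<profile_result> %s: optimum %.4g (cost %.5g), %d grid points, threshold %.3g\n  classification: %s\n",
              x$param_name, x$optimum[["value"]], x$optimum[["cost"]],
              length(x$grid), x$threshold, x$classification))
  invisible(x)
}

#' Export a profile as CSV
#'
#' @param profile A `profile_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile_result"))
  df <- data.frame(value = profile$grid, cost = profile$profile_cost)
  if (ncol(profile$co_params) > 0L) df <- cbind(df, profile$co_params)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
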