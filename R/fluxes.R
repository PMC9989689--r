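#' Metabolite fluxes along a trajectory
#'
#' Re-evaluates every named model flux at the sampled states of a
#' simulated trajectory: glucose appearance from the gut, endogenous
#' glucose production, insulin-independent and insulin-dependent glucose
#' uptake, renal excretion, pancreatic insulin secretion, hepatic insulin
#' clearance, and plasma-to-interstitium insulin transfer. Fluxes are
#' recomputed from the states (not logged during integration), so the
#' plasma balances close exactly: the glucose derivative equals gut
#' appearance + EGP - uptakes - renal excretion at every sampled time,
#' and likewise for insulin.
#'
#' @param traj An `edes_trajectory` from [simulate_edes()].
#' @param params,meal,aa Inputs the trajectory was simulated with;
#'   default to the ones carried by the trajectory. Supplying different
#'   parameters is an error.
#' @return A `flux_trajectory`: data frame with `time`, one column per
#'   flux (glucose fluxes in mmol/L/min, insulin fluxes in mU/L/min), and
#'   the state derivatives `dG_dt`, `dI_dt` for balance checks.
#' @export
compute_fluxes <- function(traj, params = attr(traj, "params"),
                           meal = attr(traj, "meal"),
                           aa = attr(traj, "aa")) {
  stopifnot(inherits(traj, "edes_trajectory"))
  ref <- attr(traj, "params")
  if (!identical(unclass(params)[sort(names(unclass(params)))],
                 unclass(ref)[sort(names(unclass(ref)))]))
    stop("params do not match the parameters the trajectory was simulated with")
  core <- edes_core(params, meal, aa,
                    clamp_nonneg = attr(traj, "solver")$clamp_nonneg)
  n <- nrow(traj)
  states <- as.matrix(as.data.frame(traj)[, STATE_NAMES])
  flux_names <- c("glucose_gut_appearance", "endogenous_glucose_production",
                  "insulin_independent_uptake", "insulin_dependent_uptake",
                  "renal_excretion", "insulin_secretion",
                  "insulin_clearance", "insulin_transfer")
  out <- matrix(NA_real_, n, length(flux_names) + 2L,
                dimnames = list(NULL, c(flux_names, "dG_dt", "dI_dt")))
  for (i in seq_len(n)) {
    ev <- core(traj$time[i], states[i, ])
    out[i, flux_names] <- ev$fluxes[flux_names]
    out[i, "dG_dt"] <- ev$deriv[2L]
    out[i, "dI_dt"] <- ev$deriv[3L]
  }
  structure(cbind(data.frame(time = traj$time), as.data.frame(out)),
            class = c("flux_trajectory", "data.frame"),
            params = params, meal = meal, aa = aa)
}

#' Compare two flux decompositions
#'
#' Pointwise differences (`a - b`) between two flux trajectories on the
#' same time grid, with a per-flux summary: peak difference (largest in
#' magnitude, signed), its time, and the incremental (trapezoidal) area
#' of the difference.
#'
#' @param flux_a,flux_b [compute_fluxes()] results on identical grids.
#' @return List with `differences` (data frame, time by flux) and
#'   `summary` (data frame: flux, peak_difference, t_peak,
#'   incremental_area).
#' @export
compare_fluxes <- function(flux_a, flux_b) {
  stopifnot(inherits(flux_a, "flux_trajectory"),
            inherits(flux_b, "flux_trajectory"))
  if (nrow(flux_a) != nrow(flux_b) || any(flux_a$time != flux_b$time))
    stop("flux trajectories are on different time grids")
  flux_cols <- setdiff(names(flux_a), c("time", "dG_dt", "dI_dt"))
  diffs <- data.frame(time = flux_a$time)
  summ <- data.frame(flux = flux_cols, peak_difference = NA_real_,
                     t_peak = NA_real_, incremental_area = NA_real_)
  for (j in seq_along(flux_cols)) {
    d <- flux_a[[flux_cols[j]]] - flux_b[[flux_cols[j]]]
    diffs[[flux_cols[j]]] <- d
    ip <- which.max(abs(d))
    summ$peak_difference[j] <- d[ip]
    summ$t_peak[j] <- flux_a$time[ip]
    summ$incremental_area[j] <- pracma::trapz(flux_a$time, d)
  }
  list(differences = diffs, summary = summ)
}

#' Export fluxes as tidy CSV
#'
#' Long format: `time`, `flux_name`, `value`.
#'
#' @param fluxes A `flux_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fluxes <- function(fluxes, path) {
  stopifnot(inherits(fluxes, "flux_trajectory"))
  flux_cols <- setdiff(names(fluxes), c("time", "dG_dt", "dI_dt"))
  long <- do.call(rbind, lapply(flux_cols, function(nm)
    data.frame(time = fluxes$time, flux_name = nm, value = fluxes[[nm]])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
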