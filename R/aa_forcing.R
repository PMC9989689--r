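#' Plasma amino-acid time series
#'
#' A sampled plasma amino-acid concentration series: strictly increasing
#' sampling times starting at 0 min and non-negative concentrations
#' (mmol/L by package convention). Either a single amino acid or the
#' pointwise total over a panel (`"tAA"`).
#'
#' @param name Identifier, e.g. `"leucine"` or `"tAA"`.
#' @param times Sampling times (min), strictly increasing, first element 0.
#' @param concentrations Concentrations at `times` (mmol/L), non-negative.
#' @return An object of class `aa_series`.
#' @export
#' @examples
#' aa_series("leucine", c(0, 30, 60), c(0.14, 0.45, 0.30))
aa_series <- function(name, times, concentrations) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations))
    stop("times and concentrations differ in length")
  if (length(times) < 1L) stop("empty series")
  if (any(!is.finite(times)) || any(!is.finite(concentrations)))
    stop("non-finite values in series '", name, "'")
  if (times[1L] != 0)
    stop("series '", name, "' must start at t = 0 (basal sample)")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing in series '", name, "'")
  if (any(concentrations < 0))
    stop("negative concentration in series '", name, "'")
  structure(list(name = as.character(name), times = times,
                 concentrations = concentrations),
            class = "aa_series")
}

#' @export
print.aa_series <- function(x, ...) {
  cat(sprintf("<aa_series '%s'> %d samples over [0, %g] min, range [%.3g, %.3g]\n",
              x$name, length(x$times), max(x$times),
              min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

#' Total amino acids
#'
#' Pointwise sum of several amino-acid series measured on one identical
#' time grid, returned as a series named `"tAA"`. Grids must match
#' exactly; no silent resampling is performed.
#'
#' @param series_list List of [aa_series()] objects on a common grid.
#' @return An `aa_series` named `"tAA"`.
#' @export
total_aa <- function(series_list) {
  if (inherits(series_list, "aa_series")) series_list <- list(series_list)
  if (length(series_list) < 1L) stop("no series supplied")
  stopifnot(all(vapply(series_list, inherits, TRUE, "aa_series")))
  ref <- series_list[[1L]]$times
  for (s in series_list) {
    if (length(s$times) != length(ref) || any(s$times != ref))
      stop("time grid of series '", s$name,
           "' does not match the first series; resample before summing")
  }
  tot <- Reduce(`+`, lapply(series_list, `[[`, "concentrations"))
  aa_series("tAA", ref, tot)
}

#' Amino-acid forcing function
#'
#' Build the continuous plasma amino-acid input AA(t) and its first
#' derivative from a sampled series, using a shape-preserving piecewise
#' cubic Hermite interpolant (Fritsch-Carlson, `stats::splinefun`
#' `method = "monoH.FC"`). The interpolant passes exactly through every
#' knot, is C1 on the sampled window, and does not overshoot local data
#' extrema. Beyond the last knot (and before the first) the forcing is
#' extended as a constant with zero derivative, so the ODE solver may
#' overshoot the sampled window without fabricating dynamics.
#'
#' @param series An [aa_series()] with at least 2 knots.
#' @return An object of class `aa_forcing`: list with callables `value(t)`
#'   and `deriv(t)` (both vectorized), the knot `series`, and `t_last`.
#' @export
#' @examples
#' f <- aa_forcing(aa_series("tAA", c(0, 30, 60), c(2.5, 4.0, 3.2)))
#' f$value(15); f$deriv(15)
#' f$value(90)   # == 3.2, constant beyond the last knot
aa_forcing <- function(series) {
  stopifnot(inherits(series, "aa_series"))
  if (length(series$times) < 2L)
    stop("at least 2 knots are required to build a forcing function")
  sf <- stats::splinefun(series$times, series$concentrations,
                         method = "monoH.FC")
  t0 <- series$times[1L]
  t1 <- series$times[length(series$times)]
  c0 <- series$concentrations[1L]
  c1 <- series$concentrations[length(series$concentrations)]
  value <- function(t) {
    out <- sf(pmin(pmax(t, t0), t1))
    out[t <= t0] <- c0
    out[t >= t1] <- c1
    out
  }
  deriv <- function(t) {
    out <- sf(pmin(pmax(t, t0), t1), deriv = 1L)
    out[t < t0 | t > t1] <- 0
    out
  }
  structure(list(value = value, deriv = deriv, series = series,
                 t_last = t1),
            class = "aa_forcing")
}

#' Constant amino-acid forcing
#'
#' Forcing fixed at one level with zero derivative everywhere; used for
#' basal (no-challenge) scenarios.
#'
#' @param level Concentration (mmol/L).
#' @param t_last End of the nominal window (min).
#' @return An `aa_forcing` object.
#' @export
aa_forcing_constant <- function(level, t_last = 300) {
  aa_forcing(aa_series("constant", c(0, t_last), c(level, level)))
}

#' @export
print.aa_forcing <- function(x, ...) {
  cat(sprintf("<aa_forcing> '%s', %d knots on [0, %g] min; constant beyond t_last\n",
              x$series$name, length(x$series$times), x$t_last))
  invisible(x)
}
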