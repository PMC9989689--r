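#' Akaike information criterion from a least-squares fit
#'
#' For a Gaussian least-squares fit with unknown residual variance the
#' criterion reduces (up to an additive constant shared by all candidate
#' models on the same data) to
#' \deqn{AIC = N \ln(SSR/N) + 2K}
#' with `N` observations and `K` estimated parameters.
#'
#' @param ssr Sum of squared (weighted) residuals, strictly positive.
#' @param n_obs Number of fitted observations (glucose and insulin
#'   pooled).
#' @param k_free Number of estimated parameters.
#' @return The criterion value (lower is preferred).
#' @export
#' @examples
#' aic_ssr(13 * exp(2), 13, 4)   # 13*2 + 8 = 34
aic_ssr <- function(ssr, n_obs, k_free) {
  check_ic_args(ssr, n_obs, k_free)
  n_obs * log(ssr / n_obs) + 2 * k_free
}

#' Bayesian information criterion from a least-squares fit
#'
#' \deqn{BIC = N \ln(SSR/N) + \ln(N) K}
#'
#' @inheritParams aic_ssr
#' @return The criterion value (lower is preferred).
#' @export
bic_ssr <- function(ssr, n_obs, k_free) {
  check_ic_args(ssr, n_obs, k_free)
  n_obs * log(ssr / n_obs) + log(n_obs) * k_free
}

check_ic_args <- function(ssr, n_obs, k_free) {
  if (!is.numeric(ssr) || ssr <= 0)
    stop("information criteria are undefined at SSR <= 0 ",
         "(report a perfect fit separately)")
  if (n_obs < 1) stop("n_obs must be at least 1")
  if (k_free < 0) stop("k_free must be non-negative")
  invisible(NULL)
}

#' Compare base and amino-acid-extended fits of one dataset
#'
#' Adjudicates between an `EDES` fit and an `EDES_PROT` fit of the same
#' dataset using AIC and BIC. Deltas are extended-minus-base, so negative
#' deltas favor the amino-acid extension; per criterion the preferred
#' model is the one with the lower value (ties go to the base model,
#' which has fewer parameters).
#'
#' @param fit_edes [fit_dataset()] result for the base variant.
#' @param fit_prot [fit_dataset()] result for the extended variant.
#' @return An object of class `model_comparison` with elements
#'   `delta_aic`, `delta_bic`, `preferred` (per-criterion), and both fits.
#' @export
compare_models <- function(fit_edes, fit_prot) {
  stopifnot(inherits(fit_edes, "edes_fit"), inherits(fit_prot, "edes_fit"))
  if (fit_edes$scenario$variant != "EDES" ||
      fit_prot$scenario$variant != "EDES_PROT")
    stop("expected an EDES fit and an EDES_PROT fit, in that order")
  same_data <- identical(fit_edes$dataset$glucose_obs,
                         fit_prot$dataset$glucose_obs) &&
    identical(fit_edes$dataset$insulin_obs, fit_prot$dataset$insulin_obs) &&
    identical(fit_edes$dataset$subject_id, fit_prot$dataset$subject_id)
  if (!same_data)
    stop("the two fits were not obtained on the same dataset")
  delta_aic <- fit_prot$aic - fit_edes$aic
  delta_bic <- fit_prot$bic - fit_edes$bic
  pref <- function(delta) if (is.finite(delta) && delta < 0) "EDES_PROT" else "EDES"
  structure(list(fit_edes = fit_edes, fit_prot = fit_prot,
                 delta_aic = delta_aic, delta_bic = delta_bic,
                 preferred = c(aic = pref(delta_aic),
                               bic = pref(delta_bic))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> dataset '%s'\n", x$fit_edes$dataset$subject_id))
  cat(sprintf("  SSR: EDES %.5g vs EDES_PROT %.5g\n",
              x$fit_edes$ssr, x$fit_prot$ssr))
  cat(sprintf("  delta AIC = %+.3f -> %s;  delta BIC = %+.3f -> %s\n",
              x$delta_aic, x$preferred[["aic"]],
              x$delta_bic, x$preferred[["bic"]]))
  invisible(x)
}

#' Summarize comparisons across challenges
#'
#' Mean per-challenge AIC and BIC for both variants plus preference
#' counts, the form in which multi-challenge results are reported.
#'
#' @param comparisons List of [compare_models()] results.
#' @return Data frame with one row per criterion.
#' @export
summarize_comparisons <- function(comparisons) {
  stopifnot(length(comparisons) > 0L,
            all(vapply(comparisons, inherits, TRUE, "model_comparison")))
  g <- function(f) vapply(comparisons, f, 0)
  data.frame(
    criterion = c("aic", "bic"),
    edes = c(mean(g(function(x) x$fit_edes$aic)),
             mean(g(function(x) x$fit_edes$bic))),
    edes_prot = c(mean(g(function(x) x$fit_prot$aic)),
                  mean(g(function(x) x$fit_prot$bic))),
    n_prefer_prot = c(
      sum(vapply(comparisons, function(x)
        x$preferred[["aic"]] == "EDES_PROT", TRUE)),
      sum(vapply(comparisons, function(x)
        x$preferred[["bic"]] == "EDES_PROT", TRUE))),
    n = length(comparisons))
}
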