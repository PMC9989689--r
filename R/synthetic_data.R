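# Sampling grids of the two study families: free-AA challenges sample
# densely over 150 min, protein ingredients and dairy products over 300.
GRID_AA <- c(0, seq(10, 120, by = 10), 150)
GRID_MEAL <- c(0, seq(15, 120, by = 15), 150, 180, 210, 240, 300)

# design-specific defaults: AA curve shape and glucose-equivalent dose.
# Free AAs are absorbed fast (early, narrow tAA peak); intact protein is
# digested slowly (later, broader peak); dairy adds carbohydrate.
DESIGN_DEFAULTS <- list(
  AA_ONLY = list(grid = GRID_AA, dose = 0,
                 curve = c(baseline = 2.5, amplitude = 1.5,
                           t_peak = 40, decay = 30)),
  AA_PLUS_GLUCOSE = list(grid = GRID_AA, dose = 25000,
                         curve = c(baseline = 2.5, amplitude = 1.5,
                                   t_peak = 40, decay = 30)),
  PROTEIN_INGREDIENT = list(grid = GRID_MEAL, dose = 0,
                            curve = c(baseline = 2.5, amplitude = 1.3,
                                      t_peak = 60, decay = 50)),
  DAIRY = list(grid = GRID_MEAL, dose = 30000,
               curve = c(baseline = 2.5, amplitude = 1.2,
                         t_peak = 90, decay = 70)))

#' Synthetic challenge design
#'
#' Describes one synthetic meal challenge: the sampling grid and glucose
#' dose of the study family, the shape of the total plasma amino-acid
#' excursion, the generating ("true") parameters, and the measurement
#' noise level per channel (coefficient of variation of multiplicative
#' Gaussian noise, at most 0.2).
#'
#' Designs `AA_ONLY` and `AA_PLUS_GLUCOSE` sample at
#' 0, 10, ..., 120, 150 min; `PROTEIN_INGREDIENT` and `DAIRY` at
#' 0, 15, ..., 240, 300 min.
#'
#' @param design One of `"AA_ONLY"`, `"AA_PLUS_GLUCOSE"`,
#'   `"PROTEIN_INGREDIENT"`, `"DAIRY"`.
#' @param aa_curve_params Named vector `baseline`, `amplitude` (mmol/L),
#'   `t_peak`, `decay` (min); defaults depend on the design.
#' @param glucose_dose_mg Glucose-equivalent carbohydrate dose; default
#'   depends on the design (25 g for AA+glucose, 30 g for dairy).
#' @param true_params Generating [edes_params()].
#' @param noise_cv Named list `glucose`, `insulin`, `aa` of CVs in
#'   `[0, 0.2]`.
#' @param seed RNG seed used by [generate_dataset()].
#' @return An object of class `synthetic_design`.
#' @export
#' @examples
#' synthetic_design("AA_ONLY", seed = 7)
synthetic_design <- function(design = c("AA_ONLY", "AA_PLUS_GLUCOSE",
                                        "PROTEIN_INGREDIENT", "DAIRY"),
                             aa_curve_params = NULL,
                             glucose_dose_mg = NULL,
                             true_params = population_params(),
                             noise_cv = list(glucose = 0.02,
                                             insulin = 0.06, aa = 0.03),
                             seed = 1L) {
  design <- match.arg(design)
  def <- DESIGN_DEFAULTS[[design]]
  if (is.null(aa_curve_params)) aa_curve_params <- def$curve
  req <- c("baseline", "amplitude", "t_peak", "decay")
  if (!all(req %in% names(aa_curve_params)))
    stop("aa_curve_params needs: ", paste(req, collapse = ", "))
  if (is.null(glucose_dose_mg)) glucose_dose_mg <- def$dose
  stopifnot(inherits(true_params, "edes_params"))
  for (ch in c("glucose", "insulin", "aa")) {
    v <- noise_cv[[ch]]
    if (is.null(v) || v < 0 || v > 0.2)
      stop("noise_cv$", ch, " must lie in [0, 0.2]")
  }
  structure(list(design = design, sampling_grid = def$grid,
                 aa_curve_params = aa_curve_params,
                 glucose_dose_mg = glucose_dose_mg,
                 true_params = true_params, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Synthetic total-AA excursion
#'
#' Gamma-shaped rise-and-decay curve
#' \deqn{AA(t) = b + A (t/t_p)^{t_p/\tau} e^{(t_p - t)/\tau}}
#' anchored at the baseline at t = 0, with a single interior maximum of
#' height `amplitude` above baseline at `t_peak`, sampled on the design
#' grid. Emulates the measured postprandial total-AA input curves.
#'
#' @param design A [synthetic_design()].
#' @return An [aa_series()] named `"tAA"`.
#' @export
make_aa_curve <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  p <- design$aa_curve_params
  t <- design$sampling_grid
  conc <- p[["baseline"]] + aa_pulse(t, p[["amplitude"]], p[["t_peak"]],
                                     p[["decay"]])
  aa_series("tAA", t, conc)
}

# the dimensionless pulse (t/tp)^(tp/tau) * exp((tp-t)/tau): 0 at t = 0,
# peak value `A` exactly at t = tp
aa_pulse <- function(t, A, tp, tau) {
  t <- pmax(t, 0)
  A * (t / tp)^(tp / tau) * exp((tp - t) / tau)
}

#' Generate a synthetic challenge dataset
#'
#' Simulates the amino-acid-extended model at the design's true
#' parameters, with the forcing built from the noise-free synthetic AA
#' curve, samples glucose and insulin on the design grid, and applies
#' independent multiplicative Gaussian noise per channel. The t = 0
#' samples are left noise-free because the calibration defines the basal
#' values from them.
#'
#' @param design A [synthetic_design()].
#' @return A [challenge_dataset()] carrying the design and the true
#'   parameters as attributes `design` and `true_params` (for recovery
#'   studies).
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_design("AA_ONLY", seed = 3))
#' ds
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  aa_clean <- make_aa_curve(design)
  meal <- meal_spec(design$glucose_dose_mg,
                    description = design$design)
  p <- design$true_params
  p$AA_b_pl <- aa_clean$concentrations[1L]
  traj <- simulate_edes(p, meal, aa_forcing(aa_clean),
                        design$sampling_grid, rtol = 1e-8, atol = 1e-10)
  noisy <- function(x, cv) {
    if (cv == 0) return(x)
    fac <- 1 + cv * stats::rnorm(length(x))
    fac[1L] <- 1  # t = 0 defines basal values, kept noise-free
    x * fac
  }
  g <- noisy(traj$G_pl, design$noise_cv$glucose)
  i <- noisy(traj$I_pl, design$noise_cv$insulin)
  a <- pmax(noisy(aa_clean$concentrations, design$noise_cv$aa), 0)
  ds <- challenge_dataset(
    subject_id = sprintf("synthetic_%s_seed%d", design$design, design$seed),
    meal = meal,
    aa = aa_series("tAA", design$sampling_grid, a),
    glucose_obs = data.frame(time = design$sampling_grid, value = g),
    insulin_obs = data.frame(time = design$sampling_grid, value = i))
  attr(ds, "design") <- design
  attr(ds, "true_params") <- p
  ds
}

#' Generate a synthetic cohort
#'
#' Per-subject heterogeneity around a template design: log-normal jitter
#' (given CV) of the basal glucose/insulin levels, of the AA-curve
#' baseline, amplitude and timing, and of the freeable rate constants.
#' With zero jitter every subject reduces to [generate_dataset()] of the
#' template (up to the per-subject seed).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param design_template A [synthetic_design()].
#' @param seed Cohort-level seed.
#' @param jitter_cv Log-normal coefficient of variation (default 0.1).
#' @return List of [challenge_dataset()] objects.
#' @export
make_cohort <- function(n_subjects, design_template, seed = 1L,
                        jitter_cv = 0.1) {
  stopifnot(n_subjects >= 1L, inherits(design_template, "synthetic_design"))
  set.seed(seed)
  sdlog <- sqrt(log(1 + jitter_cv^2))
  lnorm1 <- function(n) if (jitter_cv == 0) rep(1, n) else
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  jitter_params <- c(FREE_PARAM_NAMES, "G_b_pl", "I_b_pl")
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    des <- design_template
    fac <- stats::setNames(lnorm1(length(jitter_params)), jitter_params)
    tp <- des$true_params
    for (nm in jitter_params) tp[[nm]] <- tp[[nm]] * fac[[nm]]
    des$true_params <- tp
    cfac <- lnorm1(3L)
    des$aa_curve_params[c("baseline", "amplitude", "t_peak")] <-
      des$aa_curve_params[c("baseline", "amplitude", "t_peak")] * cfac
    des$seed <- as.integer((seed * 1000L + s) %% .Machine$integer.max)
    out[[s]] <- generate_dataset(des)
    out[[s]]$subject_id <- sprintf("S%02d_%s", s, design_template$design)
  }
  out
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("<synthetic_design %s> %d samples to %g min; dose %g mg; AA peak +%g mmol/L at %g min; noise CV g/i/aa = %g/%g/%g; seed %d\n",
              x$design, length(x$sampling_grid), max(x$sampling_grid),
              x$glucose_dose_mg, x$aa_curve_params[["amplitude"]],
              x$aa_curve_params[["t_peak"]], x$noise_cv$glucose,
              x$noise_cv$insulin, x$noise_cv$aa, x$seed))
  invisible(x)
}
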