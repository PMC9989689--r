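#' Meal descriptor
#'
#' @param D_glucose Oral glucose (glucose-equivalent carbohydrate) dose in
#'   mg; 0 for protein/AA-only challenges.
#' @param t_meal Ingestion time (min), default 0.
#' @param description Free-text label.
#' @return An object of class `meal_spec`.
#' @export
#' @examples
#' meal_spec(25000, description = "25 g glucose")
meal_spec <- function(D_glucose = 0, t_meal = 0, description = "") {
  D_glucose <- as.numeric(D_glucose)
  if (!is.finite(D_glucose) || D_glucose < 0)
    stop("D_glucose must be a non-negative dose in mg")
  structure(list(D_glucose = D_glucose, t_meal = as.numeric(t_meal),
                 description = as.character(description)),
            class = "meal_spec")
}

#' Gastric emptying rate
#'
#' Instantaneous stomach-to-gut glucose mass inflow following ingestion:
#' a Weibull-density pulse
#' \deqn{m(t) = \sigma k_1^{\sigma} t^{\sigma-1} e^{-(k_1 t)^{\sigma}} D}
#' which integrates to the full dose `D` over an infinite horizon. Zero at
#' and before the ingestion time (the shape exponent exceeds 1).
#'
#' @param t Time(s) since the start of the experiment (min), non-negative.
#' @param meal A [meal_spec()].
#' @param k1 Gastric-emptying rate constant (1/min).
#' @param sigma Weibull shape (> 1).
#' @return Mass inflow (mg/min), vectorized over `t`.
#' @export
gastric_emptying_rate <- function(t, meal, k1, sigma) {
  stopifnot(inherits(meal, "meal_spec"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("negative time in gastric_emptying_rate")
  if (sigma <= 1) stop("sigma must exceed 1")
  tau <- t - meal$t_meal
  out <- numeric(length(t))
  pos <- tau > 0
  if (meal$D_glucose > 0 && any(pos)) {
    tp <- tau[pos]
    out[pos] <- sigma * k1^sigma * tp^(sigma - 1) *
      exp(-(k1 * tp)^sigma) * meal$D_glucose
  }
  out
}

#' Hepatic glucose production flux
#'
#' Endogenous glucose production (EGP): basal output, suppressed
#' proportionally by the plasma glucose excursion (k3) and by the
#' interstitial insulin signal (k4), stimulated proportionally by the
#' plasma amino-acid excursion (k11):
#' \deqn{g_{liv} = g^{b}_{liv} - k_3 (G - G_b) - k_4 \beta I_{if}
#'       + k_{11} (AA - AA_b)}
#' The interstitial state is in deviation form (basal value 0), so the
#' flux equals `g_b_liv` at the basal point. The flux is signed and not
#' clamped at zero by default.
#'
#' @param G_pl Plasma glucose (mmol/L).
#' @param I_if Interstitial insulin signal (mU/L, deviation form).
#' @param AA_pl Plasma amino-acid concentration (mmol/L).
#' @param params An [edes_params()] object.
#' @return EGP flux (mmol/L/min), vectorized.
#' @export
hepatic_glucose_flux <- function(G_pl, I_if, AA_pl, params) {
  stopifnot(inherits(params, "edes_params"))
  params$g_b_liv - params$k3 * (G_pl - params$G_b_pl) -
    params$k4 * params$constants$beta_conv * I_if +
    params$k11 * (AA_pl - params$AA_b_pl)
}

#' Pancreatic insulin secretion flux
#'
#' PID-type secretion controller on the glucose excursion, extended with
#' derivative (k12) and proportional (k13) amino-acid terms:
#' \deqn{i_{pnc} = \beta^{-1}\left[k_6 (G - G_b)
#'   + \frac{k_7}{\tau_i}\int (G - G_b)\,dt + \frac{k_7}{\tau_i} G_b
#'   + \frac{k_8}{\tau_d}\frac{dG}{dt}
#'   + k_{12}\frac{dAA}{dt} + k_{13} (AA - AA_b)\right]}
#' At basal arguments the deviation terms vanish and the constant
#' \eqn{(k_7/\tau_i) G_b} term remains (basal secretion).
#'
#' @param G_pl Plasma glucose (mmol/L).
#' @param Z_int Running integral of the glucose excursion (mmol.min/L).
#' @param dG_dt Plasma glucose derivative (mmol/L/min).
#' @param AA_pl Plasma amino acid (mmol/L).
#' @param dAA_dt Its derivative (mmol/L/min).
#' @param params An [edes_params()] object.
#' @return Secretion flux (mU/L/min), vectorized.
#' @export
pancreatic_secretion_flux <- function(G_pl, Z_int, dG_dt, AA_pl, dAA_dt,
                                      params) {
  stopifnot(inherits(params, "edes_params"))
  cn <- params$constants
  (1 / cn$beta_conv) * (
    params$k6 * (G_pl - params$G_b_pl) +
      (params$k7 / cn$tau_i) * Z_int +
      (params$k7 / cn$tau_i) * params$G_b_pl +
      (params$k8 / cn$tau_d) * dG_dt +
      params$k12 * dAA_dt +
      params$k13 * (AA_pl - params$AA_b_pl))
}

# State vector layout used throughout
STATE_NAMES <- c("M_gut", "G_pl", "I_pl", "I_if", "Z_int")

# Parameter vector for the compiled right-hand side (layout documented in
# src/edes.c). The forcing is shipped as knot times/values/slopes of the
# same Hermite interpolant the R path evaluates; the knot slopes are the
# interpolant's own derivative at the knots.
pack_parms <- function(params, meal, aa, clamp_nonneg) {
  cn <- params$constants
  kt <- aa$series$times
  n <- length(kt)
  pv <- numeric(31 + 3 * 256)
  pv[1:13] <- unlist(params[paste0("k", 1:13)])
  pv[14:17] <- c(params$g_b_liv, params$G_b_pl, params$I_b_pl,
                 params$AA_b_pl)
  pv[18:27] <- c(cn$sigma_shape, cn$K_M, cn$G_th_ren, cn$c1_ren, cn$V_G,
                 cn$beta_conv, cn$tau_i, cn$tau_d, cn$f_conv, cn$M_b)
  pv[28:30] <- c(meal$D_glucose, meal$t_meal, as.numeric(clamp_nonneg))
  pv[31] <- n
  pv[31 + seq_len(n)] <- kt
  pv[31 + n + seq_len(n)] <- aa$series$concentrations
  pv[31 + 2 * n + seq_len(n)] <- aa$deriv(kt)
  pv
}

# Build the core derivative/flux evaluator as a closure with everything
# unpacked, so the ODE right-hand side stays cheap inside the solver.
# Returns function(t, y) -> list(deriv = numeric(5), fluxes = numeric(...)).
# Each algebraic flux form lives on its own named line so any one of them
# can be corrected without touching the rest.
edes_core <- function(params, meal, aa, clamp_nonneg = FALSE) {
  validate_params(params)
  stopifnot(inherits(meal, "meal_spec"), inherits(aa, "aa_forcing"))
  cn <- params$constants
  sigma <- cn$sigma_shape; K_M <- cn$K_M; G_th <- cn$G_th_ren
  c1r <- cn$c1_ren; V_G <- cn$V_G; beta <- cn$beta_conv
  tau_i <- cn$tau_i; tau_d <- cn$tau_d; f <- cn$f_conv; M_b <- cn$M_b
  k1 <- params$k1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  k5 <- params$k5; k6 <- params$k6; k7 <- params$k7; k8 <- params$k8
  k9 <- params$k9; k10 <- params$k10; k11 <- params$k11
  k12 <- params$k12; k13 <- params$k13
  g_b_liv <- params$g_b_liv; G_b <- params$G_b_pl; I_b <- params$I_b_pl
  AA_b <- params$AA_b_pl
  D <- meal$D_glucose; t_meal <- meal$t_meal
  aa_val <- aa$value; aa_der <- aa$deriv
  c_nonit <- g_b_liv * (K_M + G_b) / G_b  # basal-normalized uptake scale
  vgm <- V_G * M_b

  function(t, y) {
    M_gut <- y[[1L]]; G <- y[[2L]]; I <- y[[3L]]; I_if <- y[[4L]]; Z <- y[[5L]]
    AA <- aa_val(t); dAA <- aa_der(t)

    # (i) gut glucose balance
    tau <- t - t_meal
    m_meal <- if (D > 0 && tau > 0)
      sigma * k1^sigma * tau^(sigma - 1) * exp(-(k1 * tau)^sigma) * D
    else 0
    dM_gut <- m_meal - k2 * M_gut

    # (ii) plasma glucose balance
    g_gut <- f * k2 * M_gut / vgm                       # gut appearance
    g_liv <- g_b_liv - k3 * (G - G_b) - k4 * beta * I_if +
      k11 * (AA - AA_b)                                 # EGP
    if (clamp_nonneg && g_liv < 0) g_liv <- 0
    g_nonit <- c_nonit * G / (K_M + G)                  # insulin-independent
    g_it <- k5 * beta * I_if * G / (K_M + G)            # insulin-dependent
    g_ren <- if (G > G_th) c1r / vgm * (G - G_th) else 0 # renal excretion
    dG <- g_gut + g_liv - g_nonit - g_it - g_ren

    # (iii) plasma insulin balance; dG/dt enters Eq.2 by algebraic
    # substitution of the balance just evaluated (no finite differences)
    i_pnc <- (1 / beta) * (k6 * (G - G_b) + (k7 / tau_i) * Z +
                             (k7 / tau_i) * G_b + (k8 / tau_d) * dG +
                             k12 * dAA + k13 * (AA - AA_b))
    if (clamp_nonneg && i_pnc < 0) i_pnc <- 0
    i_liv <- (k7 * G_b / (beta * tau_i)) * I / I_b      # hepatic clearance
    i_trans <- k9 * (I - I_b)                           # to interstitium
    dI <- i_pnc - i_liv - i_trans

    # (iv) interstitial insulin balance (first-order removal)
    dI_if <- i_trans - k10 * I_if

    list(deriv = c(dM_gut, dG, dI, dI_if, G - G_b),
         fluxes = c(glucose_gut_appearance = g_gut,
                    endogenous_glucose_production = g_liv,
                    insulin_independent_uptake = g_nonit,
                    insulin_dependent_uptake = g_it,
                    renal_excretion = g_ren,
                    insulin_secretion = i_pnc,
                    insulin_clearance = i_liv,
                    insulin_transfer = i_trans))
  }
}

#' Model right-hand side
#'
#' Evaluate the five coupled state derivatives (gut glucose mass, plasma
#' glucose, plasma insulin, interstitial insulin, running glucose-excursion
#' integral) at one time point. The glucose derivative feeding the
#' secretion controller is the just-computed plasma glucose balance.
#'
#' @param t Time (min).
#' @param state Named or ordered numeric state vector
#'   (`M_gut`, `G_pl`, `I_pl`, `I_if`, `Z_int`).
#' @param params An [edes_params()] object.
#' @param meal A [meal_spec()].
#' @param aa An [aa_forcing()].
#' @param clamp_nonneg Clamp EGP and secretion at zero (default `FALSE`,
#'   faithful to the signed flux equations).
#' @return Named numeric vector of the five time derivatives.
#' @export
edes_rhs <- function(t, state, params, meal, aa, clamp_nonneg = FALSE) {
  state <- as_state(state)
  core <- edes_core(params, meal, aa, clamp_nonneg)
  stats::setNames(core(t, state)$deriv, STATE_NAMES)
}

as_state <- function(state) {
  v <- unlist(state)
  if (!is.null(names(v)) && all(STATE_NAMES %in% names(v)))
    v <- v[STATE_NAMES]
  v <- as.numeric(v)
  if (length(v) != 5L) stop("state must have 5 components")
  v
}

#' Basal initial state
#'
#' The basal fixed point of the model: empty gut, plasma glucose and
#' insulin at their basal values, zero interstitial deviation and zero
#' excursion integral. With no meal and constant-basal AA forcing all
#' derivatives vanish there.
#'
#' @param params An [edes_params()] object.
#' @return Named numeric state vector.
#' @export
basal_state <- function(params) {
  stopifnot(inherits(params, "edes_params"))
  stats::setNames(c(0, params$G_b_pl, params$I_b_pl, 0, 0), STATE_NAMES)
}

#' Simulate a meal challenge
#'
#' Integrate the model with a stiff-capable variable-step solver
#' (`deSolve`, default `lsoda`) and sample the solution on `t_grid`.
#'
#' @param params An [edes_params()] object.
#' @param meal A [meal_spec()].
#' @param aa An [aa_forcing()].
#' @param t_grid Output times (min), starting at 0, strictly increasing.
#' @param init Initial state; defaults to [basal_state()].
#' @param rtol,atol Solver tolerances.
#' @param method `deSolve` integration method (stiff-capable by default).
#' @param clamp_nonneg See [edes_rhs()].
#' @param use_compiled Integrate the compiled (C) right-hand side rather
#'   than the interpreted one (default `TRUE`; both evaluate the same
#'   equations and the same interpolating polynomial, and the test suite
#'   checks their agreement).
#' @return An `edes_trajectory`: data frame with columns `time`, `M_gut`,
#'   `G_pl`, `I_pl`, `I_if`, `Z_int`, carrying the inputs as attributes.
#' @export
#' @examples
#' p <- population_params()
#' aa <- aa_forcing_constant(p$AA_b_pl)
#' tr <- simulate_edes(p, meal_spec(25000), aa, seq(0, 120, 5))
#' head(tr)
simulate_edes <- function(params, meal, aa, t_grid,
                          init = NULL, rtol = 1e-6, atol = 1e-8,
                          method = "lsoda", clamp_nonneg = FALSE,
                          use_compiled = TRUE) {
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 2L || t_grid[1L] != 0)
    stop("t_grid must start at 0 and contain at least two times")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (is.null(init)) init <- basal_state(params) else init <- as_state(init)
  if (init[1L] < 0) stop("initial gut glucose mass must be non-negative")
  n_knots <- length(aa$series$times)
  if (use_compiled && n_knots <= 256L) {
    validate_params(params)
    stopifnot(inherits(meal, "meal_spec"))
    out <- try(deSolve::ode(y = init, times = t_grid, func = "edes_derivs",
                            parms = pack_parms(params, meal, aa,
                                               clamp_nonneg),
                            dllname = "edesprot", initfunc = "edes_init",
                            method = method, rtol = rtol, atol = atol),
               silent = TRUE)
  } else {
    core <- edes_core(params, meal, aa, clamp_nonneg)
    rhs <- function(t, y, p) list(core(t, y)$deriv)
    out <- try(deSolve::ode(y = init, times = t_grid, func = rhs,
                            parms = NULL, method = method, rtol = rtol,
                            atol = atol),
               silent = TRUE)
  }
  if (inherits(out, "try-error"))
    stop("ODE solver failed: ", attr(out, "condition")$message)
  if (nrow(out) < length(t_grid) || any(!is.finite(out)))
    stop("ODE solver failed to cover the requested grid (istate = ",
         attr(out, "istate")[1L], "); try tighter tolerances")
  traj <- as.data.frame(out)
  names(traj) <- c("time", STATE_NAMES)
  structure(traj, class = c("edes_trajectory", "data.frame"),
            params = params, meal = meal, aa = aa,
            solver = list(rtol = rtol, atol = atol, method = method,
                          clamp_nonneg = clamp_nonneg))
}

#' @export
print.edes_trajectory <- function(x, ...) {
  cat(sprintf("<edes_trajectory> %d times on [0, %g] min; G_pl in [%.3g, %.3g] mmol/L, I_pl in [%.3g, %.3g] mU/L\n",
              nrow(x), max(x$time), min(x$G_pl), max(x$G_pl),
              min(x$I_pl), max(x$I_pl)))
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj An `edes_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "edes_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
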