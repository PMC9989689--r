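# Reference implementation of the BASE (glucose-only) model, coded
# directly from the published balance equations as an independent check
# on the packaged simulator: the package's reduction property (amino-acid
# parameters set to zero) must reproduce these trajectories to solver
# tolerance. Deliberately self-contained: no edesprot flux function is
# called here, only deSolve for the integration itself.
#
# Arguments are plain numerics; `par` is a named list carrying k1..k10,
# g_b_liv, G_b, I_b and the constants sigma, K_M, G_th, c1, V_G, beta,
# tau_i, tau_d, f, M_b.

simulate_base_edes_reference <- function(par, D_glucose_mg, t_grid,
                                         rtol = 1e-8, atol = 1e-10) {
  derivs <- function(t, y, p) {
    Mg <- y[[1]]; G <- y[[2]]; I <- y[[3]]; Q <- y[[4]]; Z <- y[[5]]
    emptying <- 0
    if (D_glucose_mg > 0 && t > 0)
      emptying <- par$sigma * par$k1^par$sigma * t^(par$sigma - 1) *
        exp(-(par$k1 * t)^par$sigma) * D_glucose_mg
    appearance <- par$f * par$k2 * Mg / (par$V_G * par$M_b)
    production <- par$g_b_liv - par$k3 * (G - par$G_b) -
      par$k4 * par$beta * Q
    uptake_ii <- par$g_b_liv * ((par$K_M + par$G_b) / par$G_b) *
      G / (par$K_M + G)
    uptake_id <- par$k5 * par$beta * Q * G / (par$K_M + G)
    renal <- max(0, par$c1 / (par$V_G * par$M_b) * (G - par$G_th))
    dG <- appearance + production - uptake_ii - uptake_id - renal
    secretion <- (par$k6 * (G - par$G_b) + (par$k7 / par$tau_i) * Z +
                    (par$k7 / par$tau_i) * par$G_b +
                    (par$k8 / par$tau_d) * dG) / par$beta
    clearance <- par$k7 * par$G_b / (par$beta * par$tau_i) * I / par$I_b
    transfer <- par$k9 * (I - par$I_b)
    list(c(emptying - par$k2 * Mg,
           dG,
           secretion - clearance - transfer,
           transfer - par$k10 * Q,
           G - par$G_b))
  }
  y0 <- c(0, par$G_b, par$I_b, 0, 0)
  out <- deSolve::ode(y0, t_grid, derivs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  data.frame(time = out[, 1], M_gut = out[, 2], G_pl = out[, 3],
             I_pl = out[, 4], I_if = out[, 5], Z_int = out[, 6])
}

# convenience: flatten an edesprot parameter object into the plain list
# layout above (kept here so the reference stays usable without the
# package attached, given any equivalent list)
reference_par_from_params <- function(params) {
  cn <- params$constants
  list(k1 = params$k1, k2 = params$k2, k3 = params$k3, k4 = params$k4,
       k5 = params$k5, k6 = params$k6, k7 = params$k7, k8 = params$k8,
       k9 = params$k9, k10 = params$k10, g_b_liv = params$g_b_liv,
       G_b = params$G_b_pl, I_b = params$I_b_pl,
       sigma = cn$sigma_shape, K_M = cn$K_M, G_th = cn$G_th_ren,
       c1 = cn$c1_ren, V_G = cn$V_G, beta = cn$beta_conv,
       tau_i = cn$tau_i, tau_d = cn$tau_d, f = cn$f_conv, M_b = cn$M_b)
}
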