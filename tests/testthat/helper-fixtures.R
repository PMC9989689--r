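# shared fixtures: everything is generated in code, nothing is stored.

# independent base-model simulator (reduction-equivalence oracle)
ref_env <- new.env()
source(system.file("validation", "base_edes_reference.R",
                   package = "edesprot"), local = ref_env)

# noise-free design shortcut
quiet_design <- function(design, seed = 1L, ...) {
  synthetic_design(design, seed = seed,
                   noise_cv = list(glucose = 0, insulin = 0, aa = 0), ...)
}

# truth distinct from the optimizer's population start, so recovery tests
# actually have to move
recovery_truth <- function() {
  population_params(k11 = 0.003 * 1.5, k12 = 3 * 0.6, k13 = 0.5 * 1.4)
}

# lean optimizer settings for tests: convergence well beyond the 1%-level
# precision the recovery checks need, without the long tail of iterations
test_optim <- minpack.lm::nls.lm.control(epsfcn = 1e-6, ptol = 1e-7,
                                         ftol = 1e-10, maxiter = 60)
test_solver <- edesprot:::fit_solver_control(rtol = 1e-7, atol = 1e-9)

# a small AA challenge forcing used across core-model tests
test_aa_forcing <- function(params = population_params()) {
  des <- quiet_design("AA_ONLY")
  aa_forcing(make_aa_curve(des))
}
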