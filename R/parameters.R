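#' Physiological model constants
#'
#' Fixed physiological constants of the glucose-insulin model: gastric
#' emptying shape, Michaelis constant for glucose uptake, renal threshold
#' and clearance, distribution volumes, insulin unit conversion, the
#' integral/derivative time constants of the pancreatic controller, the
#' mg-to-mmol glucose conversion, and body mass. All values strictly
#' positive; defaults are the average healthy population values shipped in
#' `inst/extdata/population_healthy.yaml`.
#'
#' @param M_b Body mass (kg).
#' @param ... Named overrides for any constant (see
#'   [population_config()] for the full list and units).
#' @return An object of class `edes_constants` (named list).
#' @export
#' @examples
#' cn <- edes_constants(M_b = 80)
#' cn$tau_i
edes_constants <- function(M_b = NULL, ...) {
  cfg <- population_config()
  cn <- cfg$constants
  if (!is.null(M_b)) cn$M_b <- M_b
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cn))
  if (length(unknown) > 0L)
    stop("unknown constant(s): ", paste(unknown, collapse = ", "))
  cn[names(dots)] <- dots
  cn <- lapply(cn, as.numeric)
  validate_constants(cn)
  structure(cn, class = "edes_constants")
}

validate_constants <- function(cn) {
  req <- c("sigma_shape", "K_M", "G_th_ren", "c1_ren", "V_G", "V_I",
           "beta_conv", "tau_i", "tau_d", "f_conv", "M_b")
  miss <- setdiff(req, names(cn))
  if (length(miss) > 0L)
    stop("missing constant(s): ", paste(miss, collapse = ", "))
  for (nm in req) {
    v <- cn[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("constant '", nm, "' must be a single positive number")
  }
  if (cn$sigma_shape <= 1)
    stop("sigma_shape must exceed 1 (gastric emptying vanishes at t = 0)")
  invisible(cn)
}

#' Model parameter vector
#'
#' Assemble the full parameter vector of the model: base rate constants
#' `k1`-`k10`, the amino-acid extension parameters `k11`-`k13`, the basal
#' endogenous glucose production `g_b_liv`, the basal plasma values
#' (`G_b_pl`, `I_b_pl`, `AA_b_pl`, conventionally the t = 0 observations),
#' and the physiological constants. Unspecified entries default to the
#' average healthy population values. Setting `k11 = k12 = k13 = 0`
#' reduces the model exactly to the base (glucose-only) formulation.
#'
#' @param ... Named overrides for any of `k1`-`k13`, `g_b_liv`, `G_b_pl`,
#'   `I_b_pl`, `AA_b_pl`.
#' @param constants An [edes_constants()] object.
#' @return An object of class `edes_params`.
#' @export
#' @examples
#' p <- edes_params(k11 = 0)           # no AA effect on the liver
#' p$k11
edes_params <- function(..., constants = edes_constants()) {
  cfg <- population_config()
  p <- c(cfg$parameters, cfg$basal)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p <- lapply(p, as.numeric)
  p$constants <- constants
  validate_params(p)
  structure(p, class = "edes_params")
}

#' @export
print.edes_params <- function(x, ...) {
  cat("<edes_params>\n")
  ks <- paste0("k", 1:13)
  cat("  ", paste(sprintf("%s=%.4g", ks, unlist(x[ks])), collapse = " "), "\n")
  cat(sprintf("  g_b_liv=%.4g  G_b_pl=%.4g mmol/L  I_b_pl=%.4g mU/L  AA_b_pl=%.4g mmol/L\n",
              x$g_b_liv, x$G_b_pl, x$I_b_pl, x$AA_b_pl))
  invisible(x)
}

validate_params <- function(p) {
  ks <- paste0("k", 1:13)
  req <- c(ks, "g_b_liv", "G_b_pl", "I_b_pl", "AA_b_pl")
  miss <- setdiff(req, names(p))
  if (length(miss) > 0L)
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  for (nm in req) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (any(unlist(p[ks]) < 0))
    stop("rate constants k1-k13 must be non-negative")
  for (nm in c("G_b_pl", "I_b_pl", "AA_b_pl"))
    if (p[[nm]] <= 0) stop("basal value '", nm, "' must be positive")
  validate_constants(p$constants)
  invisible(p)
}

#' Average healthy population configuration
#'
#' Read the versioned population configuration shipped with the package
#' (constants, rate constants, basal values, solver defaults), or a
#' user-supplied YAML file with the same layout.
#'
#' @param path Path to a YAML configuration; default is the packaged
#'   healthy-population file.
#' @return A list with elements `config_version`, `constants`,
#'   `parameters`, `basal`, `solver`.
#' @export
population_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "population_healthy.yaml",
                        package = "edesprot", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  for (blk in c("constants", "parameters", "basal"))
    cfg[[blk]] <- lapply(cfg[[blk]], as.numeric)
  cfg
}

#' Population parameter set
#'
#' Convenience wrapper returning [edes_params()] at the average healthy
#' population values, optionally with overrides.
#'
#' @inheritParams edes_params
#' @return An `edes_params` object.
#' @export
population_params <- function(..., constants = edes_constants()) {
  edes_params(..., constants = constants)
}

# names of the parameters the calibration may free
FREE_PARAM_NAMES <- c("k1", "k5", "k6", "k8", "k11", "k12", "k13")
AA_PARAM_NAMES <- c("k11", "k12", "k13")
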