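#' Read a meal-challenge dataset from CSV
#'
#' Expects columns `time_min`, `glucose_mmol_L`, `insulin_mU_L` (missing
#' values allowed except at t = 0) and at least one amino-acid column.
#' Several AA columns measured on the same grid are summed into a total
#' (`tAA`) series; a single column is used as-is. The meal descriptor is
#' read from a JSON sidecar `<path>_meta.json` written by
#' [write_dataset()], or taken from the `meal` argument.
#'
#' @param path CSV file.
#' @param meal Optional [meal_spec()] overriding the sidecar.
#' @param subject_id Optional identifier overriding the sidecar (defaults
#'   to the file name).
#' @return A [challenge_dataset()].
#' @export
read_dataset <- function(path, meal = NULL, subject_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("time_min", "glucose_mmol_L", "insulin_mU_L")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("'", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  aa_cols <- setdiff(names(df), req)
  if (length(aa_cols) == 0L)
    stop("'", path, "' has no amino-acid column")
  tm <- df$time_min
  if (any(!is.finite(tm)))
    stop("non-finite time_min in '", path, "'")
  bad <- which(diff(tm) <= 0)
  if (length(bad) > 0L)
    stop("time_min not strictly increasing at row ", bad[1L] + 1L,
         " of '", path, "'")
  if (tm[1L] != 0)
    stop("'", path, "' has no t = 0 row; basal values are undefined")
  for (cc in aa_cols) {
    neg <- which(df[[cc]] < 0)
    if (length(neg) > 0L)
      stop("negative concentration in column '", cc, "' at row ", neg[1L],
           " of '", path, "'")
  }
  aa <- if (length(aa_cols) == 1L)
    aa_series(aa_cols, tm, df[[aa_cols]])
  else
    total_aa(lapply(aa_cols, function(cc) aa_series(cc, tm, df[[cc]])))

  meta_path <- sidecar_path(path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  if (is.null(meal)) {
    meal <- meal_spec(D_glucose = meta$D_glucose %||% 0,
                      t_meal = meta$t_meal %||% 0,
                      description = meta$description %||% "")
  }
  if (is.null(subject_id))
    subject_id <- meta$subject_id %||% sub("\\.csv$", "", basename(path))
  challenge_dataset(
    subject_id = subject_id, meal = meal, aa = aa,
    glucose_obs = data.frame(time = tm, value = df$glucose_mmol_L),
    insulin_obs = data.frame(time = tm, value = df$insulin_mU_L))
}

#' Write a meal-challenge dataset to CSV
#'
#' Writes `time_min`, `glucose_mmol_L`, `insulin_mU_L` and the AA column
#' on the union time grid (missing observations as empty cells), plus a
#' JSON sidecar `<path>_meta.json` carrying the meal descriptor and
#' subject id. Round-trips through [read_dataset()].
#'
#' @param dataset A [challenge_dataset()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "challenge_dataset"))
  tm <- sort(unique(c(dataset$aa$times, dataset$glucose_obs$time,
                      dataset$insulin_obs$time)))
  df <- data.frame(time_min = tm)
  df$glucose_mmol_L <- dataset$glucose_obs$value[
    match(tm, dataset$glucose_obs$time)]
  df$insulin_mU_L <- dataset$insulin_obs$value[
    match(tm, dataset$insulin_obs$time)]
  df[[dataset$aa$name]] <- dataset$aa$concentrations[
    match(tm, dataset$aa$times)]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(subject_id = dataset$subject_id,
         D_glucose = dataset$meal$D_glucose,
         t_meal = dataset$meal$t_meal,
         description = dataset$meal$description),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", "", path) |>
  paste0("_meta.json")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline run configuration
#'
#' YAML with fields `data` (vector of dataset CSV paths), `out_dir`,
#' `seed`, `free_params_edes`, `free_params_prot`, `n_starts`,
#' `start_noise`, and optional `solver` overrides (`rtol`, `atol`,
#' `method`). Missing fields fall back to package defaults, so a run is
#' reproducible from the config and the data files alone.
#'
#' @param path YAML file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  defaults <- list(data = character(), out_dir = ".", seed = 1L,
                   free_params_edes = c("k1", "k5", "k6", "k8"),
                   free_params_prot = c("k1", "k5", "k6", "k8",
                                        "k11", "k12", "k13"),
                   n_starts = 25L, start_noise = 0.25,
                   solver = list(rtol = 1e-8, atol = 1e-10,
                                 method = "lsoda"))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg$data <- unlist(cfg$data)
  cfg$free_params_edes <- unlist(cfg$free_params_edes)
  cfg$free_params_prot <- unlist(cfg$free_params_prot)
  structure(cfg, class = "run_config")
}

#' Run the full calibration pipeline
#'
#' For every dataset: fit the base and the amino-acid-extended variant,
#' compare them by AIC/BIC, and decompose the extended fit into fluxes.
#' Writes per-dataset fit JSONs, a comparison CSV, flux CSVs, and a run
#' log capturing the seed and configuration. An empty dataset list is a
#' no-op with a warning.
#'
#' @param config A `run_config` list ([read_run_config()]) or path to a
#'   YAML configuration.
#' @return A list of per-dataset results (fits, comparison, fluxes),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- as_run_config(config)
  if (length(config$data) == 0L) {
    warning("no datasets configured; nothing to do")
    return(invisible(list()))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  solver <- do.call(fit_solver_control, config$solver)
  results <- list()
  comp_rows <- list()
  log_lines <- c(sprintf("edesprot %s pipeline",
                         as.character(utils::packageVersion("edesprot"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("datasets: %d", length(config$data)))
  for (i in seq_along(config$data)) {
    ds <- read_dataset(config$data[i])
    sc_e <- scenario_config("EDES", config$free_params_edes,
                            n_starts = config$n_starts,
                            start_noise = config$start_noise,
                            seed = config$seed + i)
    sc_p <- scenario_config("EDES_PROT", config$free_params_prot,
                            n_starts = config$n_starts,
                            start_noise = config$start_noise,
                            seed = config$seed + i)
    fe <- fit_dataset(ds, sc_e, solver = solver)
    fp <- fit_dataset(ds, sc_p, solver = solver)
    cmp <- compare_models(fe, fp)
    flx <- compute_fluxes(fp$trajectory)
    base <- file.path(config$out_dir, ds$subject_id)
    write_fit_json(fe, paste0(base, "_edes_fit.json"))
    write_fit_json(fp, paste0(base, "_edes_prot_fit.json"))
    write_fluxes(flx, paste0(base, "_fluxes.csv"))
    comp_rows[[i]] <- data.frame(
      subject_id = ds$subject_id,
      ssr_edes = fe$ssr, ssr_prot = fp$ssr,
      aic_edes = fe$aic, aic_prot = fp$aic,
      bic_edes = fe$bic, bic_prot = fp$bic,
      delta_aic = cmp$delta_aic, delta_bic = cmp$delta_bic,
      preferred_aic = cmp$preferred[["aic"]],
      preferred_bic = cmp$preferred[["bic"]])
    log_lines <- c(log_lines,
                   sprintf("%s: SSR %.6g (EDES) vs %.6g (EDES_PROT), dAIC %+.3f",
                           ds$subject_id, fe$ssr, fp$ssr, cmp$delta_aic))
    results[[ds$subject_id]] <- list(fit_edes = fe, fit_prot = fp,
                                     comparison = cmp, fluxes = flx)
  }
  comp <- do.call(rbind, comp_rows)
  utils::write.csv(comp, file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(results)
}

#' Serialize a fit as JSON
#'
#' Full precision (no rounding); includes the estimates, SSR, AIC/BIC,
#' per-start outcomes, and the scenario.
#'
#' @param fit An `edes_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "edes_fit"))
  p <- unclass(fit$best_params)
  p$constants <- unclass(p$constants)
  jsonlite::write_json(
    list(variant = fit$scenario$variant,
         subject_id = fit$dataset$subject_id,
         free_params = fit$scenario$free_params,
         estimates = as.list(fit$free_values),
         ssr = fit$ssr, n_obs = fit$n_obs, k_free = fit$k_free,
         aic = fit$aic, bic = fit$bic,
         per_start = fit$per_start,
         parameters = p),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
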