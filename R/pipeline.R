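#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with the
#' package defaults filled in. A YAML file with the same structure can
#' override any subset of values.
#'
#' @return A nested list with sections `seed`, `synthetic`, `fitting`,
#'   `translation`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthetic = list(noise_cv = 0.2),
    fitting = list(ka_fixed = 2.7, n_starts = 5),
    translation = list(human_cl = 0.020, human_vss = 0.21, f_oral = 0.6,
                       ka = 0.35, body_weight = 70, interval = 24,
                       efficacious_dose = 25, efficacious_interval = 12)
  )
}

# merge a partial config into the defaults, recursively
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

read_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be NULL, a list, or a YAML path")
  cfg <- merge_config(default_config(), config)
  for (section in c("synthetic", "fitting", "translation"))
    if (!is.list(cfg[[section]]))
      stop(sprintf("configuration section '%s' is missing or malformed",
                   section))
  cfg
}

#' Run the full translational workflow
#'
#' Executes the pipeline end to end: species reference tables, hepatocyte
#' IVIVE, human PK prediction by the scaling methods, synthetic study
#' generation, sequential PK then PD fitting, validation against a held-out
#' long-term study, biomarker target derivation, and human dose projection.
#' All stage outputs are written as CSV files under `out_dir`; numeric
#' outputs are deterministic given the configuration.
#'
#' @param config `NULL` (defaults), a configuration list, or the path to a
#'   YAML file (see [default_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with all stage results and `files`, the paths
#'   written.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("pipeline")) {
  cfg <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files[[name]] <<- path
    path
  }

  records <- species_records()
  put(records, "species.csv")

  ivive <- ivive_clearance(records)
  put(ivive, "ivive.csv")

  human <- predict_human_pk(records)
  put(cbind(human$methods,
            data.frame(cl_mean = human$cl_mean, cl_sd = human$cl_sd,
                       vss_mean = human$vss_mean, vss_sd = human$vss_sd,
                       t_half = human$t_half)),
      "human_pk.csv")

  pk_true <- mouse_pk_params()
  pd_true <- mouse_pd_params()
  s1 <- generate_study(design_pkpd01(), pk_true, pd_true,
                       cfg$synthetic$noise_cv, seed = cfg$seed)
  s2 <- generate_study(design_pkpd02(), pk_true, pd_true,
                       cfg$synthetic$noise_cv, seed = cfg$seed + 500000L)
  conc <- pool_studies(list(s1, s2), "conc_obs")
  pdo <- pool_studies(list(s1, s2), "pd_obs")
  put(conc, "conc_observations.csv")
  put(pdo, "pd_observations.csv")

  pk_fit <- fit_pk(conc, fixed = c(ka = cfg$fitting$ka_fixed),
                   n_starts = cfg$fitting$n_starts)
  pd_fit <- suppressWarnings(
    fit_pd(pdo, fitted_pk_params(pk_fit), n_starts = cfg$fitting$n_starts))
  param_tab <- data.frame(
    parameter = c(names(pk_fit$fixed), names(pk_fit$estimates),
                  names(pd_fit$estimates)),
    estimate = c(unname(pk_fit$fixed), unname(pk_fit$estimates),
                 unname(pd_fit$estimates)),
    cv_percent = c(rep(NA_real_, length(pk_fit$fixed)),
                   unname(pk_fit$cv_percent), unname(pd_fit$cv_percent)))
  put(param_tab, "fitted_parameters.csv")

  holdout <- generate_study(design_eff01(), pk_true, pd_true,
                            cfg$synthetic$noise_cv,
                            seed = cfg$seed + 900000L)
  val <- validate_holdout(pk_fit, pd_fit, holdout$pd_obs)
  put(val, "validation.csv")

  tr <- cfg$translation
  target <- derive_pd_target(
    fitted_pk_params(pk_fit), fitted_pd_params(pd_fit),
    dose_regimen(tr$efficacious_dose, tr$efficacious_interval, 28))
  tconfig <- translation_config(
    human_cl = tr$human_cl, human_vss = tr$human_vss, f_oral = tr$f_oral,
    ka = tr$ka, body_weight = tr$body_weight,
    pd = fitted_pd_params(pd_fit), target_e_min = as.numeric(target))
  projection <- find_human_dose(tconfig, interval = tr$interval)
  put(data.frame(target_e_min = as.numeric(target),
                 e_min_raw = attr(target, "e_min_raw"),
                 dose_mg = projection$dose_mg,
                 c_trough = projection$c_trough,
                 e_min = projection$e_min),
      "translation.csv")

  log_path <- file.path(out_dir, "pipeline.log")
  writeLines(c(
    sprintf("metapkpd %s",
            as.character(utils::packageVersion("metapkpd"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed %d, noise_cv %g", cfg$seed, cfg$synthetic$noise_cv),
    sprintf("validation median fold error %.4g",
            attr(val, "median_fold_error")),
    sprintf("PD target %g ug/mg; projected dose %g mg q%gh",
            as.numeric(target), projection$dose_mg, tr$interval)
  ), log_path)
  files[["pipeline.log"]] <- log_path

  invisible(list(config = cfg, species = records, ivive = ivive,
                 human = human, pk_fit = pk_fit, pd_fit = pd_fit,
                 validation = val, target = target,
                 projection = projection, files = files))
}
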