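#' Define a destructive-sampling xenograft study design
#'
#' A design is a set of dosing regimens, a vector of sampling times relative
#' to the last administered dose, and a group size per (regimen, timepoint)
#' cell. Sampling is destructive: each animal contributes one plasma
#' concentration and one tumor biomarker measurement at a single timepoint.
#'
#' @param regimens List of [dose_regimen()] objects.
#' @param sample_times Sampling times (h after the last dose).
#' @param n_per_timepoint Animals per regimen-timepoint cell.
#' @param label Design label.
#' @return A list of class `study_design`.
#' @export
study_design <- function(regimens, sample_times, n_per_timepoint = 5,
                         label = "custom") {
  if (!length(regimens) || !all(vapply(regimens, inherits, TRUE,
                                       "dose_regimen")))
    stop("'regimens' must be a non-empty list of dose_regimen objects")
  if (any(sample_times < 0)) stop("'sample_times' must be non-negative")
  n_per_timepoint <- as.integer(n_per_timepoint)
  if (is.na(n_per_timepoint) || n_per_timepoint < 1L)
    stop("'n_per_timepoint' must be >= 1")
  structure(list(regimens = regimens, sample_times = sort(sample_times),
                 n_per_timepoint = n_per_timepoint, label = label),
            class = "study_design")
}

#' Built-in study designs
#'
#' The three xenograft designs used throughout the package:
#' single oral doses of 10/25/100 mg/kg sampled 1, 7, 24, 48, 72 and 96 h
#' post dose (`design_pkpd01`); the same doses given once daily for 4 days
#' and sampled at the same offsets after the last dose (`design_pkpd02`);
#' and 6 weeks of daily dosing sampled 1, 7 and 24 h after the day-42 dose
#' (`design_eff01`). Five animals per timepoint for the PK/PD studies, ten
#' for the efficacy study.
#'
#' @param doses Dose levels (mg/kg).
#' @return A [study_design()].
#' @export
design_pkpd01 <- function(doses = c(10, 25, 100)) {
  study_design(lapply(doses, dose_regimen),
               sample_times = c(1, 7, 24, 48, 72, 96),
               n_per_timepoint = 5, label = "PKPD-01")
}

#' @rdname design_pkpd01
#' @export
design_pkpd02 <- function(doses = c(10, 25, 100)) {
  study_design(lapply(doses, dose_regimen, interval = 24, n_doses = 4L),
               sample_times = c(1, 7, 24, 48, 72, 96),
               n_per_timepoint = 5, label = "PKPD-02")
}

#' @rdname design_pkpd01
#' @export
design_eff01 <- function(doses = c(10, 25, 100)) {
  study_design(lapply(doses, dose_regimen, interval = 24, n_doses = 42L),
               sample_times = c(1, 7, 24),
               n_per_timepoint = 10, label = "EFF-01")
}

# run fn with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic xenograft PK/PD study
#'
#' Simulates the PK/PD model at every (regimen, timepoint) cell of a design
#' and perturbs the predictions with multiplicative lognormal noise with
#' median 1 and coefficient of variation `noise_cv` on the natural scale
#' (sdlog = sqrt(log(1 + cv^2))). Destructive sampling: every animal has a
#' distinct subject id and contributes one concentration and one biomarker
#' value. Regeneration with the same seed is bit-identical.
#'
#' @param design A [study_design()].
#' @param pk,pd Generating ("true") model parameters.
#' @param noise_cv Observation noise CV (fraction), >= 0.
#' @param seed Integer seed.
#' @return A list of class `synthetic_study` with elements `conc_obs` and
#'   `pd_obs` (long-format observation data.frames, times in h since first
#'   dose), `design`, `true_pk`, `true_pd`, `noise_cv`, `seed`.
#' @examples
#' s <- generate_study(design_pkpd01(), mouse_pk_params(),
#'                     mouse_pd_params(), noise_cv = 0.2, seed = 1)
#' head(s$conc_obs)
#' @export
generate_study <- function(design, pk = mouse_pk_params(),
                           pd = mouse_pd_params(), noise_cv = 0.2,
                           seed = 1L) {
  if (!inherits(design, "study_design")) stop("'design' must be a study_design")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  for (ri in seq_along(design$regimens)) {
    reg <- design$regimens[[ri]]
    offset <- (reg$n_doses - 1L) * if (reg$n_doses > 1L) reg$interval else 0
    times <- offset + design$sample_times
    conc_pred <- conc_regimen(times, reg, pk)
    eff_pred <- predict_effect(times, reg, pk, pd)
    for (ti in seq_along(times)) {
      for (a in seq_len(design$n_per_timepoint)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("%s_r%d_t%d_a%d", design$label, ri, ti, a),
          time_h = times[ti],
          conc_pred = conc_pred[ti],
          eff_pred = eff_pred[ti],
          dose_mg_kg = reg$dose,
          interval_h = reg$interval,
          n_doses = reg$n_doses,
          route = reg$route,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  noise <- with_seed(seed, function() {
    list(conc = stats::rlnorm(n, meanlog = 0, sdlog = sdlog),
         pd = stats::rlnorm(n, meanlog = 0, sdlog = sdlog))
  })
  conc_obs <- data.frame(subject = tab$subject, time_h = tab$time_h,
                         value = tab$conc_pred * noise$conc,
                         dose_mg_kg = tab$dose_mg_kg,
                         interval_h = tab$interval_h,
                         n_doses = tab$n_doses, route = tab$route,
                         stringsAsFactors = FALSE)
  pd_obs <- conc_obs
  pd_obs$value <- tab$eff_pred * noise$pd
  attr(conc_obs, "kind") <- "conc"
  attr(pd_obs, "kind") <- "pd"
  structure(list(conc_obs = conc_obs, pd_obs = pd_obs, design = design,
                 true_pk = pk, true_pd = pd, noise_cv = noise_cv,
                 seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %s: %d regimens x %d timepoints x %d animals (seed %d, CV %.2g)\n",
    x$design$label, length(x$design$regimens),
    length(x$design$sample_times), x$design$n_per_timepoint, x$seed,
    x$noise_cv))
  invisible(x)
}

# pool the observation tables of several synthetic studies
pool_studies <- function(studies, what = c("conc_obs", "pd_obs")) {
  what <- match.arg(what)
  out <- do.call(rbind, lapply(studies, `[[`, what))
  attr(out, "kind") <- if (what == "conc_obs") "conc" else "pd"
  out
}

#' Parameter-recovery experiment on synthetic studies
#'
#' For each seed, generates the single-dose and repeat-dose study designs
#' from the given generating parameters, runs the sequential fitting workflow
#' (pooled PK fit with fixed ka, then pooled PD fit with the fitted PK), and
#' collects the estimates.
#'
#' @param seeds Integer vector of seeds (one replicate per seed).
#' @param pk,pd Generating parameters.
#' @param noise_cv Observation noise CV.
#' @param ka_fixed Value at which ka is fixed during the PK fit.
#' @param n_starts Optimiser starts per fit.
#' @return A data.frame with one row per seed and columns `seed`, `cl_f`,
#'   `v_f`, `ke0`, `kin`, `kout`, `imax`, `ic50`.
#' @export
parameter_recovery <- function(seeds, pk = mouse_pk_params(),
                               pd = mouse_pd_params(), noise_cv = 0.2,
                               ka_fixed = 2.7, n_starts = 5) {
  rows <- lapply(seeds, function(sd) {
    s1 <- generate_study(design_pkpd01(), pk, pd, noise_cv, seed = sd)
    s2 <- generate_study(design_pkpd02(), pk, pd, noise_cv,
                         seed = sd + 500000L)
    conc <- pool_studies(list(s1, s2), "conc_obs")
    pdo <- pool_studies(list(s1, s2), "pd_obs")
    pk_fit <- fit_pk(conc, fixed = c(ka = ka_fixed), n_starts = n_starts)
    pd_fit <- suppressWarnings(
      fit_pd(pdo, fitted_pk_params(pk_fit), n_starts = n_starts))
    est <- c(pk_fit$estimates, pd_fit$estimates)
    data.frame(seed = sd,
               cl_f = est[["cl_f"]], v_f = est[["v_f"]],
               ke0 = est[["ke0"]], kin = est[["kin"]],
               kout = est[["kout"]], imax = est[["imax"]],
               ic50 = est[["ic50"]])
  })
  do.call(rbind, rows)
}
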