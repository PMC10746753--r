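#' Configuration for the mouse-to-human projection
#'
#' Bundles the predicted human PK (clearance, volume, absorption), the mouse
#' PD parameters assumed conserved across species, and the biomarker target.
#' The one-compartment human model is parameterised with apparent oral values
#' CL/F and V/F derived from the i.v. predictions and the assumed
#' bioavailability.
#'
#' @param human_cl Predicted human plasma clearance (L/h/kg).
#' @param human_vss Predicted human steady-state volume (L/kg).
#' @param f_oral Assumed oral bioavailability, in (0, 1].
#' @param ka Assumed human absorption rate constant (1/h).
#' @param body_weight Human body weight (kg).
#' @param pd PD parameters carried over from the mouse model
#'   ([pd_params()]).
#' @param target_e_min Target minimum biomarker level (ug/mg protein).
#' @return A list of class `translation_config`; element `pk` holds the
#'   derived apparent [pk_params()].
#' @export
translation_config <- function(human_cl = 0.020, human_vss = 0.21,
                               f_oral = 0.6, ka = 0.35, body_weight = 70,
                               pd = mouse_pd_params(), target_e_min = 125) {
  vals <- c(human_cl = human_cl, human_vss = human_vss, ka = ka,
            body_weight = body_weight, target_e_min = target_e_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all translation parameters must be positive")
  if (f_oral <= 0 || f_oral > 1) stop("f_oral must be in (0, 1]")
  stopifnot(inherits(pd, "pd_params"))
  structure(list(
    human_cl = human_cl, human_vss = human_vss, f_oral = f_oral, ka = ka,
    body_weight = body_weight, pd = pd, target_e_min = target_e_min,
    pk = pk_params(ka = ka, cl_f = human_cl / f_oral,
                   v_f = human_vss / f_oral)
  ), class = "translation_config")
}

#' Derive the biomarker target from the minimal efficacious regimen
#'
#' Simulates the PK/PD model to steady state under the minimal efficacious
#' regimen and returns the minimum biomarker level over the final dosing
#' interval, rounded down to a configured granularity. The rounded level is
#' the largest multiple of `granularity` that the steady-state profile stays
#' above, a conservative round threshold suitable for carrying across
#' species.
#'
#' @param pk,pd Mouse model parameters.
#' @param regimen The minimal efficacious [dose_regimen()] (e.g. 25 mg/kg
#'   every 12 h).
#' @param granularity Rounding granularity (ug/mg).
#' @param min_time Minimum simulated time (h) before metrics are taken.
#' @return The target level (ug/mg); attribute `e_min_raw` carries the
#'   unrounded steady-state minimum, attribute `metrics` the full
#'   [steady_state_metrics()].
#' @export
derive_pd_target <- function(pk = mouse_pk_params(), pd = mouse_pd_params(),
                             regimen = dose_regimen(25, 12, 28),
                             granularity = 25, min_time = 14 * 24) {
  m <- steady_state_metrics(regimen$dose, regimen$interval, pk, pd,
                            min_time = min_time)
  target <- floor(m$e_min / granularity) * granularity
  structure(target, e_min_raw = m$e_min, metrics = m)
}

# steady-state metrics for a human oral dose in mg under a config
human_ss_metrics <- function(dose_mg, config, interval, min_time = 0) {
  dose_mg_kg <- dose_mg / config$body_weight
  steady_state_metrics(dose_mg_kg, interval, config$pk, config$pd,
                       min_time = min_time)
}

#' Find the human dose achieving the biomarker target
#'
#' Searches the smallest dose on a fixed grid (default 5 mg) whose
#' steady-state minimum biomarker level meets or exceeds the configured
#' target, by bracketing (doubling) followed by bisection on the grid.
#' Steady-state e_min is monotone increasing in dose, which the search
#' relies on.
#'
#' @param config A [translation_config()].
#' @param interval Dosing interval (h), default once daily.
#' @param dose_grid Dose grid spacing (mg).
#' @param dose_max Upper search bound (mg).
#' @return A list of class `dose_projection`: `dose_mg`, `c_trough` (ng/mL),
#'   `e_min` (ug/mg), `interval`, and the full steady-state `metrics` at the
#'   selected dose.
#' @export
find_human_dose <- function(config, interval = 24, dose_grid = 5,
                            dose_max = 5000) {
  ceiling_e <- pd_ceiling(config$pd)
  if (config$target_e_min >= ceiling_e)
    stop(sprintf(
      "target %.4g ug/mg is not reachable (model ceiling %.4g ug/mg)",
      config$target_e_min, ceiling_e))
  emin_at <- function(d) human_ss_metrics(d, config, interval)$e_min
  lo <- 0; hi <- dose_grid
  while (emin_at(hi) < config$target_e_min) {
    lo <- hi
    hi <- hi * 2
    if (hi > dose_max)
      stop(sprintf("no dose below %g mg reaches the target", dose_max))
  }
  # bisect on the grid: invariant emin(hi) >= target > emin(lo)
  while (hi - lo > dose_grid) {
    mid <- round((lo + hi) / 2 / dose_grid) * dose_grid
    if (mid <= lo || mid >= hi) break
    if (emin_at(mid) >= config$target_e_min) hi <- mid else lo <- mid
  }
  m <- human_ss_metrics(hi, config, interval)
  structure(list(dose_mg = hi, c_trough = m$c_trough, e_min = m$e_min,
                 interval = interval, metrics = m, config = config),
            class = "dose_projection")
}

#' @export
print.dose_projection <- function(x, ...) {
  cat(sprintf(
    "<dose_projection> %g mg q%gh: steady-state C_trough %.4g ng/mL, E_min %.4g ug/mg (target %g)\n",
    x$dose_mg, x$interval, x$c_trough, x$e_min, x$config$target_e_min))
  invisible(x)
}

#' Sensitivity of the projected dose to absorption assumptions
#'
#' Re-runs [find_human_dose()] over a grid of bioavailability and body
#' weight values, the two inputs the human projection is most sensitive to
#' and the least constrained by data.
#'
#' @param config Baseline [translation_config()].
#' @param f_vals Bioavailability values to scan.
#' @param bw_vals Body weights (kg) to scan.
#' @param interval Dosing interval (h).
#' @return A data.frame with `f_oral`, `body_weight`, `dose_mg`, `c_trough`,
#'   `e_min`.
#' @export
sensitivity_scan <- function(config, f_vals = c(0.6, 0.7, 0.8),
                             bw_vals = c(60, 70), interval = 24) {
  grid <- expand.grid(f_oral = f_vals, body_weight = bw_vals)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- translation_config(
      human_cl = config$human_cl, human_vss = config$human_vss,
      f_oral = grid$f_oral[i], ka = config$ka,
      body_weight = grid$body_weight[i], pd = config$pd,
      target_e_min = config$target_e_min)
    res <- find_human_dose(cfg, interval = interval)
    data.frame(f_oral = grid$f_oral[i], body_weight = grid$body_weight[i],
               dose_mg = res$dose_mg, c_trough = res$c_trough,
               e_min = res$e_min)
  })
  do.call(rbind, rows)
}
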