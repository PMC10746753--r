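#' Plasma concentration after a single oral dose
#'
#' Closed-form one-compartment model with first-order absorption and
#' elimination:
#' C(t) = ka * Dose / ((ka - ke) * V/F) * (exp(-ke t) - exp(-ka t)),
#' converted from mg/L to ng/mL. When |ka - ke| is numerically negligible the
#' analytic limit Dose * ka * t * exp(-ka t) / (V/F) is used.
#'
#' @param t Time since the dose (h), vectorised, >= 0.
#' @param dose Dose (mg/kg).
#' @param pk A [pk_params()] object.
#' @return Concentration in ng/mL.
#' @examples
#' conc_single_dose(2, 25, mouse_pk_params())
#' @export
conc_single_dose <- function(t, dose, pk) {
  if (any(t < 0)) stop("'t' must be non-negative")
  ke <- ke_elim(pk)
  ka <- pk$ka
  if (abs(ka - ke) < 1e-8 * ka) {
    c_mg_l <- dose * ka * t * exp(-ka * t) / pk$v_f
  } else {
    c_mg_l <- ka * dose / ((ka - ke) * pk$v_f) * (exp(-ke * t) - exp(-ka * t))
  }
  1000 * c_mg_l
}

#' Plasma concentration under a multiple-dose regimen
#'
#' Superposition of [conc_single_dose()] over all doses administered at or
#' before `t` (linear PK).
#'
#' @param t Time since the first dose (h), vectorised.
#' @param regimen A [dose_regimen()].
#' @param pk A [pk_params()] object.
#' @return Concentration in ng/mL.
#' @export
conc_regimen <- function(t, regimen, pk) {
  if (any(t < 0)) stop("'t' must be non-negative")
  td <- dose_times(regimen)
  out <- numeric(length(t))
  for (d0 in td) {
    active <- t >= d0
    if (!any(active)) next
    out[active] <- out[active] +
      conc_single_dose(t[active] - d0, regimen$dose, pk)
  }
  out
}

# exp(-l1 t) - exp(-l2 t) over (l2 - l1), stable as l2 -> l1
exp_diff <- function(t, l1, l2) {
  if (abs(l2 - l1) < 1e-9 * max(l1, l2)) {
    t * exp(-l1 * t)
  } else {
    (exp(-l1 * t) - exp(-l2 * t)) / (l2 - l1)
  }
}

#' Effect-compartment concentration (analytic)
#'
#' Closed-form solution of dCe/dt = ke0 (C - Ce) with Ce(0) = 0 when C(t) is
#' the superposition of one-compartment oral doses: each dose contributes a
#' tri-exponential term obtained by convolving the biexponential forcing with
#' exp(-ke0 t).
#'
#' @inheritParams conc_regimen
#' @param ke0 Effect-compartment rate constant (1/h).
#' @return Effect-site concentration in ng/mL.
#' @export
ce_regimen <- function(t, regimen, pk, ke0) {
  if (any(t < 0)) stop("'t' must be non-negative")
  ke <- ke_elim(pk)
  ka <- pk$ka
  amp <- 1000 * ka * regimen$dose / pk$v_f  # common amplitude, ng/mL * 1/h
  td <- dose_times(regimen)
  out <- numeric(length(t))
  for (d0 in td) {
    active <- t >= d0
    if (!any(active)) next
    ts <- t[active] - d0
    # ke0/(ka-ke) * [ (e^-ke t - e^-ke0 t)/(ke0-ke) - (e^-ka t - e^-ke0 t)/(ke0-ka) ]
    if (abs(ka - ke) < 1e-8 * ka) {
      # limit ka -> ke: forcing is amp * t e^{-ka t}; convolve with e^{-ke0 t}
      if (abs(ke0 - ka) < 1e-9 * ka) {
        contrib <- amp * ke0 * ts^2 / 2 * exp(-ka * ts)
      } else {
        contrib <- amp * ke0 *
          (ts * exp(-ka * ts) - exp_diff(ts, ka, ke0)) / (ke0 - ka)
      }
    } else {
      contrib <- amp * ke0 / (ka - ke) *
        (exp_diff(ts, ke, ke0) - exp_diff(ts, ka, ke0))
    }
    out[active] <- out[active] + contrib
  }
  out
}

# right-hand side used by the ODE route: states Ce, E
pkpd_rhs <- function(t, y, parms) {
  conc <- conc_regimen(t, parms$regimen, parms$pk)
  pd <- parms$pd
  inhib <- 1 - pd$imax * y[1] / (y[1] + pd$ic50)
  list(c(pd$ke0 * (conc - y[1]),
         pd$kin - pd$kout * y[2] * inhib))
}

# rhs with analytic Ce forcing: single state E (fast path for fitting)
effect_rhs <- function(t, y, parms) {
  ce <- ce_regimen(t, parms$regimen, parms$pk, parms$pd$ke0)
  pd <- parms$pd
  inhib <- 1 - pd$imax * ce / (ce + pd$ic50)
  list(pd$kin - pd$kout * y * inhib)
}

#' Simulate the coupled PK/PD model
#'
#' Integrates the effect-compartment / turnover system driven by the
#' closed-form plasma concentration, from Ce(0) = 0 and E(0) = kin/kout.
#' With `ce = "analytic"` the effect-site concentration enters as an exact
#' forcing function and only the biomarker E is integrated; with
#' `ce = "ode"` both Ce and E are integrated numerically (useful as a
#' cross-check of the analytic convolution).
#'
#' @param regimen A [dose_regimen()].
#' @param pk,pd Model parameters ([pk_params()], [pd_params()]).
#' @param t_end End of the simulation (h); defaults to the regimen span plus
#'   96 h of washout.
#' @param dt Output grid spacing (h).
#' @param ce `"analytic"` or `"ode"`.
#' @param init Optional initial state `c(ce, effect)`; defaults to
#'   `c(0, kin/kout)`.
#' @return A data.frame of class `pd_sim` with columns `time`, `conc`
#'   (ng/mL), `ce` (ng/mL), `effect` (ug/mg protein).
#' @export
simulate_pkpd <- function(regimen, pk, pd, t_end = NULL, dt = 0.1,
                          ce = c("analytic", "ode"), init = NULL) {
  ce <- match.arg(ce)
  if (is.null(t_end)) t_end <- regimen_span(regimen) + 96
  times <- seq(0, t_end, by = dt)
  parms <- list(regimen = regimen, pk = pk, pd = pd)
  if (is.null(init)) init <- c(0, pd_baseline(pd))
  if (ce == "analytic") {
    sol <- deSolve::lsoda(c(E = init[2]), times, effect_rhs, parms,
                          rtol = 1e-8, atol = 1e-10)
    ce_vals <- ce_regimen(times, regimen, pk, pd$ke0) +
      init[1] * exp(-pd$ke0 * times)
    eff <- sol[, "E"]
  } else {
    sol <- deSolve::lsoda(c(Ce = init[1], E = init[2]), times, pkpd_rhs,
                          parms, rtol = 1e-8, atol = 1e-10)
    ce_vals <- sol[, "Ce"]
    eff <- sol[, "E"]
  }
  out <- data.frame(time = times,
                    conc = conc_regimen(times, regimen, pk),
                    ce = ce_vals, effect = eff)
  class(out) <- c("pd_sim", "data.frame")
  attr(out, "regimen") <- regimen
  out
}

# biomarker predictions for several regimens at once on a shared fixed grid
# (estimation fast path): the loss rate w(t) = kout (1 - Imax Ce/(Ce + IC50))
# is precomputed from the analytic Ce on a half-step grid and E' = kin - w E
# is advanced by classical RK4. Deterministic in the parameters (no adaptive
# stepping), which keeps finite-difference Jacobians clean.
predict_effect_batch <- function(times_by_reg, regimens, pk, pd, h = 0.1) {
  t_end <- max(unlist(times_by_reg), h)
  n_steps <- ceiling(t_end / h - 1e-9)
  grid <- seq(0, by = h, length.out = n_steps + 1)
  half <- seq(0, by = h / 2, length.out = 2 * n_steps + 1)
  nr <- length(regimens)
  ce_h <- vapply(seq_len(nr),
                 function(i) ce_regimen(half, regimens[[i]], pk, pd$ke0),
                 numeric(length(half)))
  w <- pd$kout * (1 - pd$imax * ce_h / (ce_h + pd$ic50))
  eff <- matrix(NA_real_, n_steps + 1, nr)
  e <- rep(pd_baseline(pd), nr)
  eff[1, ] <- e
  kin <- pd$kin
  for (k in seq_len(n_steps)) {
    w1 <- w[2 * k - 1, ]; w2 <- w[2 * k, ]; w3 <- w[2 * k + 1, ]
    k1 <- kin - w1 * e
    k2 <- kin - w2 * (e + h / 2 * k1)
    k3 <- kin - w2 * (e + h / 2 * k2)
    k4 <- kin - w3 * (e + h * k3)
    e <- e + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    eff[k + 1, ] <- e
  }
  lapply(seq_len(nr), function(i)
    stats::approx(grid, eff[, i], xout = times_by_reg[[i]], rule = 2)$y)
}

# biomarker predictions at arbitrary times for one regimen (reference path):
# integrates E only, with analytic Ce, reporting at the requested times
predict_effect <- function(times, regimen, pk, pd) {
  ord <- order(times)
  tt <- times[ord]
  grid <- sort(unique(c(0, tt)))
  parms <- list(regimen = regimen, pk = pk, pd = pd)
  sol <- deSolve::lsoda(c(E = pd_baseline(pd)), grid, effect_rhs, parms,
                        rtol = 1e-8, atol = 1e-10)
  eff <- sol[match(tt, grid), "E"]
  out <- numeric(length(times))
  out[ord] <- eff
  out
}

#' Steady-state exposure and biomarker metrics under repeated dosing
#'
#' Simulates the PK/PD system interval by interval under indefinite repeated
#' dosing until the per-interval change in both the trough concentration and
#' the minimum biomarker level falls below `tol` (relative), or a hard time
#' cap of ten PK half-lives plus 10/ke0 is reached. Metrics are reported over
#' the final simulated interval.
#'
#' @param dose Dose per administration (mg/kg).
#' @param interval Dosing interval (h).
#' @param pk,pd Model parameters.
#' @param tol Relative convergence tolerance on (c_trough, e_min) per
#'   interval.
#' @param min_time Minimum time (h) to simulate regardless of convergence.
#' @param dt Within-interval output grid (h).
#' @return A list of class `steady_state_metrics`: `c_trough`, `c_max`,
#'   `c_avg` (ng/mL), `e_min`, `e_max` (ug/mg), `converged`, `n_intervals`,
#'   `time_simulated` (h).
#' @examples
#' \donttest{
#' steady_state_metrics(25, 12, mouse_pk_params(), mouse_pd_params())
#' }
#' @export
steady_state_metrics <- function(dose, interval, pk, pd, tol = 1e-3,
                                 min_time = 0, dt = interval / 240) {
  if (interval <= 0) stop("'interval' must be positive")
  t_half_pk <- log(2) / ke_elim(pk)
  cap <- max(10 * t_half_pk + 10 / pd$ke0, min_time, 3 * interval)
  state <- c(0, pd_baseline(pd))
  prev <- c(NA_real_, NA_real_)
  k <- 0L
  converged <- FALSE
  metrics <- NULL
  repeat {
    k <- k + 1L
    # simulate interval k of an ongoing regimen with k doses given
    reg_k <- dose_regimen(dose, interval, k)
    t0 <- (k - 1L) * interval
    times <- seq(t0, t0 + interval, by = dt)
    parms <- list(regimen = reg_k, pk = pk, pd = pd)
    sol <- deSolve::lsoda(c(Ce = state[1], E = state[2]), times, pkpd_rhs,
                          parms, rtol = 1e-8, atol = 1e-10)
    conc <- conc_regimen(times, reg_k, pk)
    seg_auc <- sum(segment_auc(times, conc))
    metrics <- list(
      c_trough = conc[length(conc)],
      c_max = max(conc),
      c_avg = seg_auc / interval,
      e_min = min(sol[, "E"]),
      e_max = max(sol[, "E"])
    )
    state <- unname(c(sol[nrow(sol), "Ce"], sol[nrow(sol), "E"]))
    cur <- c(metrics$c_trough, metrics$e_min)
    t_now <- k * interval
    if (!anyNA(prev) && t_now >= min_time &&
        all(abs(cur - prev) <= tol * pmax(abs(prev), .Machine$double.eps))) {
      converged <- TRUE
      break
    }
    if (t_now >= cap) break
    prev <- cur
  }
  structure(c(metrics, list(converged = converged, n_intervals = k,
                            time_simulated = k * interval)),
            class = "steady_state_metrics")
}

#' @export
print.steady_state_metrics <- function(x, ...) {
  cat(sprintf(
    "<steady_state_metrics> C trough/avg/max %.4g / %.4g / %.4g ng/mL\n",
    x$c_trough, x$c_avg, x$c_max))
  cat(sprintf("  E min/max %.4g / %.4g ug/mg; %d intervals (%g h), %s\n",
              x$e_min, x$e_max, x$n_intervals, x$time_simulated,
              if (x$converged) "converged" else "cap reached"))
  invisible(x)
}

#' Closed-form steady-state trough concentration
#'
#' Geometric-series accumulation of the one-compartment oral model at the end
#' of a dosing interval at steady state:
#' C_trough = D/(V/F) * ka/(ka - ke) *
#'   (exp(-ke tau)/(1 - exp(-ke tau)) - exp(-ka tau)/(1 - exp(-ka tau))).
#'
#' @param dose Dose per administration (mg/kg).
#' @param interval Dosing interval tau (h).
#' @param pk A [pk_params()] object.
#' @return Steady-state trough concentration (ng/mL).
#' @export
ctrough_closed_form <- function(dose, interval, pk) {
  if (dose <= 0 || interval <= 0) stop("dose and interval must be positive")
  ke <- ke_elim(pk); ka <- pk$ka
  acc <- function(l) exp(-l * interval) / (1 - exp(-l * interval))
  if (abs(ka - ke) < 1e-8 * ka) {
    # limit form: d/dl of the accumulation factor
    tau <- interval
    e <- exp(-ka * tau)
    return(1000 * dose / pk$v_f * ka * tau * e / (1 - e)^2)
  }
  1000 * dose / pk$v_f * ka / (ka - ke) * (acc(ke) - acc(ka))
}
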