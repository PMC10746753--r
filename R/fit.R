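## Naive-pooled nonlinear least squares on log observations (multiplicative
## error), shared by the PK and PD fits. Parameters are estimated on an
## unconstrained scale (log, or logit for bounded fractions) and reported on
## the natural scale with delta-method CV%.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# transform/back-transform a named parameter vector
to_unconstrained <- function(theta, logit_names = character()) {
  out <- theta
  for (nm in names(theta)) {
    out[nm] <- if (nm %in% logit_names) logit(theta[nm]) else log(theta[nm])
  }
  out
}
to_natural <- function(u, logit_names = character()) {
  out <- u
  for (nm in names(u)) {
    out[nm] <- if (nm %in% logit_names) inv_logit(u[nm]) else exp(u[nm])
  }
  out
}

# central-difference Jacobian of a residual function at a point
num_jacobian <- function(fn, x, eps = 1e-6) {
  r0 <- fn(x)
  J <- matrix(NA_real_, length(r0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# deterministic jitter offsets for multistart (fixed, seed-independent)
jitter_offsets <- function(n_starts, n_par, sd = 0.4) {
  base <- c(0.7, -0.9, 1.3, -0.5, 0.4, -1.1, 0.8, 0.2, -0.3, 1.0,
            -0.6, 0.5, -1.2, 0.9, -0.8, 0.3, 1.1, -0.4, 0.6, -1.0)
  m <- matrix(0, n_starts, n_par)
  if (n_starts > 1L) {
    vals <- rep_len(base, (n_starts - 1L) * n_par)
    m[-1L, ] <- matrix(vals, n_starts - 1L, n_par, byrow = TRUE) * sd
  }
  m
}

# run nls.lm from several jittered starts; keep the best converged fit
multistart_lm <- function(resid_fn, start_u, n_starts) {
  offs <- jitter_offsets(n_starts, length(start_u))
  best <- NULL
  objs <- rep(NA_real_, n_starts)
  for (s in seq_len(n_starts)) {
    st <- start_u + offs[s, ]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12,
                           epsfcn = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    objs[s] <- fit$deviance
    if (is.null(best) || fit$deviance < best$deviance - 1e-12) best <- fit
  }
  if (is.null(best)) stop("estimation failed from every start")
  list(fit = best, start_objectives = objs)
}

# assemble a fit_result from an optimiser solution
make_fit_result <- function(fit, resid_fn, logit_names, fixed, n_obs,
                            n_excluded, start_objectives, kind) {
  u <- fit$par
  est <- to_natural(u, logit_names)
  resid <- resid_fn(u)
  rss <- sum(resid^2)
  p <- length(u)
  sigma2_mle <- rss / n_obs
  neg2ll <- n_obs * (log(2 * pi * sigma2_mle) + 1)
  k <- p + 1  # + residual SD
  se_u <- rep(NA_real_, p)
  J <- num_jacobian(resid_fn, u)
  JtJ <- crossprod(J)
  cov_u <- tryCatch(solve(JtJ) * rss / max(n_obs - p, 1),
                    error = function(e) NULL)
  if (!is.null(cov_u)) se_u <- sqrt(pmax(diag(cov_u), 0))
  names(se_u) <- names(u)
  # delta method to natural-scale CV%
  cv <- vapply(names(u), function(nm) {
    if (nm %in% logit_names) 100 * (1 - est[nm]) * se_u[nm]
    else 100 * se_u[nm]
  }, numeric(1))
  structure(list(
    kind = kind,
    estimates = est,
    fixed = fixed,
    cv_percent = cv,
    objective = neg2ll,
    aic = neg2ll + 2 * k,
    bic = neg2ll + k * log(n_obs),
    rss = rss,
    n_obs = n_obs,
    n_excluded = n_excluded,
    rss_trace = fit$rsstrace,
    convergence = fit$info,
    message = fit$message,
    start_objectives = start_objectives
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s fit, %d observations (%d excluded)\n",
              x$kind, x$n_obs, x$n_excluded))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    cv_percent = signif(x$cv_percent, 3))
  print(tab)
  if (length(x$fixed))
    cat(sprintf("  fixed: %s\n",
                paste(names(x$fixed), x$fixed, sep = " = ",
                      collapse = ", ")))
  cat(sprintf("  -2LL %.2f, AIC %.2f, BIC %.2f\n", x$objective, x$aic,
              x$bic))
  invisible(x)
}

#' Extract fitted PK parameters from a fit result
#' @param fit A `fit_result` from [fit_pk()].
#' @return A [pk_params()] object combining estimated and fixed values.
#' @export
fitted_pk_params <- function(fit) {
  all <- c(fit$estimates, fit$fixed)
  pk_params(ka = all[["ka"]], cl_f = all[["cl_f"]], v_f = all[["v_f"]])
}

#' Extract fitted PD parameters from a fit result
#' @param fit A `fit_result` from [fit_pd()].
#' @return A [pd_params()] object combining estimated and fixed values.
#' @export
fitted_pd_params <- function(fit) {
  all <- c(fit$estimates, fit$fixed)
  pd_params(ke0 = all[["ke0"]], kin = all[["kin"]], kout = all[["kout"]],
            imax = all[["imax"]], ic50 = all[["ic50"]])
}

#' Fit the one-compartment oral PK model to pooled concentrations
#'
#' Naive-pooled nonlinear least squares on log-transformed concentrations
#' (multiplicative error), with closed-form superposition predictions.
#' Zero or negative observations are excluded (they carry no information on
#' the log scale) with a message. By default the absorption rate constant is
#' fixed; pass `fixed = NULL` to estimate it.
#'
#' @param obs Concentration observation table (see [read_observations()]).
#' @param fixed Named numeric vector of parameters to hold constant, e.g.
#'   `c(ka = 2.7)`.
#' @param init Optional [pk_params()] with starting values; defaults to
#'   data-driven heuristics.
#' @param n_starts Number of jittered starts for the optimiser.
#' @return A `fit_result`; retrieve parameters with [fitted_pk_params()].
#' @export
fit_pk <- function(obs, fixed = c(ka = 2.7), init = NULL, n_starts = 5) {
  obs <- validate_observations(obs, "conc")
  pos <- obs$value > 0
  n_excluded <- sum(!pos)
  if (n_excluded)
    message(sprintf("excluding %d non-positive concentration(s)", n_excluded))
  obs <- obs[pos, , drop = FALSE]
  if (length(unique(obs$time_h)) < 3L)
    stop("PK fitting requires >= 3 distinct positive-concentration timepoints")
  regs <- obs_regimens(obs)
  ridx <- obs_regimen_index(obs)
  fixed <- fixed[names(fixed) %in% c("ka", "cl_f", "v_f")]
  free <- setdiff(c("ka", "cl_f", "v_f"), names(fixed))
  if (!length(free)) stop("no free PK parameters to estimate")

  if (is.null(init)) {
    # heuristics: volume from dose-normalised peak, ke from late decline
    cmax_norm <- max(obs$value / obs$dose_mg_kg)
    v0 <- max(1000 / cmax_norm * 0.7, 1e-3)
    init <- list(ka = 2, cl_f = 0.3 * v0, v_f = v0)
  }
  theta0 <- unlist(init[free])
  logobs <- log(obs$value)

  predict_log <- function(u) {
    nat <- to_natural(u)
    all <- c(nat, fixed)
    pk <- pk_params(all[["ka"]], all[["cl_f"]], all[["v_f"]])
    pred <- numeric(nrow(obs))
    for (i in seq_along(regs)) {
      sel <- ridx == i
      pred[sel] <- conc_regimen(obs$time_h[sel], regs[[i]], pk)
    }
    log(pmax(pred, 1e-12))
  }
  resid_fn <- function(u) predict_log(u) - logobs

  ms <- multistart_lm(resid_fn, to_unconstrained(theta0), n_starts)
  make_fit_result(ms$fit, resid_fn, character(), fixed, nrow(obs),
                  n_excluded, ms$start_objectives, kind = "PK")
}

#' Fit the effect-compartment / turnover PD model (sequential step)
#'
#' Sequential (fixed-PK) naive-pooled fit of the biomarker model: plasma
#' concentrations entering the effect compartment are model predictions from
#' the supplied PK parameters, not observations. Estimation is least squares
#' on log-transformed biomarker levels (multiplicative error); ke0, kin, kout
#' and IC50 are log-parameterised and Imax logit-parameterised to enforce
#' their ranges.
#'
#' @param pd_obs Biomarker observation table (see [read_observations()]).
#' @param pk Fixed [pk_params()] from the PK step (or
#'   [fitted_pk_params()]).
#' @param fixed Optional named vector of PD parameters to hold constant.
#' @param init Optional [pd_params()] starting values; defaults to
#'   data-driven heuristics.
#' @param n_starts Number of jittered starts.
#' @return A `fit_result`; retrieve parameters with [fitted_pd_params()].
#'   An estimate of Imax within 1e-3 of 1 or any CV% above 100 is reported
#'   with a warning (poor identifiability).
#' @export
fit_pd <- function(pd_obs, pk, fixed = NULL, init = NULL, n_starts = 5) {
  pd_obs <- validate_observations(pd_obs, "pd")
  pos <- pd_obs$value > 0
  n_excluded <- sum(!pos)
  if (n_excluded)
    message(sprintf("excluding %d non-positive biomarker value(s)",
                    n_excluded))
  pd_obs <- pd_obs[pos, , drop = FALSE]
  if (nrow(pd_obs) < 5L)
    stop("PD fitting requires >= 5 positive biomarker observations")
  regs <- obs_regimens(pd_obs)
  ridx <- obs_regimen_index(pd_obs)
  par_names <- c("ke0", "kin", "kout", "imax", "ic50")
  fixed <- fixed[names(fixed) %in% par_names]
  free <- setdiff(par_names, names(fixed))
  if (!length(free)) stop("no free PD parameters to estimate")

  if (is.null(init)) {
    base0 <- max(stats::quantile(pd_obs$value, 0.1), 1e-3)
    emax0 <- max(pd_obs$value)
    imax0 <- min(max(1 - base0 / emax0, 0.3), 0.95)
    # typical effect-site exposure: median model concentration at obs times
    cc <- numeric(nrow(pd_obs))
    for (i in seq_along(regs)) {
      sel <- ridx == i
      cc[sel] <- conc_regimen(pd_obs$time_h[sel], regs[[i]], pk)
    }
    ic50_0 <- max(stats::median(cc[cc > 0]) / 3, 1)
    init <- list(ke0 = 0.1, kin = base0 * 1.0, kout = 1.0, imax = imax0,
                 ic50 = ic50_0)
  }
  theta0 <- unlist(init[free])
  logit_names <- intersect("imax", free)
  logobs <- log(pd_obs$value)
  times_by_reg <- lapply(seq_along(regs),
                         function(i) pd_obs$time_h[ridx == i])

  resid_fn <- function(u) {
    nat <- to_natural(u, logit_names)
    all <- c(nat, fixed)
    pd <- tryCatch(
      pd_params(all[["ke0"]], all[["kin"]], all[["kout"]], all[["imax"]],
                all[["ic50"]]),
      error = function(e) NULL)
    if (is.null(pd)) return(rep(1e6, nrow(pd_obs)))
    pred_by_reg <- tryCatch(
      predict_effect_batch(times_by_reg, regs, pk, pd),
      error = function(e) NULL)
    if (is.null(pred_by_reg)) return(rep(1e6, nrow(pd_obs)))
    pred <- numeric(nrow(pd_obs))
    for (i in seq_along(regs)) pred[ridx == i] <- pred_by_reg[[i]]
    if (anyNA(pred)) return(rep(1e6, nrow(pd_obs)))
    log(pmax(pred, 1e-12)) - logobs
  }

  ms <- multistart_lm(resid_fn, to_unconstrained(theta0, logit_names),
                      n_starts)
  res <- make_fit_result(ms$fit, resid_fn, logit_names, fixed, nrow(pd_obs),
                         n_excluded, ms$start_objectives, kind = "PD")
  if ("imax" %in% names(res$estimates) &&
      res$estimates[["imax"]] > 1 - 1e-3)
    warning("Imax estimate at its upper bound (1); interpret with caution")
  poor <- is.na(res$cv_percent) | res$cv_percent > 100
  if (any(poor))
    warning(sprintf(
      "poorly identified parameter(s): %s (CV%% > 100 or singular information)",
      paste(names(res$cv_percent)[poor], collapse = ", ")))
  res
}

#' Validate a fitted model against a held-out study
#'
#' Simulates the biomarker at the held-out design's observation times using
#' the fitted (or supplied) parameters and pairs predictions with the
#' observations.
#'
#' @param pk,pd Model parameters ([pk_params()] / [pd_params()] or the
#'   corresponding `fit_result`s).
#' @param holdout Biomarker observation table of the held-out study.
#' @return A data.frame with the holdout rows plus `predicted` and
#'   `fold_error` (predicted / observed) columns; attributes
#'   `median_fold_error` and `frac_within_2fold` summarise agreement. An
#'   empty holdout returns an empty table with a warning.
#' @export
validate_holdout <- function(pk, pd, holdout) {
  if (inherits(pk, "fit_result")) pk <- fitted_pk_params(pk)
  if (inherits(pd, "fit_result")) pd <- fitted_pd_params(pd)
  if (!nrow(holdout)) {
    warning("empty holdout dataset")
    out <- cbind(holdout, predicted = numeric(0), fold_error = numeric(0))
    attr(out, "median_fold_error") <- NA_real_
    return(out)
  }
  holdout <- validate_observations(holdout, "pd")
  regs <- obs_regimens(holdout)
  ridx <- obs_regimen_index(holdout)
  pred <- numeric(nrow(holdout))
  for (i in seq_along(regs)) {
    sel <- ridx == i
    pred[sel] <- predict_effect(holdout$time_h[sel], regs[[i]], pk, pd)
  }
  out <- holdout
  out$predicted <- pred
  out$fold_error <- ifelse(holdout$value > 0, pred / holdout$value, NA_real_)
  attr(out, "median_fold_error") <-
    stats::median(out$fold_error, na.rm = TRUE)
  attr(out, "frac_within_2fold") <-
    mean(out$fold_error >= 0.5 & out$fold_error <= 2, na.rm = TRUE)
  out
}

#' Convert a mass concentration IC50 to molar units
#'
#' total uM = IC50(ng/mL) / molar mass(g/mol); free nM = total * fu * 1000.
#'
#' @param ic50 IC50 in ng/mL.
#' @param fu Plasma fraction unbound.
#' @param molar_mass Molar mass (g/mol); defaults to
#'   [compound_molar_mass()].
#' @return A list with `total_um` and `free_nm`.
#' @examples
#' ic50_unit_conversion(340, fu = 0.032)
#' @export
ic50_unit_conversion <- function(ic50, fu, molar_mass = compound_molar_mass()) {
  vals <- c(ic50 = ic50, fu = fu, molar_mass = molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("ic50, fu and molar_mass must be positive")
  total_um <- ic50 / molar_mass
  list(total_um = total_um, free_nm = total_um * fu * 1000)
}
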