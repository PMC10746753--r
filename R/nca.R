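#' Linear-up/log-down trapezoidal AUC
#'
#' Area under the concentration-time curve by the linear-up/log-down rule:
#' each interval contributes a linear trapezoid when the concentration is
#' rising (C2 >= C1) or either endpoint is zero, and a log trapezoid
#' (C1 - C2) * dt / ln(C1/C2) when it is falling with both endpoints positive.
#'
#' @param times Sampling times (h), strictly increasing, length >= 2.
#' @param concs Concentrations (ng/mL), non-negative, same length as `times`.
#' @return AUC from `times[1]` to the last time, in ng*h/mL.
#' @examples
#' auc_lin_up_log_down(c(0, 1), c(100, 50))  # 50 / log(2)
#' @export
auc_lin_up_log_down <- function(times, concs) {
  check_profile(times, concs)
  sum(segment_auc(times, concs))
}

check_profile <- function(times, concs) {
  if (length(times) < 2L)
    stop("at least 2 concentration-time points are required")
  if (length(times) != length(concs))
    stop("'times' and 'concs' must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (any(concs < 0)) stop("'concs' must be non-negative")
  invisible(NULL)
}

# per-interval AUC increments under the lin-up/log-down rule
segment_auc <- function(times, concs) {
  n <- length(times)
  c1 <- concs[-n]; c2 <- concs[-1L]
  dt <- diff(times)
  lin <- (c1 + c2) / 2 * dt
  logdown <- c2 < c1 & c2 > 0
  out <- lin
  out[logdown] <- (c1[logdown] - c2[logdown]) * dt[logdown] /
    log(c1[logdown] / c2[logdown])
  out
}

# per-interval AUMC (first moment) increments: linear trapezoid on t*C when
# rising or touching zero; on falling intervals the exact integral of
# t * C1 * exp(-k (t - t1)) with k = ln(C1/C2)/dt (the log-down assumption)
segment_aumc <- function(times, concs) {
  n <- length(times)
  t1 <- times[-n]; t2 <- times[-1L]
  c1 <- concs[-n]; c2 <- concs[-1L]
  dt <- diff(times)
  lin <- (t1 * c1 + t2 * c2) / 2 * dt
  logdown <- c2 < c1 & c2 > 0
  out <- lin
  if (any(logdown)) {
    k <- log(c1[logdown] / c2[logdown]) / dt[logdown]
    out[logdown] <- (t1[logdown] * c1[logdown] - t2[logdown] * c2[logdown]) /
      k + (c1[logdown] - c2[logdown]) / k^2
  }
  out
}

#' Terminal slope (lambda_z) estimation
#'
#' Log-linear regression on the terminal portion of the profile. The window is
#' chosen by best adjusted R-squared over all contiguous terminal windows of
#' at least 3 positive-concentration points that start after tmax.
#'
#' @param times,concs Concentration-time profile (see
#'   [auc_lin_up_log_down()]).
#' @return A list with `lambda_z` (1/h), `intercept` (log scale), `n_points`,
#'   `adj_r_squared`, and the window `start_time`.
#' @export
lambda_z <- function(times, concs) {
  check_profile(times, concs)
  tmax_i <- which.max(concs)
  idx <- which(seq_along(times) > tmax_i & concs > 0)
  if (length(idx) < 3L)
    stop("lambda_z requires >= 3 positive terminal points after tmax")
  best <- NULL
  for (start in idx[seq_len(length(idx) - 2L)]) {
    win <- idx[idx >= start]
    fit <- stats::lm(log(concs[win]) ~ times[win])
    slope <- unname(stats::coef(fit)[2])
    if (slope >= -1e-10) next  # flat or rising terminal phase
    arsq <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || arsq > best$adj_r_squared + 1e-12) {
      best <- list(lambda_z = -slope,
                   intercept = unname(stats::coef(fit)[1]),
                   n_points = length(win),
                   adj_r_squared = arsq,
                   start_time = times[win[1]])
    }
  }
  if (is.null(best))
    stop("no terminal window with a negative slope: lambda_z undefined")
  best
}

#' Non-compartmental analysis of an i.v. profile
#'
#' Computes AUC (linear-up/log-down), the terminal slope, half-life,
#' clearance, mean residence time, and steady-state volume from a single-dose
#' intravenous concentration-time profile.
#'
#' @param times,concs Concentration-time profile (h, ng/mL).
#' @param dose Dose in mg/kg.
#' @return A list of class `nca_result` with `auc_last`, `auc_inf`
#'   (ng*h/mL), `lambda_z` (1/h), `t_half` (h), `cl` (L/h/kg), `mrt` (h),
#'   `vss` (L/kg), `cmax` (ng/mL), `tmax` (h), `extrap_frac`, and
#'   `extrap_warning` (TRUE when more than 20% of AUC_inf is extrapolated).
#' @export
nca_iv <- function(times, concs, dose) {
  if (!is.numeric(dose) || dose <= 0) stop("'dose' must be positive (mg/kg)")
  lz <- lambda_z(times, concs)
  auc_last <- sum(segment_auc(times, concs))
  aumc_last <- sum(segment_aumc(times, concs))
  n <- length(times)
  c_last <- concs[n]; t_last <- times[n]
  auc_inf <- auc_last + c_last / lz$lambda_z
  aumc_inf <- aumc_last + c_last * t_last / lz$lambda_z +
    c_last / lz$lambda_z^2
  # dose mg/kg over AUC ng*h/mL = mg/kg / (1e-3 mg*h/L) -> *1000 gives L/h/kg
  cl <- dose / auc_inf * 1000
  mrt <- aumc_inf / auc_inf
  extrap <- (auc_inf - auc_last) / auc_inf
  if (extrap > 0.2)
    warning(sprintf("%.1f%% of AUC_inf is extrapolated (> 20%%)", 100 * extrap))
  structure(list(
    auc_last = auc_last, auc_inf = auc_inf,
    lambda_z = lz$lambda_z, t_half = log(2) / lz$lambda_z,
    cl = cl, mrt = mrt, vss = cl * mrt,
    cmax = max(concs), tmax = times[which.max(concs)],
    extrap_frac = extrap, extrap_warning = extrap > 0.2,
    lambda_z_fit = lz, n_obs = n
  ), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "<nca_result> AUCinf %.4g ng*h/mL (%.1f%% extrapolated), t1/2 %.3g h\n",
    x$auc_inf, 100 * x$extrap_frac, x$t_half))
  cat(sprintf("  CL %.4g L/h/kg, Vss %.4g L/kg, Cmax %.4g ng/mL at %g h\n",
              x$cl, x$vss, x$cmax, x$tmax))
  invisible(x)
}

#' Oral bioavailability from dose-normalised AUC ratio
#'
#' F = (AUC_po / dose_po) / (AUC_iv / dose_iv).
#'
#' @param auc_po,auc_iv AUC after oral and intravenous dosing (ng*h/mL).
#' @param dose_po,dose_iv The respective doses (mg/kg).
#' @return Bioavailability fraction. Values above 1 are returned as computed
#'   with a warning.
#' @export
bioavailability <- function(auc_po, dose_po, auc_iv, dose_iv) {
  vals <- c(auc_po = auc_po, dose_po = dose_po, auc_iv = auc_iv,
            dose_iv = dose_iv)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all AUCs and doses must be positive")
  f <- (auc_po / dose_po) / (auc_iv / dose_iv)
  if (f > 1) warning(sprintf("computed bioavailability %.3g exceeds 1", f))
  f
}
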