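#' One-compartment oral PK parameters
#'
#' Parameters of the one-compartment model with first-order absorption and
#' elimination, C(t) = ka * Dose / ((ka - ke) * V/F) * (exp(-ke t) - exp(-ka t)),
#' with ke = (CL/F) / (V/F). Clearance and volume are apparent (oral) values;
#' for an i.v.-parameterised model pass CL and V with F = 1 absorbed into them.
#'
#' @param ka First-order absorption rate constant (1/h).
#' @param cl_f Apparent clearance CL/F (L/h/kg).
#' @param v_f Apparent volume of distribution V/F (L/kg).
#' @return An object of class `pk_params`.
#' @seealso [mouse_pk_params()] for the fitted mouse xenograft estimates.
#' @export
pk_params <- function(ka, cl_f, v_f) {
  vals <- c(ka = ka, cl_f = cl_f, v_f = v_f)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PK parameters (ka, cl_f, v_f) must be positive and finite")
  structure(list(ka = ka, cl_f = cl_f, v_f = v_f), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> ka %g 1/h, CL/F %g L/h/kg, V/F %g L/kg (ke %.4g 1/h)\n",
              x$ka, x$cl_f, x$v_f, ke_elim(x)))
  invisible(x)
}

#' Elimination rate constant ke = (CL/F)/(V/F)
#' @param pk A [pk_params()] object.
#' @return ke in 1/h.
#' @export
ke_elim <- function(pk) pk$cl_f / pk$v_f

#' Effect-compartment and turnover PD parameters
#'
#' Parameters of the biomarker model: an effect compartment equilibrating with
#' plasma, dCe/dt = ke0 (C - Ce), driving inhibition of the first-order loss of
#' the biomarker, dE/dt = kin - kout * E * (1 - Imax * Ce / (Ce + IC50)).
#' The pre-treatment baseline is E0 = kin/kout and the asymptotic maximum under
#' saturating exposure is kin / (kout * (1 - Imax)).
#'
#' @param ke0 Effect-compartment equilibration rate constant (1/h).
#' @param kin Zero-order biomarker synthesis rate (ug/mg protein per h).
#' @param kout First-order biomarker degradation rate constant (1/h).
#' @param imax Maximal fractional inhibition of degradation, between 0 and 1.
#' @param ic50 Effect-compartment concentration giving half-maximal inhibition
#'   (ng/mL).
#' @return An object of class `pd_params`.
#' @seealso [mouse_pd_params()] for the fitted mouse xenograft estimates.
#' @export
pd_params <- function(ke0, kin, kout, imax, ic50) {
  pos <- c(ke0 = ke0, kin = kin, kout = kout, ic50 = ic50)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("ke0, kin, kout and ic50 must be positive and finite")
  if (!is.finite(imax) || imax < 0 || imax > 1)
    stop("imax must lie in [0, 1]")
  structure(list(ke0 = ke0, kin = kin, kout = kout, imax = imax, ic50 = ic50),
            class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf(
    "<pd_params> ke0 %g 1/h, kin %g ug/mg/h, kout %g 1/h, Imax %g, IC50 %g ng/mL\n",
    x$ke0, x$kin, x$kout, x$imax, x$ic50))
  cat(sprintf("  baseline kin/kout = %.4g ug/mg; ceiling kin/(kout(1-Imax)) = %.4g ug/mg\n",
              pd_baseline(x), pd_ceiling(x)))
  invisible(x)
}

#' Biomarker baseline kin/kout
#' @param pd A [pd_params()] object.
#' @return Baseline biomarker level (ug/mg protein).
#' @export
pd_baseline <- function(pd) pd$kin / pd$kout

#' Biomarker ceiling kin/(kout (1 - Imax)) under saturating exposure
#' @param pd A [pd_params()] object.
#' @return Maximum attainable biomarker level (ug/mg protein); `Inf` if
#'   `imax == 1`.
#' @export
pd_ceiling <- function(pd) {
  if (pd$imax >= 1) Inf else pd$kin / (pd$kout * (1 - pd$imax))
}
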