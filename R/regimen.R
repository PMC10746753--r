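#' Define a dosing regimen
#'
#' A regimen is a series of `n_doses` identical doses given every `interval`
#' hours, starting at time 0. Animal doses are in mg/kg; human doses are
#' normalised to mg/kg by the caller (see [translation_config()]).
#'
#' @param dose Dose per administration (mg/kg).
#' @param interval Dosing interval in hours. Ignored for a single dose.
#' @param n_doses Number of administrations (>= 1).
#' @param route Administration route, `"oral"` or `"iv"`.
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(25, interval = 12, n_doses = 28)  # 25 mg/kg BID, 14 days
#' @export
dose_regimen <- function(dose, interval = 24, n_doses = 1L, route = "oral") {
  route <- match.arg(route, c("oral", "iv"))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0)
    stop("'dose' must be a single positive number (mg/kg)")
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L)
    stop("'n_doses' must be a positive integer")
  if (n_doses > 1L && (!is.numeric(interval) || interval <= 0))
    stop("'interval' must be > 0 h when n_doses > 1")
  structure(
    list(dose = dose, interval = interval, n_doses = n_doses, route = route),
    class = "dose_regimen"
  )
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> %g mg/kg %s x%d", x$dose, x$route, x$n_doses))
  if (x$n_doses > 1L) cat(sprintf(" q%gh", x$interval))
  cat("\n")
  invisible(x)
}

# times (h) at which the regimen's doses are administered
dose_times <- function(regimen) {
  (seq_len(regimen$n_doses) - 1) * if (regimen$n_doses > 1L) regimen$interval else 0
}

# total duration from first dose to the end of the last dosing interval
regimen_span <- function(regimen) {
  if (regimen$n_doses == 1L) 0 else regimen$n_doses * regimen$interval
}
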