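#' Log-log allometric regression
#'
#' Ordinary least squares of log10(value) on log10(body weight). The
#' allometric coefficient is the back-transformed intercept, i.e. the value
#' of the scaled quantity at 1 kg body weight.
#'
#' @param body_weights Species body weights (kg), > 0, length >= 2.
#' @param values Absolute quantities to scale (e.g. L/h or L), > 0.
#' @return A list of class `allometry_fit` with `coefficient`, `exponent`,
#'   `r_squared`, and the underlying `lm` fit.
#' @examples
#' fit_loglog(c(0.02, 0.25, 5, 10), 3 * c(0.02, 0.25, 5, 10)^0.8)
#' @export
fit_loglog <- function(body_weights, values) {
  if (length(body_weights) < 2L)
    stop("allometric regression requires >= 2 species")
  if (length(body_weights) != length(values))
    stop("'body_weights' and 'values' must have equal length")
  if (any(body_weights <= 0) || any(values <= 0))
    stop("all body weights and values must be positive")
  lx <- log10(body_weights); ly <- log10(values)
  fit <- stats::lm(ly ~ lx)
  r2 <- if (length(values) == 2L) 1
        else suppressWarnings(summary(fit)$r.squared)
  structure(list(
    coefficient = unname(10^stats::coef(fit)[1]),
    exponent = unname(stats::coef(fit)[2]),
    r_squared = r2,
    lm = fit
  ), class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("<allometry_fit> y = %.4g * BW^%.4g, R^2 = %.4g\n",
              x$coefficient, x$exponent, x$r_squared))
  invisible(x)
}

#' Predict the scaled quantity at a body weight
#' @param object An `allometry_fit`.
#' @param body_weight Body weight (kg) at which to evaluate the power law.
#' @param ... Unused.
#' @return Predicted absolute quantity.
#' @export
predict.allometry_fit <- function(object, body_weight, ...) {
  object$coefficient * body_weight^object$exponent
}

#' A human PK parameter prediction
#'
#' Container for the per-method human clearance / volume predictions.
#'
#' @param method Method label.
#' @param cl Predicted clearance (L/h/kg), or `NA`.
#' @param vss Predicted steady-state volume (L/kg), or `NA`.
#' @param r_squared Regression R-squared where applicable.
#' @param detail Free-form list of method internals.
#' @return A list of class `human_prediction`.
#' @export
human_prediction <- function(method, cl = NA_real_, vss = NA_real_,
                             r_squared = NA_real_, detail = list()) {
  if (is.na(cl) && is.na(vss))
    stop("a prediction must carry at least one of cl or vss")
  if (!is.na(cl) && cl <= 0) stop("cl must be positive")
  if (!is.na(vss) && vss <= 0) stop("vss must be positive")
  structure(list(method = method, cl = cl, vss = vss,
                 r_squared = r_squared, detail = detail),
            class = "human_prediction")
}

#' @export
print.human_prediction <- function(x, ...) {
  cat(sprintf("<human_prediction> %s:", x$method))
  if (!is.na(x$cl)) cat(sprintf(" CL %.4g L/h/kg", x$cl))
  if (!is.na(x$vss)) cat(sprintf(" Vss %.4g L/kg", x$vss))
  if (!is.na(x$r_squared)) cat(sprintf(" (R^2 %.4g)", x$r_squared))
  cat("\n")
  invisible(x)
}

animal_rows <- function(records) {
  records[records$species != "human", , drop = FALSE]
}

#' Human clearance by fu-normalised, CLint-corrected four-species allometry
#'
#' For each animal species the absolute clearance is normalised by its plasma
#' fraction unbound and corrected by the human-to-species ratio of microsomal
#' intrinsic clearance: (CL/fu) * (CLint_mic,human / CLint_mic,species) * BW.
#' These corrected absolute clearances are regressed on body weight on the
#' log-log scale, the power law is evaluated at the human body weight, and
#' the result is back-multiplied by the human fraction unbound and expressed
#' per kg.
#'
#' @param records Species table ([species_records()]); must contain the four
#'   animal species with `cl_obs`, `fu_plasma`, `clint_mic`, `body_weight`,
#'   and a human row with `fu_plasma` and `clint_mic`.
#' @param human_bw Human body weight (kg).
#' @return A [human_prediction()] with `cl` (L/h/kg) and the regression
#'   `r_squared`.
#' @export
nas_fub_cl <- function(records = species_records(), human_bw = 70) {
  an <- require_fields(animal_rows(records),
                       c("cl_obs", "fu_plasma", "clint_mic", "body_weight"))
  hu <- require_fields(species_row(records, "human"),
                       c("fu_plasma", "clint_mic"))
  corrected <- (an$cl_obs / an$fu_plasma) *
    (hu$clint_mic / an$clint_mic) * an$body_weight
  fit <- fit_loglog(an$body_weight, corrected)
  cl_abs_unbound <- predict(fit, human_bw)
  cl <- cl_abs_unbound * hu$fu_plasma / human_bw
  human_prediction("NAS_fub", cl = cl, r_squared = fit$r_squared,
                   detail = list(fit = fit, corrected_cl = corrected))
}

#' Human steady-state volume by fu-normalised four-species allometry
#'
#' Regresses the fu-normalised absolute volume (Vss/fu) * BW on body weight
#' (log-log), evaluates at the human body weight, back-multiplies by the
#' human fraction unbound, and expresses per kg.
#'
#' @inheritParams nas_fub_cl
#' @return A [human_prediction()] with `vss` (L/kg).
#' @export
sa_fub_vss <- function(records = species_records(), human_bw = 70) {
  an <- require_fields(animal_rows(records),
                       c("vss_obs", "fu_plasma", "body_weight"))
  hu <- require_fields(species_row(records, "human"), "fu_plasma")
  unbound <- (an$vss_obs / an$fu_plasma) * an$body_weight
  fit <- fit_loglog(an$body_weight, unbound)
  vss <- predict(fit, human_bw) * hu$fu_plasma / human_bw
  human_prediction("SA_fub", vss = vss, r_squared = fit$r_squared,
                   detail = list(fit = fit))
}

#' Maximum lifespan potential and brain weight constants
#'
#' Standard literature values used by the product methods of the rule of
#' exponents: maximum lifespan potential (years) and brain weight (kg) per
#' species.
#'
#' @return A data.frame with `species`, `mlp_years`, `brain_weight_kg`.
#' @export
mlp_brw_table <- function() {
  data.frame(
    species = c("mouse", "rat", "monkey", "dog", "human"),
    mlp_years = c(2.7, 4.7, 22.3, 19.7, 93.4),
    brain_weight_kg = c(0.00036, 0.002, 0.095, 0.080, 1.53),
    stringsAsFactors = FALSE
  )
}

#' Human clearance by simple allometry with the rule of exponents
#'
#' Fits simple allometry to the absolute species clearances, then applies the
#' branch prescribed by the fitted exponent b: plain simple allometry for
#' b < 0.71; the CL x maximum-lifespan-potential product method for
#' 0.71 <= b <= 1; the CL x brain-weight product method for b > 1.
#'
#' @inheritParams nas_fub_cl
#' @param constants Species MLP / brain-weight table ([mlp_brw_table()]);
#'   only consulted when a product branch is selected.
#' @return A [human_prediction()] with `cl` (L/h/kg); `detail$branch` records
#'   the branch taken (`"SA"`, `"MLP"` or `"BrW"`) and `detail$fit` the
#'   underlying regression.
#' @export
rule_of_exponents_cl <- function(records = species_records(), human_bw = 70,
                                 constants = mlp_brw_table()) {
  an <- require_fields(animal_rows(records), c("cl_obs", "body_weight"))
  fit_sa <- fit_loglog(an$body_weight, an$cl_obs * an$body_weight)
  b <- fit_sa$exponent
  if (b < 0.71) {
    cl_abs <- predict(fit_sa, human_bw)
    branch <- "SA"; fit <- fit_sa
  } else {
    idx <- match(an$species, constants$species)
    hidx <- match("human", constants$species)
    if (anyNA(idx) || is.na(hidx))
      stop("MLP/brain-weight constants missing for a required species")
    if (b <= 1.0) {
      y <- an$cl_obs * an$body_weight * constants$mlp_years[idx]
      fit <- fit_loglog(an$body_weight, y)
      cl_abs <- predict(fit, human_bw) / constants$mlp_years[hidx]
      branch <- "MLP"
    } else {
      y <- an$cl_obs * an$body_weight * constants$brain_weight_kg[idx]
      fit <- fit_loglog(an$body_weight, y)
      cl_abs <- predict(fit, human_bw) / constants$brain_weight_kg[hidx]
      branch <- "BrW"
    }
  }
  human_prediction("SA/RoE", cl = cl_abs / human_bw,
                   r_squared = fit$r_squared,
                   detail = list(branch = branch, exponent = b, fit = fit))
}

#' Human clearance by the Tang-Mayersohn equation
#'
#' CL_human (mL/min) = 33.35 * (a / Rfu)^0.77, where a is the simple-allometry
#' coefficient of absolute clearance in mL/min at 1 kg body weight and
#' Rfu = fu_rat / fu_human is the rat-to-human unbound-fraction ratio.
#'
#' @param records Species table with rat and human `fu_plasma` and animal
#'   `cl_obs`/`body_weight`.
#' @param human_bw Human body weight (kg) used to express the result per kg.
#' @return A [human_prediction()] with `cl` (L/h/kg); `detail` carries the
#'   allometric coefficient (mL/min) and Rfu.
#' @export
tang_mayersohn_cl <- function(records = species_records(), human_bw = 70) {
  an <- require_fields(animal_rows(records), c("cl_obs", "body_weight"))
  fu_rat <- species_row(records, "rat")$fu_plasma
  fu_human <- species_row(records, "human")$fu_plasma
  fit <- fit_loglog(an$body_weight, an$cl_obs * an$body_weight)
  a_ml_min <- fit$coefficient * 1000 / 60  # L/h -> mL/min
  rfu <- fu_rat / fu_human
  cl_ml_min <- 33.35 * (a_ml_min / rfu)^0.77
  cl <- cl_ml_min * 60 / 1000 / human_bw  # mL/min -> L/h, per kg
  human_prediction("TME", cl = cl, r_squared = fit$r_squared,
                   detail = list(a_ml_min = a_ml_min, rfu = rfu, fit = fit))
}

#' Physiological volumes for the Oie-Tozer model
#'
#' Standard literature values of plasma volume, extracellular fluid volume,
#' remainder volume (all L/kg) and the extravascular-to-intravascular binding
#' protein ratio RE/I, per species.
#'
#' @return A data.frame with columns `species`, `vp`, `ve`, `vr`, `re_i`.
#' @export
oie_tozer_constants <- function() {
  data.frame(
    species = c("mouse", "rat", "monkey", "dog", "human"),
    vp = c(0.0500, 0.0313, 0.0448, 0.0515, 0.0436),
    ve = c(0.265, 0.265, 0.208, 0.216, 0.151),
    vr = c(0.364, 0.364, 0.485, 0.450, 0.380),
    re_i = c(1.4, 1.4, 1.4, 1.4, 1.4),
    stringsAsFactors = FALSE
  )
}

# forward Oie-Tozer equation: Vss from fu, fu_t and physiological volumes
oie_tozer_forward <- function(fu, fut, phys) {
  phys$vp * (1 + phys$re_i) + fu * phys$vp * (phys$ve / phys$vp - phys$re_i) +
    phys$vr * fu / fut
}

#' Human steady-state volume by the Oie-Tozer model
#'
#' Solves the Oie-Tozer equation
#' Vss = Vp (1 + RE/I) + fu Vp (Ve/Vp - RE/I) + Vr fu / fut
#' for the apparent tissue unbound fraction fut in each animal species, then
#' applies the equation forward with human physiological constants, the human
#' plasma fu, and the cross-species mean fut. Species whose solved fut is not
#' strictly positive are excluded with a warning.
#'
#' @inheritParams nas_fub_cl
#' @param physios Physiological constants table ([oie_tozer_constants()]).
#' @return A [human_prediction()] with `vss` (L/kg); `detail$fut` holds the
#'   per-species solved values.
#' @export
oie_tozer_vss <- function(records = species_records(),
                          physios = oie_tozer_constants()) {
  an <- require_fields(animal_rows(records), c("vss_obs", "fu_plasma"))
  idx <- match(an$species, physios$species)
  if (anyNA(idx)) stop("Oie-Tozer constants missing for a species")
  ph <- physios[idx, ]
  denom <- an$vss_obs - ph$vp * (1 + ph$re_i) -
    an$fu_plasma * ph$vp * (ph$ve / ph$vp - ph$re_i)
  fut <- ph$vr * an$fu_plasma / denom
  names(fut) <- an$species
  ok <- is.finite(fut) & fut > 0
  if (!all(ok)) {
    warning(sprintf("solved fu_t non-positive for %s; excluded",
                    paste(an$species[!ok], collapse = ", ")))
    if (!any(ok)) stop("no species yields a valid fu_t")
  }
  fut_mean <- mean(fut[ok])
  hu_fu <- species_row(records, "human")$fu_plasma
  hu_ph <- physios[match("human", physios$species), ]
  vss <- oie_tozer_forward(hu_fu, fut_mean, hu_ph)
  human_prediction("OT", vss = vss,
                   detail = list(fut = fut, fut_mean = fut_mean))
}

#' Human volume by human-dog unbound-fraction proportionality
#'
#' V_human = V_dog * fu_human / fu_dog.
#'
#' @param v_dog Dog steady-state volume (L/kg).
#' @param fu_human,fu_dog Plasma unbound fractions.
#' @return A [human_prediction()] with `vss` (L/kg).
#' @export
dog_proportionality_vss <- function(v_dog, fu_human, fu_dog) {
  vals <- c(v_dog = v_dog, fu_human = fu_human, fu_dog = fu_dog)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs must be positive")
  human_prediction("Human-dog proportionality",
                   vss = v_dog * fu_human / fu_dog)
}

#' Elimination half-life from clearance and volume
#'
#' t1/2 = ln(2) * Vss / CL, the half-life consistent with first-order
#' elimination at rate CL/Vss.
#'
#' @param cl Clearance (L/h/kg).
#' @param vss Steady-state volume (L/kg).
#' @return Half-life in hours.
#' @examples
#' halflife(0.02, 0.21)  # ~7.3 h
#' @export
halflife <- function(cl, vss) {
  if (any(cl <= 0) || any(vss <= 0)) stop("cl and vss must be positive")
  log(2) * vss / cl
}

#' Combine per-method human predictions into mean +/- SD
#'
#' Arithmetic mean and sample standard deviation of the available clearance
#' and volume predictions across methods, plus the half-life derived from the
#' mean parameters.
#'
#' @param predictions A list of [human_prediction()] objects.
#' @return A list of class `human_summary` with `cl_mean`, `cl_sd`,
#'   `vss_mean`, `vss_sd`, `t_half` (from the means), `n_cl`, `n_vss`, and
#'   the input table as a data.frame (`methods`). The SD is `NA` when only
#'   one prediction contributes.
#' @export
combine_predictions <- function(predictions) {
  if (!length(predictions)) stop("no predictions to combine")
  tab <- data.frame(
    method = vapply(predictions, `[[`, "", "method"),
    cl = vapply(predictions, `[[`, NA_real_, "cl"),
    vss = vapply(predictions, `[[`, NA_real_, "vss"),
    stringsAsFactors = FALSE
  )
  cls <- tab$cl[!is.na(tab$cl)]
  vsss <- tab$vss[!is.na(tab$vss)]
  if (!length(cls) && !length(vsss))
    stop("predictions carry neither cl nor vss")
  cl_mean <- if (length(cls)) mean(cls) else NA_real_
  vss_mean <- if (length(vsss)) mean(vsss) else NA_real_
  structure(list(
    cl_mean = cl_mean,
    cl_sd = if (length(cls) > 1) stats::sd(cls) else NA_real_,
    vss_mean = vss_mean,
    vss_sd = if (length(vsss) > 1) stats::sd(vsss) else NA_real_,
    t_half = if (length(cls) && length(vsss)) halflife(cl_mean, vss_mean)
             else NA_real_,
    n_cl = length(cls), n_vss = length(vsss),
    methods = tab
  ), class = "human_summary")
}

#' @export
print.human_summary <- function(x, ...) {
  cat("<human_summary>\n")
  print(x$methods, row.names = FALSE)
  cat(sprintf("  CL  %.3g +/- %.2g L/h/kg (n=%d)\n", x$cl_mean, x$cl_sd,
              x$n_cl))
  cat(sprintf("  Vss %.3g +/- %.2g L/kg (n=%d)\n", x$vss_mean, x$vss_sd,
              x$n_vss))
  cat(sprintf("  t1/2 from means: %.3g h\n", x$t_half))
  invisible(x)
}

#' All scaling-method predictions for the default dataset
#'
#' Convenience wrapper running the clearance methods (NAS_fub,
#' Tang-Mayersohn, simple allometry / rule of exponents) and the volume
#' methods (SA_fub, Oie-Tozer, human-dog proportionality) on a species table
#' and combining them.
#'
#' @inheritParams nas_fub_cl
#' @return A `human_summary` (see [combine_predictions()]).
#' @export
predict_human_pk <- function(records = species_records(), human_bw = 70) {
  dog <- species_row(records, "dog")
  hu <- species_row(records, "human")
  preds <- list(
    nas_fub_cl(records, human_bw),
    tang_mayersohn_cl(records, human_bw),
    rule_of_exponents_cl(records, human_bw),
    sa_fub_vss(records, human_bw),
    oie_tozer_vss(records),
    dog_proportionality_vss(dog$vss_obs, hu$fu_plasma, dog$fu_plasma)
  )
  combine_predictions(preds)
}
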