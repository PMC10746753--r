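#' Physiological scaling constants for hepatic clearance extrapolation
#'
#' Standard literature values for hepatocellularity, microsomal protein yield,
#' liver weight, and hepatic blood flow, per species. All values are
#' overridable through the `...` arguments, since such system constants vary
#' between sources.
#'
#' @param species One of mouse, rat, monkey, dog, human.
#' @param hepatocellularity 10^6 cells per g liver.
#' @param microsomal_protein mg microsomal protein per g liver.
#' @param liver_weight g liver per kg body weight.
#' @param q_h Hepatic blood flow (L/h/kg).
#' @return A list of class `physio_constants`.
#' @export
physio_constants <- function(species,
                             hepatocellularity = NULL,
                             microsomal_protein = NULL,
                             liver_weight = NULL,
                             q_h = NULL) {
  defaults <- list(
    mouse  = list(hepatocellularity = 120, microsomal_protein = 45,
                  liver_weight = 55.0, q_h = 5.4),
    rat    = list(hepatocellularity = 117, microsomal_protein = 45,
                  liver_weight = 36.6, q_h = 3.31),
    monkey = list(hepatocellularity = 120, microsomal_protein = 45,
                  liver_weight = 35.0, q_h = 2.62),
    dog    = list(hepatocellularity = 215, microsomal_protein = 45,
                  liver_weight = 32.9, q_h = 1.85),
    human  = list(hepatocellularity = 99, microsomal_protein = 40,
                  liver_weight = 24.4, q_h = 1.16)
  )
  if (!species %in% names(defaults))
    stop(sprintf("unknown species '%s'", species))
  p <- defaults[[species]]
  for (nm in c("hepatocellularity", "microsomal_protein", "liver_weight",
               "q_h")) {
    override <- get(nm)
    if (!is.null(override)) p[[nm]] <- override
  }
  if (any(unlist(p) <= 0)) stop("all physiological constants must be positive")
  structure(c(list(species = species), p), class = "physio_constants")
}

#' Fraction unbound in a microsomal incubation
#'
#' Lipophilicity-based estimate of nonspecific microsomal binding:
#' fu_inc = 1 / (1 + P * 10^(0.072 logD^2 + 0.067 logD - 1.126)), where P is
#' the microsomal protein concentration in the incubation.
#'
#' @param logd Octanol-buffer distribution coefficient (log10).
#' @param protein_conc Microsomal protein concentration P (mg/mL), >= 0.
#' @return Fraction unbound in the incubation, in (0, 1].
#' @export
microsomal_fu_inc <- function(logd, protein_conc) {
  if (!is.numeric(protein_conc) || any(protein_conc < 0))
    stop("'protein_conc' must be non-negative")
  1 / (1 + protein_conc * 10^(0.072 * logd^2 + 0.067 * logd - 1.126))
}

#' Scale in vitro intrinsic clearance to whole-liver intrinsic clearance
#'
#' Multiplies the unbound in vitro intrinsic clearance by the per-gram-liver
#' cell or protein yield and liver weight per kg body weight, converting
#' uL/min to L/h.
#'
#' @param clu_int Unbound intrinsic clearance, uL/min per 10^6 cells
#'   (`system = "hepatocyte"`) or per mg microsomal protein
#'   (`system = "microsome"`).
#' @param system In vitro system.
#' @param constants A [physio_constants()] object.
#' @return Whole-body in vivo intrinsic clearance (L/h/kg).
#' @examples
#' scale_clint(6.0, "hepatocyte", physio_constants("human"))
#' @export
scale_clint <- function(clu_int, system = c("hepatocyte", "microsome"),
                        constants) {
  system <- match.arg(system)
  if (!is.numeric(clu_int) || any(clu_int < 0))
    stop("'clu_int' must be non-negative")
  yield <- switch(system,
                  hepatocyte = constants$hepatocellularity,
                  microsome = constants$microsomal_protein)
  # uL/min -> L/h: 1e-6 * 60
  clu_int * yield * constants$liver_weight * 1e-6 * 60
}

#' Hepatic plasma clearance from intrinsic clearance
#'
#' The default model evaluates
#' CL_H = Qh * fu * CLint / (Qh + fu * CLint / (B/P)),
#' the binding- and blood-partitioning-corrected liver blood-flow model in
#' plasma-clearance form. `model = "parallel-tube"` instead uses the
#' parallel-tube (tube) liver model on blood clearance,
#' CL_b = Qh * (1 - exp(-fu * CLint / (Qh * B/P))), converted back to plasma
#' clearance, for sensitivity analysis.
#'
#' @param q_h Hepatic blood flow (L/h/kg).
#' @param fu Fraction unbound in plasma.
#' @param clint In vivo intrinsic clearance (L/h/kg), from [scale_clint()].
#' @param bp Blood-to-plasma concentration ratio.
#' @param model `"well-stirred"` (the printed-form default) or
#'   `"parallel-tube"`.
#' @return Hepatic plasma clearance (L/h/kg), bounded above by `q_h * bp`.
#' @export
hepatic_clearance <- function(q_h, fu, clint, bp,
                              model = c("well-stirred", "parallel-tube")) {
  model <- match.arg(model)
  if (!is.numeric(q_h) || q_h <= 0) stop("'q_h' must be positive")
  if (fu <= 0 || fu > 1) stop("'fu' must be in (0, 1]")
  if (bp <= 0) stop("'bp' must be positive")
  if (any(clint < 0)) stop("'clint' must be non-negative")
  switch(model,
    "well-stirred" = q_h * fu * clint / (q_h + fu * clint / bp),
    "parallel-tube" = {
      cl_blood <- q_h * (1 - exp(-fu * clint / (q_h * bp)))
      cl_blood * bp
    })
}

#' Hepatic extraction ratio
#'
#' First-pass hepatic extraction as a percentage of liver blood flow,
#' 100 * CL / Qh.
#'
#' @param cl_plasma Plasma clearance (L/h/kg).
#' @param q_h Hepatic blood flow (L/h/kg).
#' @return Extraction ratio in percent.
#' @export
extraction_ratio <- function(cl_plasma, q_h) {
  if (!is.numeric(q_h) || q_h <= 0) stop("'q_h' must be positive")
  if (any(cl_plasma < 0)) stop("'cl_plasma' must be non-negative")
  100 * cl_plasma / q_h
}

#' Predict in vivo clearance for each species from hepatocyte data
#'
#' Runs the full in vitro to in vivo extrapolation chain
#' ([scale_clint()] then [hepatic_clearance()]) for each species in a
#' records table, using per-species [physio_constants()].
#'
#' @param records A species table as returned by [species_records()].
#' @param system In vitro system to scale from.
#' @param model Liver model passed to [hepatic_clearance()].
#' @return A data.frame with species, predicted plasma clearance
#'   (`cl_pred`, L/h/kg), observed clearance (`cl_obs`, NA for human), and
#'   `fold_error` (cl_pred / cl_obs).
#' @export
ivive_clearance <- function(records = species_records(),
                            system = c("hepatocyte", "microsome"),
                            model = "well-stirred") {
  system <- match.arg(system)
  clcol <- switch(system, hepatocyte = "clint_hep", microsome = "clint_mic")
  pred <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    pc <- physio_constants(r$species)
    clint <- scale_clint(r[[clcol]], system, pc)
    hepatic_clearance(pc$q_h, r$fu_plasma, clint, r$bp_ratio, model)
  }, numeric(1))
  data.frame(species = records$species, cl_pred = pred,
             cl_obs = records$cl_obs,
             fold_error = pred / records$cl_obs,
             stringsAsFactors = FALSE)
}
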