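#' Species in vitro and in vivo parameter table
#'
#' The cross-species reference data used throughout the package: body weight,
#' plasma protein binding (median fraction unbound at 5 uM), blood-to-plasma
#' concentration ratio, unbound intrinsic clearance in hepatocytes
#' (uL/min/10^6 cells) and in liver microsomes (uL/min/mg protein), and the
#' in vivo PK parameters from non-compartmental analysis of single-dose i.v.
#' studies (plasma clearance, steady-state volume, oral bioavailability).
#' The human row carries the in vitro measurements only; its in vivo fields
#' are `NA` (they are what the scaling methods predict).
#'
#' @return A data.frame with one row per species (mouse, rat, monkey, dog,
#'   human) and columns `species`, `body_weight` (kg), `fu_plasma` (fraction),
#'   `bp_ratio`, `clint_hep` (uL/min/10^6 cells), `clint_mic`
#'   (uL/min/mg protein), `cl_obs` (L/h/kg), `vss_obs` (L/kg), `f_obs`
#'   (fraction).
#' @examples
#' species_records()
#' @export
species_records <- function() {
  data.frame(
    species     = c("mouse", "rat", "monkey", "dog", "human"),
    body_weight = c(0.029, 0.270, 4.60, 8.36, 70),
    fu_plasma   = c(0.032, 0.096, 0.044, 0.019, 0.018),
    bp_ratio    = c(0.71, 0.74, 0.73, 0.59, 0.58),
    clint_hep   = c(120, 30, 3.8, 3.6, 6.0),
    clint_mic   = c(60, 29, 19, 11, 12),
    cl_obs      = c(0.378, 0.350, 0.078, 0.034, NA),
    vss_obs     = c(0.37, 1.30, 0.41, 0.23, NA),
    f_obs       = c(0.38, 0.72, 0.68, 0.80, NA),
    stringsAsFactors = FALSE
  )
}

#' Fitted mouse xenograft PK parameters
#'
#' Naive-pooled estimates from the single-dose and 4-day repeat-dose mouse
#' xenograft PK studies: absorption rate fixed at 2.7 1/h, apparent clearance
#' 0.415 L/h/kg, apparent volume 1.034 L/kg.
#'
#' @return A [pk_params()] object.
#' @export
mouse_pk_params <- function() pk_params(ka = 2.7, cl_f = 0.415, v_f = 1.034)

#' Fitted mouse xenograft PD parameters
#'
#' Estimates of the effect-compartment/turnover model for the Met-EF1alpha
#' biomarker: ke0 0.0566 1/h, kin 29.1 ug/mg/h, kout 1.45 1/h, Imax 0.91,
#' IC50 340 ng/mL (baseline kin/kout ~ 20.1 ug/mg).
#'
#' @return A [pd_params()] object.
#' @export
mouse_pd_params <- function() {
  pd_params(ke0 = 0.0566, kin = 29.1, kout = 1.45, imax = 0.91, ic50 = 340)
}

#' Molar mass of the compound
#'
#' Derived from the reported equivalence of the fitted IC50 (340 ng/mL and
#' 0.88 uM total): 340 / 0.88 ~ 386.4 g/mol.
#'
#' @return Molar mass in g/mol.
#' @export
compound_molar_mass <- function() 386.4

# fetch one species row, erroring informatively
species_row <- function(tab, species) {
  i <- match(species, tab$species)
  if (is.na(i)) stop(sprintf("species '%s' not found in records", species))
  tab[i, , drop = FALSE]
}

# check that required fields are present (non-NA) for given species rows
require_fields <- function(tab, fields) {
  for (f in fields) {
    bad <- is.na(tab[[f]])
    if (any(bad))
      stop(sprintf("field '%s' missing for species: %s",
                   f, paste(tab$species[bad], collapse = ", ")))
  }
  invisible(tab)
}
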