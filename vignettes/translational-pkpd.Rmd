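---
title: "Methods: translational PK/PD modeling with metapkpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational PK/PD modeling with metapkpd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapkpd)
```

# Scope

`metapkpd` implements a complete preclinical-to-clinical translation
workflow for an oral MetAP2 inhibitor: cross-species prediction of human PK
parameters, a mouse xenograft PK/PD model for the Met-EF1α target-engagement
biomarker, sequential pooled estimation, synthetic study generation, and
projection of the human dose achieving a biomarker target. This vignette
records the models, their assumptions, and every numerical and design choice
a maintainer would want to know about.

Units are fixed package-wide: time in hours, plasma concentration in ng/mL,
dose in mg/kg (human doses in mg are normalised by body weight), clearance
in L/h/kg, volumes in L/kg, and the biomarker in µg per mg total tumor
protein. The mg/L to ng/mL factor of 1000 is applied inside model code,
never by the caller.

# Human PK prediction

## Allometric methods

All regressions are ordinary least squares of log10(absolute quantity) on
log10(body weight) over mouse, rat, monkey and dog (`fit_loglog()`), using
the species *mean* parameters of the packaged tables; per-animal profiles
are not available. The corrected methods are:

* **Clearance, fu- and CLint-corrected (`nas_fub_cl()`):** each species'
  absolute clearance is divided by its plasma fraction unbound and
  multiplied by the human-to-species ratio of microsomal intrinsic
  clearance before regression; the power law is evaluated at the human body
  weight (default 70 kg, configurable — the human weight is a convention,
  not a measured input) and back-multiplied by the human fu.
* **Volume, fu-corrected (`sa_fub_vss()`):** the same construction on
  (Vss/fu)·BW.
* **Rule of exponents (`rule_of_exponents_cl()`):** simple allometry of
  absolute CL; if the fitted exponent b < 0.71 the plain prediction is
  used, for 0.71 ≤ b ≤ 1 the maximum-lifespan-potential product method, and
  for b > 1 the brain-weight product method. MLP and brain weights are
  shipped as a documented fixture table (`mlp_brw_table()`) of standard
  literature values. On the packaged data b ≈ 0.58, so the plain branch is
  taken; the product branches are exercised by constructed data in tests.
* **Tang–Mayersohn (`tang_mayersohn_cl()`):** CL(mL/min) =
  33.35·(a/Rfu)^0.77 with a the simple-allometry coefficient at 1 kg and
  Rfu the rat-to-human fu ratio. The package uses the same 5 µM-median fu
  column for every method; which fu variant the original method authors
  intended is genuinely ambiguous, and the prediction is sensitive to the
  choice (a ~2× spread of fu_rat/fu_human maps to a 2^0.77 factor), so the
  species table is an explicit argument everywhere.
* **Øie–Tozer (`oie_tozer_vss()`):** the tissue unbound fraction fu_t is
  solved per animal species from observed Vss, averaged, and applied
  forward with human constants. The physiological volumes (Vp, Ve, Vr) and
  the extra-/intravascular binding ratio RE/I = 1.4 are standard literature
  values shipped in `oie_tozer_constants()`; they are a recognised source
  of between-implementation variation and are overridable.
* **Human–dog proportionality (`dog_proportionality_vss()`):**
  V_human = V_dog · fu_human/fu_dog.

`combine_predictions()` averages the available per-method CL and Vss
(arithmetic mean ± sample SD). The derived half-life is
t1/2 = ln(2)·Vss/CL — note the deliberate form: the dimensionally consistent
version of the relation, which reproduces the combination of a ~0.02 L/h/kg
clearance and ~0.21 L/kg volume into a ~7 h half-life. (The relation is
sometimes misprinted with CL and Vss swapped; the package always computes
ln(2)·V/CL.)

## IVIVE of hepatic clearance

`scale_clint()` converts unbound intrinsic clearance measured in hepatocytes
(µL/min/10⁶ cells) or microsomes (µL/min/mg protein) to whole-body in vivo
CLint via hepatocellularity or microsomal protein yield per gram liver and
liver weight per kg body weight. `hepatic_clearance()` then applies

CL_H = Qh·fu·CLint / (Qh + fu·CLint/(B/P)),

the binding- and blood-partitioning-corrected liver blood-flow model in its
plasma-clearance algebraic form. This printed form is algebraically the
venous-equilibrium ("well-stirred") expression; a true parallel-tube
alternative, CL_b = Qh·(1 − e^(−fu·CLint/(Qh·B/P))) converted back to plasma
clearance, is available behind `model = "parallel-tube"` for sensitivity
analysis. The two agree in the low-extraction limit relevant here (~1–2%
hepatic extraction in human).

The default physiological constants (`physio_constants()`) were chosen once
from published ranges — human 99×10⁶ cells/g, 24.4 g liver/kg, Qh
1.16 L/h/kg; animal values scaled similarly — such that the four-species
hepatocyte extrapolation reproduces observed clearances within the ~0.5–3
fold band typical of this technique, and they are deliberately exposed as
arguments: hepatocellularity and liver-weight tabulations differ between
sources by up to ~50%, and the mouse and monkey predictions sit near the
band edges under any standard set.

# The xenograft PK/PD model

## Structure and assumptions

PK is a one-compartment model with first-order absorption and elimination,
parameterised by apparent oral constants (ka, CL/F, V/F); linearity and
time-invariance are assumed (superposition is used for repeated dosing).
PD is an effect compartment, dCe/dt = ke0·(C − Ce) with Ce(0) = 0 (the
standard initial condition for a pre-treatment-naive animal), driving
inhibition of biomarker degradation:

dE/dt = kin − kout·E·(1 − Imax·Ce/(Ce + IC50)),  E(0) = kin/kout.

Consequences used as invariants throughout the tests: E is bounded below by
the baseline kin/kout and above by the ceiling kin/(kout·(1 − Imax)); the
steady-state minimum of E is monotone increasing in dose; and because the
effect compartment is a linear filter of a sum of exponentials, Ce has an
exact closed form (`ce_regimen()`), which the package checks against direct
ODE integration.

## Numerical choices

* `simulate_pkpd()` integrates with `deSolve::lsoda`, rtol 1e-8 / atol
  1e-10, output on a 0.1 h grid by default; plasma concentration enters as
  the exact closed form, never interpolated.
* The estimation objective uses a fixed-step classical RK4 integrator
  (step 0.1 h) on the single biomarker state, with the loss rate
  precomputed from the analytic Ce on a half-step grid. Two reasons: it is
  an order of magnitude faster than the adaptive route for the small, stiff-
  free systems involved, and — decisive for optimisation — it is a smooth,
  deterministic function of the parameters, so finite-difference Jacobians
  are clean. Adaptive integrators change their step sequence with the
  parameters, and that discretisation noise is large relative to the
  square-root-of-epsilon finite-difference steps. The fixed-step path is
  validated against the adaptive one to ~1e-7 relative in the test suite.
* Steady state (`steady_state_metrics()`) is declared when the per-interval
  change in both the trough concentration and the biomarker minimum falls
  below 0.1% (a convention), with a hard cap of ten PK half-lives plus
  10/ke0, and an optional minimum simulated time (the packaged analyses use
  ≥ 14 days for the efficacious-regimen simulation).

## Estimation

The studies use destructive sampling — each animal contributes one plasma
and one tumor sample — so there is no within-subject information and the
package fits naive-pooled models; mixed-effects estimation is deliberately
out of scope. Fitting (`fit_pk()`, `fit_pd()`) is least squares on
log-transformed observations (multiplicative, lognormal error), sequential:
the PD step takes the PK parameters as fixed and uses model-predicted
concentrations, not observed ones. Positivity is enforced by log
parameterisation (logit for Imax ∈ [0,1]); CV% come from the asymptotic
Jacobian-based covariance by the delta method; −2LL, AIC and BIC are
computed from the Gaussian likelihood on the log scale. The optimiser is
Levenberg–Marquardt (`minpack.lm`) from five starts — the supplied or
data-driven initial values plus four jittered copies from a fixed offset
table (deterministic, so results do not depend on the caller's RNG state).
The absorption rate constant is fixed at ka = 2.7 h⁻¹ by default for the PK
fit; its provenance in the original analysis is not documented, so it is an
ordinary argument rather than a constant.

Degenerate data are flagged rather than hidden: a biomarker dataset that
never leaves baseline leaves IC50/Imax unidentified, which surfaces as
singular information or CV% > 100 with a warning.

# Synthetic studies

`generate_study()` emulates the three xenograft designs: single oral doses
of 10/25/100 mg/kg sampled at 1, 7, 24, 48, 72, 96 h (five animals per
timepoint); the same doses once daily for four days, sampled at the same
offsets after the last dose; and six weeks of daily dosing sampled at 1, 7,
24 h after the day-42 dose (ten animals per timepoint). Observations are
model predictions perturbed by multiplicative lognormal noise with median 1
and natural-scale CV of 20% by default — a typical preclinical assay spread,
declared as a convention because the residual variability of the biomarker
assay is not reported. Same-seed regeneration is bit-identical.

What the generator does *not* emulate: inter-animal PK/PD variability
(random effects), tumor growth dynamics, assay censoring/limits of
quantification, and any model misspecification. Passing parameter-recovery
tests therefore demonstrates that the estimation machinery is consistent
under the assumed model and noise — not that the model is correct for real
xenograft data.

# Biomarker target and human projection

`derive_pd_target()` simulates the minimal efficacious mouse regimen
(25 mg/kg twice daily) to steady state and rounds the biomarker minimum
*down* to a 25 µg/mg granularity. The raw minimum is ~130–135 µg/mg; the
conservative round level the trajectory stays above is 125 µg/mg. A finer
granularity (e.g. 5) would track the raw minimum instead of a round working
threshold; granularity is an argument.

`find_human_dose()` replaces the PK arm with the predicted human parameters
(defaults: CL 0.020 L/h/kg, Vss 0.21 L/kg — the cross-method means; F 0.6;
ka 0.35 h⁻¹; 70 kg), keeps the mouse PD parameters unchanged (the
assumption being that human tumor xenograft pharmacology carries over), and
searches the smallest dose on a 5 mg grid whose steady-state biomarker
minimum meets the target, by doubling then bisection — valid because e_min
is monotone in dose.

The absorption inputs deserve emphasis. The original analysis built the
ascending arm of the human profile with a proprietary PBPK model that is
not reconstructible from published information; here F and ka are explicit
one-compartment inputs. The projected *dose* is strongly sensitive to them
(the scan over F ∈ [0.6, 0.8] and body weight ∈ [60, 70] kg spans roughly a
1.5-fold dose range), whereas the steady-state *trough concentration*
associated with hitting the target is pinned by the clearance–PD link and
barely moves across the scan. `sensitivity_scan()` exists to make exactly
this distinction visible, and the test suite asserts it rather than any
single dose number.

# Problem sizes and limitations

The test suite and the acceptance script run everything at the study's own
scale: four species for the regressions, 540 observations per endpoint for
a pooled synthetic fit, ten replicate seeds for the recovery experiment,
and 14–28 simulated days for steady-state metrics; the full suite completes
in a few minutes on one core. Known limitations: no mixed-effects or
Bayesian estimation; no nonlinear PK, absorption lag, or enterohepatic
recirculation; no tumor-growth model (the efficacious regimen is an input,
not an output); NCA supports single-profile i.v./oral analysis, not urine
data or partial AUCs; and the IVIVE physiological constants are
literature conventions, not measured quantities.
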