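Package: metapkpd
Title: Translational Pharmacokinetic/Pharmacodynamic Modeling for a
    MetAP2 Inhibitor Program
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the preclinical-to-clinical translation of an oral
    methionine aminopeptidase 2 (MetAP2) inhibitor. Implements human
    pharmacokinetic parameter prediction by allometric scaling (simple
    allometry, rule of exponents, fu-corrected and CLint-corrected
    four-species scaling, Tang-Mayersohn, Oie-Tozer, human-dog
    proportionality) and in vitro-in vivo extrapolation of hepatic
    clearance; non-compartmental analysis of concentration-time profiles;
    a one-compartment oral PK model coupled to an effect-compartment plus
    turnover model for the Met-EF1alpha target-engagement biomarker in
    mouse xenografts; naive-pooled sequential PK/PD estimation with
    multiplicative error; synthetic destructive-sampling study generation;
    and projection of the human dose and steady-state trough concentration
    achieving a pharmacodynamic target level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
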