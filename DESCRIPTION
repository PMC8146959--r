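Package: ketoflux
Title: Dual-Tracer Two-Pool Flux Analysis of Ketone Body Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of in vivo ketone body kinetics from dual stable-isotope
    tracer infusions of beta-hydroxybutyrate (BHB) and acetoacetate (AcAc).
    Implements decoding of the combined deuterium-tagged BHB mass isotopomer
    distribution produced by in situ borodeuteride reduction of AcAc, natural
    abundance correction, the exact matrix solution of the steady-state
    two-pool model (rates of appearance, disposal and interconversion for both
    ketones), an isotopomer-network forward simulator, and a weighted
    least-squares regression of isotopologue fractions and infusion rates that
    yields profile-likelihood confidence intervals, per-flux precision scores
    and data-inconsistency diagnostics. Includes single-tracer dilution
    estimators for comparison, an infusion-rate error sensitivity analysis and
    a synthetic-experiment generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
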