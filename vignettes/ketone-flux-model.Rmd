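---
title: "The two-pool model of ketone turnover: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-pool model of ketone turnover: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ketoflux)
```

## The measurement this package models

Acetoacetate (AcAc) and β-hydroxybutyrate (BHB) are produced by the liver,
consumed by peripheral tissues, and interconverted by β-hydroxybutyrate
dehydrogenase in both liver and periphery. Because the two circulating pools
exchange on a timescale comparable to their turnover, neither a single-BHB
nor a single-AcAc dilution experiment measures ketone kinetics correctly: a
two-pool model with distinguishable tracers in each pool is required.

The experimental design this package analyzes infuses [U-¹³C₄]BHB and
[3,4-¹³C₂]AcAc simultaneously at constant rates (defaults 2.08 and
1.91 µmol/h per mouse). Because AcAc is chemically labile, blood is treated
immediately with sodium borodeuteride, which reduces every AcAc molecule to
a BHB carrying one deuterium. A single LC-MS/MS measurement of BHB
isotopologues M+0…M+5 therefore encodes both pools: even mass shifts are
plasma BHB, odd mass shifts are plasma AcAc displaced by the deuterium tag,
and the total odd-channel fraction is the AcAc share of the combined ketone
signal.

## Decoding and natural-abundance handling

`correct_natural_abundance()` inverts the theoretical isotope envelope of
the unlabeled atoms of the measured ion. The default formula is the
four-carbon skeleton at ¹³C abundance 0.0107; hydrogen and oxygen
contributions of either the precursor or product ion can be added through
`ion_formula()` because the fragment actually integrated differs between
instruments. Tracer carbons and the derivatization deuterium are part of the
labeled skeleton and are excluded from the correction. Two numerical points
matter:

* the convolution matrix is lower triangular (a molecule can only gain
  mass from natural isotopes), so truncating the envelope to the six
  measured channels does not mix the retained channels, and the 6×6
  correction is exact after renormalization;
* fractions driven slightly negative by measurement noise are clipped to
  zero and the vector renormalized; clips above 0.005 mol fraction raise a
  warning because they indicate a data problem rather than noise.

`decode_combined_mid()` then splits even/odd channels into the individual
BHB and AcAc distributions and the pool share. Under these tracers in vivo
carbon labeling occupies only even shifts, so any odd-carbon signal
remaining *within* a decoded pool is a data-quality diagnostic, not biology.

## The exact matrix solution

At steady state the model is six linear mass balances — total AcAc, total
BHB, and one balance per tracer species per pool — in the six unknown
fluxes (Ra, Ri, Rd for each ketone), driven by the two infusion rates and
the four enrichments *A* (AcAc M+2), *B* (BHB M+2), *C* (AcAc M+4), *D*
(BHB M+4). `two_pool_matrix()` assembles the coefficient matrix and
`solve_two_pool()` solves it exactly. The solution is linear in the infusion
rates, which makes the infusion-error sensitivity analysis
(`sensitivity_scan()`) exactly affine in the relative error ε — a property
the test suite asserts to machine precision rather than estimates.

The matrix method solves *any* enrichment set, including flawed ones; it
signals trouble only by returning physiologically implausible (negative)
fluxes, which are flagged but not suppressed. The condition number is
reported and a warning is emitted above 1e8, since near-singular enrichment
sets let small measurement errors flip flux signs.

## The isotopomer network and forward simulator

`build_network()` writes out the eleven atom-transition reactions of the
regression model, including zero-stoichiometry sampling reactions that
expose blood labeling (with the deuterium tag on AcAc-derived molecules)
without entering the mass balances. Because no reaction cleaves or condenses
the tracked carbon skeleton, isotopologue balances close at the level of
whole-molecule MIDs; the simulator therefore solves one 2×2 linear system
per carbon mass (`simulate_steady_state()`) instead of running a generic
elementary-unit decomposition. This is exact, not an approximation, and the
atom maps are still validated for conservation so the network remains the
source of truth if it is ever extended. An independent dense 6×6 solve is
kept in the test suite as an oracle against the specialized path.

## The regression, its weights and its degrees of freedom

`fit_fluxes()` minimizes the weighted squared mismatch of the six
isotopologue fractions (default σ = 0.003 mol fraction, a typical LC-MS/MS
MID precision) and the two infusion rates (default 2% relative). The free
parameters are the four endogenous fluxes, the two infusion fluxes and the
pool ratio; disposal fluxes are reconstructed from the node balances, so
mass balance holds exactly at every iterate rather than being penalized.
Fluxes are bounded below at zero. Optimization is Levenberg–Marquardt
(`minpack.lm`) from a warm start at the exact matrix solution plus seeded
random log-uniform multistarts; identical seed, configuration and data give
bit-identical results.

The design has zero degrees of freedom: five independent MID fractions plus
two rate measurements against seven parameters
(`count_degrees_of_freedom()`). The regression therefore reproduces the
matrix solution exactly on consistent data — the point of carrying both
implementations is that they are mutually validating — and adds what the
matrix method lacks: bounds, confidence intervals and residual diagnostics.

Profile-likelihood intervals (`profile_confidence_interval()`) re-optimize
all other parameters while walking one flux until the SSR rises by
χ²(0.95, 1) = 3.841, with bisection refinement and truncation at the flux
bound; disposal fluxes are profiled through the balance substitution.
The precision score `exp(-r/3)` of the normalized interval width `r` maps
each interval to (0, 1]; a zero-width interval scores 1, and a non-negative
flux whose interval spans 0 to ≥2× the estimate floors at
`exp(-2/3) ≈ 0.513`.

## What inconsistency detection can and cannot see

With zero degrees of freedom, a consistent data set admits an exact fit, so
`residual_report()` flags inconsistency whenever the best SSR exceeds a
small floor (default 1e-3) and ranks the weighted residuals to point at the
worst-fitting measurements. It is important to be precise about what is
detectable:

* **Detectable:** any corruption that forces the exact solution outside the
  non-negative flux cone. The canonical example is an *understated*
  infusion rate at strong interconversion — the bounded fit cannot
  reconcile the enrichments with the reported rate, the SSR rises sharply,
  and the matrix method run on the same data returns negative fluxes.
* **Not detectable:** corruptions whose implied exact solution remains
  non-negative. Undetected tracer loss (an *overstated* reported rate)
  simply rescales the solution along the sensitivity line and remains
  feasible under realistic physiology; likewise, zeroing the M+5 channel
  always admits an exact solution with Ri BHB = 0 — one can show the
  alternative would require a negative Ra BHB or Rd AcAc in the generating
  system, which cannot occur. A uniquely determined model cannot
  distinguish these data sets from genuine biology; only measuring the
  infusate concentration directly (`adjust_infusion_rate()`) closes that
  gap.

This asymmetry is a property of the model structure, not of the optimizer,
and the test suite encodes both directions.

## The synthetic generator

`scenario_preset()` provides four ground-truth states spanning fed to
obese-fasted metabolism. The magnitudes are synthetic but chosen on
physiological grounds fixed before any testing: total Ra spans ~2.5-fold
from fed (6.5 µmol/h) to fasted (16 µmol/h); interconversion escalates with
ketosis and AcAc→BHB exchange exceeds the reverse in the moderate states;
the AcAc share of the pool falls as ketosis deepens; and the obese-fasted
state carries strong bidirectional exchange with a small AcAc disposal.
Infusion rates are the standard protocol values.

`generate_experiment()` layers, in order: undetected tracer loss (effective
rates scaled by 1 − loss while the reported protocol keeps nominal rates),
Gaussian pump variation, selective attenuation of the odd channels by the
derivatization completeness (which shifts the decoded pool share but — as
the model predicts — leaves every flux estimate untouched, because the
balances use only within-pool enrichment ratios), optional
natural-abundance convolution, and additive truncated-Gaussian fraction
noise with renormalization. The generator emulates the *statistical*
structure the analysis assumes: steady state, independent per-fraction
noise, pure tracers by default. It does not emulate drifting enrichments,
correlated channel noise, pseudoketogenesis exchange with tissue
acetoacetyl-CoA, or tissue compartments — so passing tests demonstrate
correctness of the estimators under the model's own assumptions, not
robustness to every failure mode of real data.

## Numerical choices and problem sizes

Tolerances follow the structure of each computation: exact linear-algebra
identities are tested at 1e-9–1e-10; the regression-vs-matrix equivalence
at 1e-6 relative (optimizer tolerance, not model error). Monte-Carlo checks
in the test suite use 100 random flux states for the oracle-equivalence
sweep and 200 noisy replicates for coverage and bias of the profile
intervals (observed: ~93% coverage at the 95% level, median per-flux bias
under 5%); these sizes give stable verdicts while keeping the default test
run fast. The multistart count in routine fits can be small because the
matrix warm start is already in the basin of the global optimum on
consistent data; multistarts matter mainly for corrupted data, where the
objective is genuinely non-convex.

## Known limitations

* Steady state only: prime-infusion metadata is carried but unused; no
  time-course kinetics.
* Whole-body pools: hepatic versus peripheral interconversion is not
  resolved, so individual Ra values inherit the interpretation caveats of
  any two-pool model (their sum is the robust quantity).
* Pseudoketogenesis is not modeled; it can inflate apparent AcAc turnover.
* The precision scores published for real cohorts depend on per-animal
  data that are not public; this package reproduces the score *definition*
  and its analytic properties, not those cohort values.
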