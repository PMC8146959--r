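# ketoflux

Estimation of in vivo ketone body kinetics from dual stable-isotope tracer
infusions.

## The problem

Ketone turnover cannot be measured with a single tracer: acetoacetate
(AcAc) and β-hydroxybutyrate (BHB) interconvert in vivo too fast to be
independent pools and too slowly to be one pool. The established design
infuses [U-¹³C₄]BHB and [3,4-¹³C₂]AcAc simultaneously at known rates,
reduces blood AcAc in situ with sodium borodeuteride (NaB²H₄) so that every
AcAc becomes a deuterium-tagged BHB, and measures one combined BHB mass
isotopomer distribution (MID) M+0…M+5 by LC-MS/MS. Even mass shifts are
plasma BHB; odd shifts are plasma AcAc displaced by +1.

`ketoflux` is for investigators running such experiments in rodents or
humans. It takes the combined MID and the two infusion rates and returns
the six fluxes of the steady-state two-pool model — rates of appearance
(*Ra*), disposal (*Rd*) and interconversion (*Ri*) for each ketone — with
confidence intervals, precision scores and data-consistency diagnostics.

## The model

At steady state the system obeys six linear mass balances. With enrichments
*A* = AcAc M+2, *B* = BHB M+2, *C* = AcAc M+4, *D* = BHB M+4:

```
Rinf_AcAc + Ra_AcAc + Ri_BHB          = Rd_AcAc + Ri_AcAc        (total AcAc)
Rinf_BHB  + Ra_BHB  + Ri_AcAc         = Rd_BHB  + Ri_BHB         (total BHB)
Rinf_AcAc + B·Ri_BHB                  = A·(Rd_AcAc + Ri_AcAc)    (¹³C₂ AcAc)
Rinf_BHB  + C·Ri_AcAc                 = D·(Rd_BHB + Ri_BHB)      (¹³C₄ BHB)
A·Ri_AcAc                             = B·(Ri_BHB + Rd_BHB)      (¹³C₂ BHB)
D·Ri_BHB                              = C·(Ri_AcAc + Rd_AcAc)    (¹³C₄ AcAc)
```

Two complementary solvers are provided. `solve_two_pool()` solves the
system exactly in matrix form, `E · R = P`. `fit_fluxes()` regresses the
same data against the isotopomer network (11 atom-transition reactions,
including zero-stoichiometry sampling reactions that encode the AcAc:BHB
pool ratio) by weighted bounded least squares; on consistent data the two
agree to optimizer precision, and the regression additionally yields
profile-likelihood confidence intervals, the precision score
`S = exp(-r/3)` of the normalized interval width, and weighted residual
diagnostics that flag inconsistent data. A sensitivity module propagates
systematic infusion-rate errors (exactly affine in the error), and a
synthetic-data module generates complete experiments with known ground
truth, including the classic failure modes (tracer loss, incomplete
derivatization).

## Worked example

A small synthetic cohort ships with the package (generated by
`generate_cohort()`; see `inst/extdata/`):

```r
library(ketoflux)
csv <- system.file("extdata", "synthetic_samples.csv", package = "ketoflux")
samples <- read_samples(csv)
out <- run_pipeline(samples[samples$sample_id == "fasted_01", ], profile = TRUE)
subset(out$report, select = -matrix_estimate)
#>   sample_id    flux estimate    lb    ub precision
#> 1 fasted_01 ra_acac    11.68  9.63 14.42     0.872
#> 2 fasted_01  ra_bhb     4.21  1.99  5.97     0.730
#> 3 fasted_01 ri_acac    12.70  9.88 17.17     0.826
#> 4 fasted_01  ri_bhb     5.42  2.49  9.82     0.637
#> 5 fasted_01 rd_acac     6.31  4.34  8.76     0.792
#> 6 fasted_01  rd_bhb    13.57 11.67 15.15     0.918
out$verdicts$verdict
#> [1] "consistent"
```

Fluxes are µmol/h per animal. This fasted-state sample turns over ketones
at `ra_acac + ra_bhb ≈ 15.9` µmol/h, with AcAc→BHB exchange (`ri_acac`)
exceeding the reverse direction, and every 95% profile interval bracketing
the estimate. Precision scores sit near 0.8 for well-determined fluxes;
`ri_bhb`, the flux least constrained by this design, scores lowest. The
`consistent` verdict means the zero-degrees-of-freedom model fit the data
exactly (SSR ≈ 0); an inconsistent data set (for example an understated
infusion rate) produces a large SSR and a ranking of the worst-fitting
measurements.

Decoding alone:

```r
d <- decode_combined_mid(mid(as.numeric(samples[4, paste0("m", 0:5)])))
d$acac_fraction          # AcAc share of the combined ketone signal
#> [1] 0.2991
unclass(enrichments_from_decoded(d))
#>          A          B          C          D
#> 0.12417046 0.08304774 0.03862086 0.13534726
```

A thin command-line wrapper lives at `inst/scripts/ketoflux.R`
(subcommands `fit`, `decode`, `simulate`, `sensitivity`; YAML configuration
as in `inst/extdata/example_run.yaml`).

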