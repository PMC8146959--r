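# Example run configuration for the ketoflux pipeline.
ion_formula:
  counts: {C: 4}          # unlabeled carbon skeleton used for NA correction
protocol:
  rinf_acac: 1.91         # umol/h, continuous infusion
  rinf_bhb: 2.08
  infusate_acac_mid: [0, 1, 0]   # M+0 / M+2 / M+4
  infusate_bhb_mid: [0, 0, 1]
fit:
  mid_sigma: 0.003        # mol fraction
  rinf_sigma_rel: 0.02
  level: 0.95
corrected: true           # fractions already corrected for natural abundance
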