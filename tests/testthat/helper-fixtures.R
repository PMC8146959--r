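# shared fixtures: all synthetic, built in code at test time

default_protocol <- tracer_protocol()

# the forward-simulation reference system used across modules
reference_flux <- function() {
  flux_state(ra_acac = 12, ra_bhb = 6, ri_acac = 8, ri_bhb = 4,
             rinf_acac = 1.91, rinf_bhb = 2.08, pool_ratio_acac = 0.3)
}

clean_experiment <- function(preset_name = "fasted") {
  generate_experiment(scenario_preset(preset_name),
                      noise_config(mid_sigma = 0, rinf_sigma_rel = 0))
}

fast_cfg <- fit_config(multistart = 5)

flux_names6 <- c("ra_acac", "ra_bhb", "ri_acac", "ri_bhb", "rd_acac", "rd_bhb")

flux_vec <- function(fl) unlist(fl[flux_names6])

# random admissible flux state: non-negative fluxes, balanced, enrichments
# end up strictly inside (0, 1)
random_flux_state <- function(protocol = default_protocol) {
  repeat {
    ra_a <- stats::runif(1, 1, 30)
    ra_b <- stats::runif(1, 1, 30)
    ri_a <- stats::runif(1, 0.5, 25)
    ri_b <- stats::runif(1, 0.5, 25)
    rd_a <- protocol$rinf_acac + ra_a + ri_b - ri_a
    rd_b <- protocol$rinf_bhb + ra_b + ri_a - ri_b
    if (rd_a > 0.5 && rd_b > 0.5) {
      return(flux_state(ra_acac = ra_a, ra_bhb = ra_b,
                        ri_acac = ri_a, ri_bhb = ri_b,
                        rinf_acac = protocol$rinf_acac,
                        rinf_bhb = protocol$rinf_bhb,
                        pool_ratio_acac = stats::runif(1, 0.1, 0.6)))
    }
  }
}
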