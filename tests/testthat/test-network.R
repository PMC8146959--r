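test_that("the network has 11 reactions with conserved atom maps and zero-stoichiometry sampling", {
  net <- build_network()
  expect_equal(nrow(net), 11L)
  expect_true(validate_network(net))
  # the AcAc-to-BHB interconversion picks up an unlabeled water hydrogen
  ri <- net[net$flux == "ri_acac", ]
  expect_equal(ri$lhs, "AcAc.blood (ABCD) + H.h2o (a)")
  expect_equal(ri$rhs, "BHB.blood (AaBCD)")
  # sampling reactions do not enter the mass balances
  expect_equal(net$stoichiometry[net$flux %in% c("rs_bhb", "rs_acac")], c(0, 0))
  # free parameters after the two node balances: 6 net fluxes + pool ratio
  expect_equal(network_free_parameters(net), 7L)
})

test_that("atom-map violations are caught", {
  net <- build_network()
  net$rhs[net$flux == "ri_acac"] <- "BHB.blood (ABCD)"  # dropped a hydrogen
  expect_error(validate_network(net), "not conserved")
  net2 <- build_network()
  net2$stoichiometry[net2$flux == "rs_acac"] <- 1
  expect_error(validate_network(net2), "stoichiometric coefficient 0")
})

test_that("steady-state simulation reproduces limiting cases", {
  # pure-tracer limit: no endogenous appearance or interconversion
  fl <- flux_state(ra_acac = 0, ra_bhb = 0, ri_acac = 0, ri_bhb = 0,
                   rinf_acac = 1.91, rinf_bhb = 2.08, pool_ratio_acac = 0.4)
  ss <- simulate_steady_state(fl, default_protocol)
  expect_equal(as.numeric(ss$acac_blood_mid), c(0, 0, 1, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(ss$bhb_blood_mid), c(0, 0, 0, 0, 1), tolerance = 1e-12)

  # unlabeled infusates: no label anywhere
  un <- tracer_protocol(infusate_acac_mid = c(1, 0, 0),
                        infusate_bhb_mid = c(1, 0, 0))
  fl2 <- reference_flux()
  ss2 <- simulate_steady_state(fl2, un)
  expect_equal(as.numeric(ss2$acac_blood_mid), c(1, 0, 0, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(ss2$bhb_blood_mid), c(1, 0, 0, 0, 0), tolerance = 1e-12)
})

test_that("per-mass solver agrees with an independent dense 6x6 linear solve", {
  set.seed(5)
  for (i in 1:10) {
    fl <- random_flux_state()
    ss <- simulate_steady_state(fl, default_protocol)
    # oracle: one dense system over all 6 unknowns (2 pools x 3 masses)
    out_a <- fl$rd_acac + fl$ri_acac
    out_b <- fl$rd_bhb + fl$ri_bhb
    big <- matrix(0, 6, 6)
    rhs <- numeric(6)
    for (j in 1:3) {
      ia <- j; ib <- 3 + j
      big[ia, ia] <- out_a; big[ia, ib] <- -fl$ri_bhb
      big[ib, ib] <- out_b; big[ib, ia] <- -fl$ri_acac
      rhs[ia] <- fl$rinf_acac * default_protocol$infusate_acac_mid[j] +
        fl$ra_acac * (j == 1)
      rhs[ib] <- fl$rinf_bhb * default_protocol$infusate_bhb_mid[j] +
        fl$ra_bhb * (j == 1)
    }
    sol <- solve(big, rhs)
    expect_lt(max(abs(as.numeric(ss$acac_blood_mid)[c(1, 3, 5)] - sol[1:3])), 1e-10)
    expect_lt(max(abs(as.numeric(ss$bhb_blood_mid)[c(1, 3, 5)] - sol[4:6])), 1e-10)
    # label conservation at each pool and mass at the returned steady state
    xa <- sol[1:3]; xb <- sol[4:6]
    for (j in 1:3) {
      inflow_a <- fl$rinf_acac * default_protocol$infusate_acac_mid[j] +
        fl$ra_acac * (j == 1) + fl$ri_bhb * xb[j]
      expect_lt(abs(inflow_a - out_a * xa[j]), 1e-10 * max(flux_vec(fl)))
    }
  }
})

test_that("simulation rejects unbalanced or degenerate flux input", {
  bad <- reference_flux()
  bad$rd_acac <- bad$rd_acac + 1   # break the AcAc balance
  expect_error(simulate_steady_state(bad, default_protocol), "balance")
  expect_error(
    simulate_steady_state(
      flux_state(ra_acac = 0, ra_bhb = 0, ri_acac = 0, ri_bhb = 0,
                 rinf_acac = 0, rinf_bhb = 0, check_balance = FALSE),
      default_protocol),
    "outflow|positive")
})

test_that("combined MID interleaves the pools with the deuterium shift", {
  # pure tracers, equal pools: AcAc M+2 appears at M+3, BHB M+4 at M+4
  fl <- flux_state(ra_acac = 0, ra_bhb = 0, ri_acac = 0, ri_bhb = 0,
                   rinf_acac = 1.91, rinf_bhb = 2.08, pool_ratio_acac = 0.5)
  cm <- simulate_combined_mid(fl, default_protocol)
  expect_equal(as.numeric(cm), c(0, 0, 0, 0.5, 0.5, 0), tolerance = 1e-12)

  # fully unlabeled system at p = 0.2
  un <- tracer_protocol(infusate_acac_mid = c(1, 0, 0),
                        infusate_bhb_mid = c(1, 0, 0))
  fl2 <- flux_state(ra_acac = 5, ra_bhb = 5, ri_acac = 2, ri_bhb = 2,
                    rinf_acac = 1.91, rinf_bhb = 2.08, pool_ratio_acac = 0.2)
  cm2 <- simulate_combined_mid(fl2, un)
  expect_equal(as.numeric(cm2), c(0.8, 0.2, 0, 0, 0, 0), tolerance = 1e-12)
})

test_that("decoding inverts the combined-MID encoding", {
  set.seed(31)
  for (i in 1:10) {
    fl <- random_flux_state()
    ss <- simulate_steady_state(fl, default_protocol)
    d <- decode_combined_mid(simulate_combined_mid(fl, default_protocol))
    expect_lt(max(abs(as.numeric(d$bhb_mid) - as.numeric(ss$bhb_blood_mid))), 1e-9)
    expect_lt(max(abs(as.numeric(d$acac_mid) - as.numeric(ss$acac_blood_mid))), 1e-9)
    expect_equal(d$acac_fraction, fl$pool_ratio_acac, tolerance = 1e-9)
  }
})

test_that("only even carbon masses are populated in blood MIDs", {
  set.seed(13)
  for (i in 1:5) {
    ss <- simulate_steady_state(random_flux_state(), default_protocol)
    expect_equal(as.numeric(ss$acac_blood_mid)[c(2, 4)], c(0, 0))
    expect_equal(as.numeric(ss$bhb_blood_mid)[c(2, 4)], c(0, 0))
  }
})
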