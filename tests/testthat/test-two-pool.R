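test_that("matrix solution reduces to independent dilution when interconversion is absent", {
  e <- enrichment_set(A = 0.10, B = 0, C = 0, D = 0.10)
  sol <- solve_two_pool(e, rinf_acac = 2, rinf_bhb = 2)
  expect_equal(sol$ri_acac, 0, tolerance = 1e-12)
  expect_equal(sol$ri_bhb, 0, tolerance = 1e-12)
  expect_equal(sol$rd_acac, 20, tolerance = 1e-9)
  expect_equal(sol$rd_bhb, 20, tolerance = 1e-9)
  expect_equal(sol$ra_acac, 18, tolerance = 1e-9)
  expect_equal(sol$ra_bhb, 18, tolerance = 1e-9)
  # agreement with the single-pool dilution formulas in this limit
  st <- single_tracer_turnover(2, 0.10)
  expect_equal(sol$ra_bhb, st[["ra"]], tolerance = 1e-9)
  expect_equal(sol$rd_bhb, st[["rd"]], tolerance = 1e-9)
})

test_that("the solution is linear in the infusion rates", {
  e <- enrichment_set(A = 0.12, B = 0.08, C = 0.04, D = 0.13)
  s1 <- flux_vec(solve_two_pool(e, 2, 2))
  s2 <- flux_vec(solve_two_pool(e, 4, 4))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # affine superposition over the two rates
  sa <- flux_vec(solve_two_pool(e, 3, 2))
  sb <- flux_vec(suppressWarnings(solve_two_pool(e, 2, 5)))
  sab <- flux_vec(suppressWarnings(solve_two_pool(e, 3 + 2 - 2, 2 + 5 - 2)))
  expect_equal(sab, sa + sb - s1, tolerance = 1e-10)
})

test_that("matrix method exactly recovers forward-simulated fluxes", {
  fl <- reference_flux()
  expect_equal(fl$rd_acac, 9.91, tolerance = 1e-12)
  expect_equal(fl$rd_bhb, 12.08, tolerance = 1e-12)
  cm <- simulate_combined_mid(fl, default_protocol)
  e <- enrichments_from_decoded(decode_combined_mid(cm))
  sol <- solve_two_pool(e, 1.91, 2.08)
  expect_lt(max(abs(flux_vec(sol) - flux_vec(fl)) / flux_vec(fl)), 1e-9)
  # the returned state satisfies all six balances
  expect_lt(max(abs(balance_residuals(sol, e))), 1e-9 * max(flux_vec(sol)))
})

test_that("recovery holds across random admissible flux states", {
  set.seed(11)
  for (i in 1:25) {
    fl <- random_flux_state()
    cm <- simulate_combined_mid(fl, default_protocol)
    sol <- solve_two_pool(enrichments_from_decoded(decode_combined_mid(cm)),
                          fl$rinf_acac, fl$rinf_bhb)
    expect_lt(max(abs(flux_vec(sol) - flux_vec(fl)) /
                    pmax(flux_vec(fl), 1e-6)), 1e-9)
  }
})

test_that("singular enrichment systems raise an inconsistency error", {
  expect_error(solve_two_pool(enrichment_set(0, 0, 0, 0), 2, 2), "singular")
})

test_that("implausible (negative) matrix solutions are flagged, not hidden", {
  # enrichments inconsistent with non-negative fluxes
  e <- enrichment_set(A = 0.02, B = 0.3, C = 0.01, D = 0.4)
  expect_warning(sol <- solve_two_pool(e, 2, 2), "implausible")
  expect_true(sol$implausible)
})

test_that("single-tracer dilution follows the steady-state formulas", {
  st <- single_tracer_turnover(rinf = 1, enrichment = 0.5)
  expect_equal(st[["ra"]], 1)
  expect_equal(st[["rd"]], 2)
  st2 <- single_tracer_turnover(rinf = 2, enrichment = 1)
  expect_equal(st2[["ra"]], 0)
  expect_equal(st2[["rd"]], 2)
  expect_equal(single_tracer_turnover(2, 1, include_tracer_in_rd = FALSE)[["rd"]], 0)
  expect_error(single_tracer_turnover(1, 0), "undefined")
})

test_that("single-tracer estimates are biased upward on interconverting systems", {
  set.seed(23)
  for (i in 1:10) {
    fl <- random_flux_state()
    cm <- simulate_combined_mid(fl, default_protocol)
    cmp <- compare_single_vs_double(decode_combined_mid(cm), default_protocol)
    two <- cmp[cmp$method == "two_pool", ]
    one_b <- cmp[cmp$method == "single_bhb", ]
    one_a <- cmp[cmp$method == "single_acac", ]
    # single BHB tracer overestimates Ra BHB; single AcAc overestimates Rd AcAc
    expect_gte(one_b$ra_bhb, two$ra_bhb - 1e-9)
    expect_gte(one_a$rd_acac, two$rd_acac - 1e-9)
    # the two-pool totals reproduce the generating truth
    expect_equal(two$ra_total, fl$ra_acac + fl$ra_bhb, tolerance = 1e-9)
  }
})

test_that("all estimators coincide in the no-interconversion limit", {
  fl <- flux_state(ra_acac = 10, ra_bhb = 8, ri_acac = 0, ri_bhb = 0,
                   rinf_acac = 1.91, rinf_bhb = 2.08, pool_ratio_acac = 0.3)
  cm <- simulate_combined_mid(fl, default_protocol)
  cmp <- compare_single_vs_double(decode_combined_mid(cm), default_protocol)
  two <- cmp[cmp$method == "two_pool", ]
  expect_equal(cmp[cmp$method == "single_bhb", "ra_bhb"], two$ra_bhb,
               tolerance = 1e-9)
  expect_equal(cmp[cmp$method == "single_bhb", "rd_bhb"], two$rd_bhb,
               tolerance = 1e-9)
  expect_equal(cmp[cmp$method == "single_acac", "ra_acac"], two$ra_acac,
               tolerance = 1e-9)
  expect_equal(cmp[cmp$method == "single_acac", "rd_acac"], two$rd_acac,
               tolerance = 1e-9)
})

test_that("infusion-rate concentration correction and unit conversion behave", {
  expect_equal(adjust_infusion_rate(2, 30, 30), 2)
  expect_equal(adjust_infusion_rate(2, 18, 30), 1.2)  # 40% loss -> rate x 0.6
  expect_error(adjust_infusion_rate(2, 10, 0), "positive")
  expect_error(adjust_infusion_rate(2, -1, 30), "positive")
  expect_equal(per_kg_min(12, 30), 12 / 0.03 / 60)
})
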