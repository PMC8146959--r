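#' Flux state of the two-pool ketone model
#'
#' Holds the six model fluxes (rates of appearance `ra_*`, interconversion
#' `ri_*` and disposal `rd_*` for acetoacetate and beta-hydroxybutyrate), the
#' two tracer infusion fluxes, and the AcAc fraction of the total blood
#' ketone signal. All flows are in µmol/h per animal. At steady state each
#' pool's inflow equals its outflow:
#'
#' * AcAc node: `rinf_acac + ra_acac + ri_bhb = rd_acac + ri_acac`
#' * BHB node:  `rinf_bhb + ra_bhb + ri_acac = rd_bhb + ri_bhb`
#'
#' If `rd_acac`/`rd_bhb` are omitted they are filled in from the balances.
#' Negative components are accepted (the exact matrix method can produce
#' them from inconsistent data) but mark the state `implausible`.
#'
#' @param ra_acac,ra_bhb endogenous rates of appearance (µmol/h).
#' @param ri_acac,ri_bhb interconversion rates: `ri_acac` converts AcAc to
#'   BHB, `ri_bhb` converts BHB to AcAc (µmol/h).
#' @param rd_acac,rd_bhb rates of disposal (µmol/h); `NULL` to derive from
#'   the node balances.
#' @param rinf_acac,rinf_bhb tracer infusion rates (µmol/h).
#' @param pool_ratio_acac AcAc fraction of the total blood ketone signal,
#'   in `[0, 1]`; independent of the steady-state fluxes.
#' @param check_balance error if the stated rd values violate the node
#'   balances beyond `1e-6` relative (default `TRUE`).
#' @return object of class `flux_state` (named list; `implausible` flags any
#'   negative flux).
#' @examples
#' flux_state(ra_acac = 12, ra_bhb = 6, ri_acac = 8, ri_bhb = 4,
#'            rinf_acac = 1.91, rinf_bhb = 2.08, pool_ratio_acac = 0.3)
#' @export
flux_state <- function(ra_acac, ra_bhb, ri_acac, ri_bhb,
                       rd_acac = NULL, rd_bhb = NULL,
                       rinf_acac = 0, rinf_bhb = 0,
                       pool_ratio_acac = 0.5,
                       check_balance = TRUE) {
  bal_rd_acac <- rinf_acac + ra_acac + ri_bhb - ri_acac
  bal_rd_bhb <- rinf_bhb + ra_bhb + ri_acac - ri_bhb
  if (is.null(rd_acac)) rd_acac <- bal_rd_acac
  if (is.null(rd_bhb)) rd_bhb <- bal_rd_bhb
  fl <- list(ra_acac = ra_acac, ra_bhb = ra_bhb,
             ri_acac = ri_acac, ri_bhb = ri_bhb,
             rd_acac = rd_acac, rd_bhb = rd_bhb,
             rinf_acac = rinf_acac, rinf_bhb = rinf_bhb,
             pool_ratio_acac = pool_ratio_acac)
  if (anyNA(unlist(fl))) stop("flux state contains NA", call. = FALSE)
  if (pool_ratio_acac < 0 || pool_ratio_acac > 1) {
    stop("pool_ratio_acac must lie in [0, 1]", call. = FALSE)
  }
  if (check_balance) {
    scale <- max(abs(unlist(fl[1:8])), 1e-12)
    if (abs(rd_acac - bal_rd_acac) > 1e-6 * scale ||
        abs(rd_bhb - bal_rd_bhb) > 1e-6 * scale) {
      stop("flux state violates the steady-state node balances", call. = FALSE)
    }
  }
  v <- unlist(fl[1:8])
  fl$implausible <- any(v < -1e-9 * max(abs(v), 1e-12))
  structure(fl, class = "flux_state")
}

#' @rdname flux_state
#' @param x object to test.
#' @export
is_flux_state <- function(x) inherits(x, "flux_state")

#' @export
print.flux_state <- function(x, ...) {
  v <- unlist(x[c("ra_acac", "ra_bhb", "ri_acac", "ri_bhb", "rd_acac", "rd_bhb")])
  cat("<flux state> (umol/h)\n")
  print(round(v, 4))
  cat(sprintf("  rinf_acac=%.4g rinf_bhb=%.4g  pool_ratio_acac=%.3f%s\n",
              x$rinf_acac, x$rinf_bhb, x$pool_ratio_acac,
              if (isTRUE(x$implausible)) "  [implausible: negative flux]" else ""))
  invisible(x)
}

#' Residuals of the six steady-state mass balances
#'
#' Evaluates the total and tracer-species balances of the two-pool model for
#' a flux state and enrichment set; all six residuals are zero (to numerical
#' precision) for an exact solution.
#'
#' @param fl a [flux_state()].
#' @param e an [enrichment_set()].
#' @return numeric vector of six balance residuals (inflow minus outflow).
#' @export
balance_residuals <- function(fl, e) {
  stopifnot(is_flux_state(fl), inherits(e, "enrichment_set"))
  A <- e[["A"]]; B <- e[["B"]]; C <- e[["C"]]; D <- e[["D"]]
  with(fl, c(
    total_acac = rinf_acac + ra_acac + ri_bhb - rd_acac - ri_acac,
    total_bhb = rinf_bhb + ra_bhb + ri_acac - rd_bhb - ri_bhb,
    c13_2_acac = rinf_acac + B * ri_bhb - A * rd_acac - A * ri_acac,
    c13_4_bhb = rinf_bhb + C * ri_acac - D * rd_bhb - D * ri_bhb,
    c13_2_bhb = A * ri_acac - B * ri_bhb - B * rd_bhb,
    c13_4_acac = D * ri_bhb - C * ri_acac - C * rd_acac
  ))
}

#' Dual-tracer infusion protocol
#'
#' Records the continuous infusion rates of the two tracers and the labeling
#' of each infusate as a carbon-shift MID over M+0/M+2/M+4 (position M+2 is
#' the 13C2 species, M+4 the 13C4 species). Defaults correspond to the
#' standard mouse protocol: 1.91 µmol/h of 13C2-AcAc and 2.08 µmol/h of
#' 13C4-BHB, each isotopically pure. Prime-infusion rate and duration are
#' carried as metadata only; the steady-state model does not use them.
#'
#' @param rinf_acac,rinf_bhb continuous infusion rates (µmol/h), `> 0`.
#' @param infusate_acac_mid,infusate_bhb_mid 3-element MIDs over carbon
#'   shifts (M+0, M+2, M+4) describing infusate labeling including impurity.
#' @param prime_rate_acac,prime_rate_bhb,prime_duration_min optional prime
#'   metadata (µmol/h, min).
#' @return object of class `tracer_protocol`.
#' @export
tracer_protocol <- function(rinf_acac = 1.91, rinf_bhb = 2.08,
                            infusate_acac_mid = c(0, 1, 0),
                            infusate_bhb_mid = c(0, 0, 1),
                            prime_rate_acac = 4.77, prime_rate_bhb = 5.21,
                            prime_duration_min = 10) {
  if (rinf_acac <= 0 || rinf_bhb <= 0) {
    stop("infusion rates must be positive", call. = FALSE)
  }
  norm3 <- function(v) {
    v <- as.numeric(v)
    if (length(v) != 3L || any(v < 0) || sum(v) <= 0) {
      stop("infusate MIDs must be 3 non-negative fractions over M+0/M+2/M+4",
           call. = FALSE)
    }
    v / sum(v)
  }
  structure(list(
    rinf_acac = rinf_acac, rinf_bhb = rinf_bhb,
    infusate_acac_mid = norm3(infusate_acac_mid),
    infusate_bhb_mid = norm3(infusate_bhb_mid),
    prime_rate_acac = prime_rate_acac, prime_rate_bhb = prime_rate_bhb,
    prime_duration_min = prime_duration_min
  ), class = "tracer_protocol")
}

#' Correct a nominal infusion rate for measured infusate concentration
#'
#' Tracer can be lost during infusate preparation (notably AcAc during pH
#' neutralization), so the concentration actually present in the infusate
#' should be measured and the nominal pump rate rescaled.
#'
#' @param nominal nominal infusion rate (µmol/h).
#' @param measured_conc measured infusate concentration (mM), `> 0`.
#' @param theoretical_conc theoretical concentration from weighed-in
#'   material (mM), `> 0`.
#' @return corrected rate: `nominal * measured_conc / theoretical_conc`.
#' @examples
#' adjust_infusion_rate(1.91, measured_conc = 18, theoretical_conc = 30)
#' @export
adjust_infusion_rate <- function(nominal, measured_conc, theoretical_conc) {
  if (!is.finite(theoretical_conc) || theoretical_conc <= 0) {
    stop("theoretical infusate concentration must be positive", call. = FALSE)
  }
  if (!is.finite(measured_conc) || measured_conc <= 0) {
    stop("measured infusate concentration must be positive", call. = FALSE)
  }
  nominal * measured_conc / theoretical_conc
}

#' Convert fluxes from per-animal to body-weight-normalized units
#'
#' @param flow flux in µmol/h per animal.
#' @param body_weight_g body weight in grams.
#' @return flux in µmol/kg/min.
#' @export
per_kg_min <- function(flow, body_weight_g) {
  if (body_weight_g <= 0) stop("body weight must be positive", call. = FALSE)
  flow / (body_weight_g / 1000) / 60
}
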