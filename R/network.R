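#' Isotopomer network of the two-pool ketone model
#'
#' Builds the 11-reaction atom-transition network used by the regression
#' model: tracer infusions, endogenous appearance, interconversion and
#' disposal for both blood pools, plus zero-stoichiometry sampling reactions
#' that expose blood labeling (with the borodeuteride deuterium tag on the
#' AcAc-derived molecules) without entering the mass balances, and a sink.
#' Capital letters in atom maps are carbons, lower-case are hydrogens.
#'
#' Because no reaction cleaves or condenses the tracked carbon skeletons,
#' isotopologue balances close at the level of whole-molecule MIDs; the
#' simulator therefore solves one 2x2 linear system per carbon mass instead
#' of a generic elementary-unit decomposition. The atom maps are still
#' validated for carbon conservation, and the hydrogen bookkeeping is checked
#' to reduce to "all in vivo hydrogen sources unlabeled, derivatization
#' deuterium a deterministic +1 on AcAc-derived molecules".
#'
#' @return object of class `keto_network`: a data frame of reactions with
#'   columns `flux`, `stoichiometry`, `lhs`, `rhs` (atom-map strings) and
#'   `in_balance`.
#' @examples
#' net <- build_network()
#' nrow(net)
#' @export
build_network <- function() {
  rx <- data.frame(
    flux = c("rinf_bhb", "rinf_acac", "ra_bhb", "ra_acac",
             "ri_bhb", "ri_acac", "rd_bhb", "rd_acac",
             "rs_bhb", "rs_acac", "sink"),
    stoichiometry = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 1),
    lhs = c("BHB.inf (AaBCD)",
            "AcAc.inf (ABCD)",
            "BHB.source (AaBCD)",
            "AcAc.source (ABCD)",
            "BHB.blood (AaBCD)",
            "AcAc.blood (ABCD) + H.h2o (a)",
            "BHB.blood (AaBCD)",
            "AcAc.blood (ABCD)",
            "0*BHB.blood (AaBCD)",
            "0*AcAc.blood (ABCD) + D.h2o (a)",
            "BHB.s (AaBCD)"),
    rhs = c("BHB.blood (AaBCD)",
            "AcAc.blood (ABCD)",
            "BHB.blood (AaBCD)",
            "AcAc.blood (ABCD)",
            "AcAc.blood (ABCD) + H.bhb (a)",
            "BHB.blood (AaBCD)",
            "BHB.tissue (AaBCD)",
            "AcAc.tissue (ABCD)",
            "BHB.s (AaBCD)",
            "BHB.s (AaBCD)",
            "SINK"),
    stringsAsFactors = FALSE
  )
  rx$in_balance <- rx$stoichiometry > 0
  class(rx) <- c("keto_network", "data.frame")
  validate_network(rx)
  rx
}

# parse "A.b (XyZ) + C.d (w)" into a list of species with atom vectors
.parse_side <- function(s) {
  if (s == "SINK") return(list())
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  out <- list()
  for (t in terms) {
    t <- trimws(t)
    zero <- startsWith(t, "0*")
    if (zero) t <- sub("^0\\*", "", t)
    m <- regmatches(t, regexec("^([A-Za-z0-9._]+) \\(([A-Za-z]*)\\)$", t))[[1]]
    if (length(m) != 3L) stop("unparseable atom-map term: ", t, call. = FALSE)
    atoms <- strsplit(m[3], "")[[1]]
    out[[length(out) + 1L]] <- list(
      species = m[2], zero = zero,
      carbons = atoms[grepl("[A-Z]", atoms)],
      hydrogens = atoms[grepl("[a-z]", atoms)]
    )
  }
  out
}

#' Validate atom-map conservation of the ketone network
#'
#' Checks, for every reaction, that the multiset of carbon labels on the
#' left equals that on the right (carbon conservation) and that hydrogen
#' labels are likewise conserved, and that both sampling reactions carry
#' stoichiometric coefficient zero.
#'
#' @param net a `keto_network` from [build_network()].
#' @return invisibly `TRUE`; errors on violation.
#' @export
validate_network <- function(net) {
  for (i in seq_len(nrow(net))) {
    l <- .parse_side(net$lhs[i])
    r <- .parse_side(net$rhs[i])
    lc <- sort(unlist(lapply(l, `[[`, "carbons")))
    rc <- sort(unlist(lapply(r, `[[`, "carbons")))
    if (net$rhs[i] != "SINK" && !identical(lc, rc)) {
      stop("carbon atoms not conserved in reaction ", net$flux[i], call. = FALSE)
    }
    lh <- sort(unlist(lapply(l, `[[`, "hydrogens")))
    rh <- sort(unlist(lapply(r, `[[`, "hydrogens")))
    if (net$rhs[i] != "SINK" && !identical(lh, rh)) {
      stop("tracked hydrogen atoms not conserved in reaction ", net$flux[i],
           call. = FALSE)
    }
  }
  if (any(net$stoichiometry[net$flux %in% c("rs_bhb", "rs_acac")] != 0)) {
    stop("sampling reactions must have stoichiometric coefficient 0", call. = FALSE)
  }
  # hydrogen sources feeding blood pools in vivo must be unlabeled water or
  # source hydrogens; only the sampling reaction may introduce deuterium
  lhs_balance <- net$lhs[net$in_balance]
  if (any(grepl("D\\.", lhs_balance))) {
    stop("deuterium may only enter through the zero-stoichiometry sampling reaction",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Degrees of freedom of the network after node balances
#'
#' Number of independently adjustable rate parameters: the six net fluxes
#' less the two blood-node balances, plus the sampled pool-ratio parameter.
#'
#' @param net a `keto_network`.
#' @return integer (7 for the standard network: 6 free net fluxes and the
#'   pool ratio... see Details).
#' @details The balance-carrying reactions (stoichiometry > 0, excluding the
#'   pure sink) number eight; two node balances leave six free net fluxes;
#'   the AcAc:BHB sampling ratio adds one adjustable parameter.
#' @export
network_free_parameters <- function(net) {
  n_rates <- sum(net$in_balance & net$rhs != "SINK" & net$lhs != "BHB.s (AaBCD)")
  n_rates - 2L + 1L
}

#' Steady-state blood MIDs under the two-pool network
#'
#' Solves the per-mass steady-state label balances of the two blood pools.
#' For each carbon mass shift `m` in {0, 2, 4}:
#'
#' ```
#' (rd_acac + ri_acac) * xA[m] - ri_bhb  * xB[m] = rinf_acac * infA[m] + ra_acac * (m == 0)
#' (rd_bhb  + ri_bhb)  * xB[m] - ri_acac * xA[m] = rinf_bhb  * infB[m] + ra_bhb  * (m == 0)
#' ```
#'
#' Endogenous appearance is unlabeled; all in vivo hydrogen sources are
#' unlabeled, so in vivo mass shifts are carbon-only and only even shifts are
#' populated under these tracers.
#'
#' @param flux a balanced, non-negative [flux_state()].
#' @param protocol a [tracer_protocol()].
#' @return list with `acac_blood_mid` and `bhb_blood_mid`, each a 5-channel
#'   [mid()] populated at M+0/M+2/M+4.
#' @export
simulate_steady_state <- function(flux, protocol) {
  stopifnot(is_flux_state(flux), inherits(protocol, "tracer_protocol"))
  fl <- unlist(flux[c("ra_acac", "ra_bhb", "ri_acac", "ri_bhb",
                      "rd_acac", "rd_bhb", "rinf_acac", "rinf_bhb")])
  if (any(fl < 0)) stop("forward simulation requires non-negative fluxes", call. = FALSE)
  scale <- max(fl, 1e-12)
  bal_a <- flux$rinf_acac + flux$ra_acac + flux$ri_bhb - flux$rd_acac - flux$ri_acac
  bal_b <- flux$rinf_bhb + flux$ra_bhb + flux$ri_acac - flux$rd_bhb - flux$ri_bhb
  if (abs(bal_a) > 1e-6 * scale || abs(bal_b) > 1e-6 * scale) {
    stop("flux state violates node balances; cannot simulate steady state", call. = FALSE)
  }
  out_a <- flux$rd_acac + flux$ri_acac
  out_b <- flux$rd_bhb + flux$ri_bhb
  if (out_a <= 0 || out_b <= 0) {
    stop("each pool needs positive total outflow (rd + ri) for a steady state",
         call. = FALSE)
  }
  xa <- xb <- numeric(3)
  for (j in 1:3) {               # carbon masses 0, 2, 4
    m <- rbind(c(out_a, -flux$ri_bhb),
               c(-flux$ri_acac, out_b))
    rhs <- c(flux$rinf_acac * protocol$infusate_acac_mid[j] +
               flux$ra_acac * (j == 1L),
             flux$rinf_bhb * protocol$infusate_bhb_mid[j] +
               flux$ra_bhb * (j == 1L))
    sol <- solve(m, rhs)
    xa[j] <- sol[1]; xb[j] <- sol[2]
  }
  expand <- function(v3) {
    out <- numeric(5)
    out[c(1, 3, 5)] <- v3
    mid(out)
  }
  list(acac_blood_mid = expand(xa / sum(xa)),
       bhb_blood_mid = expand(xb / sum(xb)))
}

#' Simulate the combined derivatized BHB MID
#'
#' Applies the sample-preparation step to the steady-state blood MIDs: every
#' AcAc-derived molecule gains one deuterium (+1 mass) during borodeuteride
#' reduction, so with AcAc signal fraction `p` the combined six-channel MID is
#' `combined[2j] = (1 - p) * bhb[2j]` and `combined[2j + 1] = p * acac[2j]`.
#'
#' @param flux a [flux_state()] whose `pool_ratio_acac` lies in `(0, 1)`.
#' @param protocol a [tracer_protocol()].
#' @return a 6-channel [mid()] (M+0...M+5).
#' @export
simulate_combined_mid <- function(flux, protocol) {
  p <- flux$pool_ratio_acac
  if (p <= 0 || p >= 1) {
    stop("pool_ratio_acac must lie strictly in (0, 1) for both signals to exist",
         call. = FALSE)
  }
  ss <- simulate_steady_state(flux, protocol)
  xb <- as.numeric(ss$bhb_blood_mid)[c(1, 3, 5)]
  xa <- as.numeric(ss$acac_blood_mid)[c(1, 3, 5)]
  combined <- numeric(6)
  combined[c(1, 3, 5)] <- (1 - p) * xb
  combined[c(2, 4, 6)] <- p * xa
  mid(combined)
}
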