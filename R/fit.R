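#' Configuration of the flux regression
#'
#' @param mid_sigma assumed standard deviation of each isotopologue fraction
#'   measurement (mol fraction; default 0.003, typical LC-MS/MS MID
#'   precision).
#' @param rinf_sigma_rel assumed relative standard deviation of the infusion
#'   rate measurements (default 0.02).
#' @param level confidence level for profile-likelihood intervals
#'   (default 0.95).
#' @param multistart number of random starting points tried in addition to
#'   the matrix-method warm start (default 20).
#' @param seed integer seed controlling the random starts; identical seed,
#'   configuration and data give identical results.
#' @param lower lower bound applied to every flux during regression
#'   (default 0: non-negative fluxes).
#' @param ssr_floor with zero degrees of freedom an exact fit is expected
#'   whenever the data are consistent; a best SSR above this floor flags
#'   inconsistency (default 1e-3).
#' @param ftol,ptol optimizer tolerances passed to [minpack.lm::nls.lm()].
#' @param max_profile_steps outward steps allowed when bracketing a profile
#'   confidence bound before the interval is reported open.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(mid_sigma = 0.003, rinf_sigma_rel = 0.02,
                       level = 0.95, multistart = 20, seed = 1L,
                       lower = 0, ssr_floor = 1e-3,
                       ftol = 1e-12, ptol = 1e-12,
                       max_profile_steps = 40L) {
  if (mid_sigma <= 0 || rinf_sigma_rel <= 0) {
    stop("measurement sigmas must be positive", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  structure(list(mid_sigma = mid_sigma, rinf_sigma_rel = rinf_sigma_rel,
                 level = level, multistart = as.integer(multistart),
                 seed = as.integer(seed), lower = lower,
                 ssr_floor = ssr_floor, ftol = ftol, ptol = ptol,
                 max_profile_steps = as.integer(max_profile_steps)),
            class = "fit_config")
}

#' Degrees of freedom of the regression design
#'
#' Independent measurements minus adjustable parameters. A combined
#' six-channel MID contributes five independent fractions (one is lost to
#' normalization); each measured infusion rate contributes one. The model has
#' seven structural parameters: six net fluxes less two node balances, two
#' infusion fluxes, and the pool-ratio parameter.
#'
#' @param net a `keto_network` from [build_network()] (used for the parameter
#'   count).
#' @param n_mids number of independent combined-MID measurements regressed
#'   jointly against one flux set (default 1).
#' @param n_rate_measurements number of measured infusion rates (default 2).
#' @return integer degrees of freedom; 0 for the standard dual-tracer design
#'   (a uniquely determined system), negative values indicate an
#'   underdetermined design.
#' @examples
#' count_degrees_of_freedom()                          # standard design: 0
#' count_degrees_of_freedom(n_rate_measurements = 1)   # AcAc tracer omitted: -1
#' @export
count_degrees_of_freedom <- function(net = build_network(), n_mids = 1L,
                                     n_rate_measurements = 2L) {
  n_channels <- 6L
  measurements <- (n_channels - 1L) * n_mids + n_rate_measurements
  parameters <- network_free_parameters(net)
  dof <- as.integer(measurements - parameters)
  if (dof < 0L) {
    attr(dof, "underdetermined") <- TRUE
  }
  dof
}

# fast forward model used inside the optimizer: theta =
# (ra_acac, ra_bhb, ri_acac, ri_bhb, rinf_acac, rinf_bhb, pool_ratio_acac);
# returns the 6-channel combined MID or NULL when the implied disposal
# fluxes are negative (infeasible point)
.sim_combined_fast <- function(theta, inf_a, inf_b) {
  ra_a <- theta[1]; ra_b <- theta[2]
  ri_a <- theta[3]; ri_b <- theta[4]
  rf_a <- theta[5]; rf_b <- theta[6]
  p <- theta[7]
  rd_a <- rf_a + ra_a + ri_b - ri_a
  rd_b <- rf_b + ra_b + ri_a - ri_b
  if (rd_a < 0 || rd_b < 0) return(NULL)
  out_a <- rd_a + ri_a
  out_b <- rd_b + ri_b
  det <- out_a * out_b - ri_a * ri_b
  if (out_a <= 0 || out_b <= 0 || det <= 0) return(NULL)
  xa <- xb <- numeric(3)
  for (j in 1:3) {
    rhs_a <- rf_a * inf_a[j] + ra_a * (j == 1L)
    rhs_b <- rf_b * inf_b[j] + ra_b * (j == 1L)
    xa[j] <- (out_b * rhs_a + ri_b * rhs_b) / det
    xb[j] <- (ri_a * rhs_a + out_a * rhs_b) / det
  }
  xa <- xa / sum(xa); xb <- xb / sum(xb)
  c((1 - p) * xb[1], p * xa[1],
    (1 - p) * xb[2], p * xa[2],
    (1 - p) * xb[3], p * xa[3])
}

.theta_names <- c("ra_acac", "ra_bhb", "ri_acac", "ri_bhb",
                  "rinf_acac", "rinf_bhb", "pool_ratio_acac")

# weighted residual vector: 6 MID channels + 2 infusion rates; infeasible
# points are mapped to a large finite plateau so the optimizer retreats
.keto_residuals <- function(theta, measured, protocol, cfg) {
  sim <- .sim_combined_fast(theta, protocol$infusate_acac_mid,
                            protocol$infusate_bhb_mid)
  if (is.null(sim)) return(rep(1e4, 8L))
  c((measured - sim) / cfg$mid_sigma,
    (theta[5] - protocol$rinf_acac) / (cfg$rinf_sigma_rel * protocol$rinf_acac),
    (theta[6] - protocol$rinf_bhb) / (cfg$rinf_sigma_rel * protocol$rinf_bhb))
}

.run_lm <- function(start, lower, upper, fn, cfg) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = cfg$ftol, ptol = cfg$ptol, maxiter = 400)),
    error = function(err) NULL)
  if (is.null(fit)) return(NULL)
  list(par = fit$par, ssr = fit$deviance, info = fit$info,
       message = fit$message)
}

# bounds of the full 7-parameter vector
.theta_bounds <- function(cfg) {
  list(lower = c(rep(cfg$lower, 4), 1e-9, 1e-9, 1e-6),
       upper = c(rep(Inf, 6), 1 - 1e-6))
}

#' Regress the combined MID and infusion rates against the two-pool model
#'
#' Weighted bounded least squares over the free parameters of the isotopomer
#' network: the four endogenous fluxes, the two infusion fluxes (weighted
#' toward the measured rates) and the AcAc pool-ratio parameter; disposal
#' fluxes are reconstructed from the node balances so mass balance holds
#' exactly at every iterate. The objective is
#' `sum(((measured - simulated) / sigma)^2)` over the six isotopologue
#' fractions and the two infusion rates. Optimization uses
#' Levenberg-Marquardt with a warm start from the exact matrix solution
#' (clipped into bounds) plus `cfg$multistart` random log-uniform starts.
#'
#' @param measured a corrected, normalized six-channel [mid()].
#' @param protocol a [tracer_protocol()] carrying the nominal rates and
#'   infusate labeling.
#' @param cfg a [fit_config()].
#' @return object of class `fit_result`: list with elements `flux`
#'   (a [flux_state()]), `ssr`, `dof`, `residuals` (weighted, named),
#'   `converged`, `n_starts_converged`, `start_log`, and the inputs
#'   (`measured`, `protocol`, `cfg`) needed for profiling.
#' @export
fit_fluxes <- function(measured, protocol, cfg = fit_config()) {
  stopifnot(is_mid(measured), inherits(protocol, "tracer_protocol"),
            inherits(cfg, "fit_config"))
  if (length(measured) != 6L) {
    stop("measured MID must have six channels", call. = FALSE)
  }
  y <- as.numeric(measured)
  fn <- function(th) .keto_residuals(th, y, protocol, cfg)
  b <- .theta_bounds(cfg)

  starts <- list()
  # warm start from the exact matrix method
  warm <- tryCatch({
    d <- decode_combined_mid(measured)
    sol <- suppressWarnings(solve_two_pool(enrichments_from_decoded(d),
                                           protocol$rinf_acac, protocol$rinf_bhb))
    th <- c(sol$ra_acac, sol$ra_bhb, sol$ri_acac, sol$ri_bhb,
            protocol$rinf_acac, protocol$rinf_bhb, d$acac_fraction)
    scale <- max(protocol$rinf_acac, protocol$rinf_bhb)
    th[1:4] <- pmax(th[1:4], cfg$lower + 0.01 * scale)
    th[7] <- min(max(th[7], 0.01), 0.99)
    th
  }, error = function(err) NULL)
  if (!is.null(warm)) starts[[1]] <- warm

  # seeded random multistart (log-uniform flux draws)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(cfg$seed)
  scale <- max(protocol$rinf_acac, protocol$rinf_bhb)
  for (i in seq_len(cfg$multistart)) {
    starts[[length(starts) + 1L]] <- c(
      exp(stats::runif(4, log(0.1 * scale), log(50 * scale))),
      protocol$rinf_acac, protocol$rinf_bhb,
      stats::runif(1, 0.05, 0.95))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  best <- NULL
  log_rows <- list()
  n_conv <- 0L
  for (i in seq_along(starts)) {
    res <- .run_lm(starts[[i]], b$lower, b$upper, fn, cfg)
    ok <- !is.null(res) && res$info %in% 1:4
    if (ok) n_conv <- n_conv + 1L
    log_rows[[i]] <- data.frame(
      start = i, warm = (i == 1L && !is.null(warm)),
      ssr = if (is.null(res)) NA_real_ else res$ssr,
      converged = ok,
      message = if (is.null(res)) "nls.lm error" else res$message,
      stringsAsFactors = FALSE)
    if (!is.null(res) && (is.null(best) || res$ssr < best$ssr)) best <- res
  }
  if (is.null(best)) {
    stop("flux regression failed to converge from any starting point; ",
         "per-start log:\n",
         paste(utils::capture.output(print(do.call(rbind, log_rows))),
               collapse = "\n"), call. = FALSE)
  }

  th <- best$par
  names(th) <- .theta_names
  fl <- flux_state(ra_acac = th[[1]], ra_bhb = th[[2]],
                   ri_acac = th[[3]], ri_bhb = th[[4]],
                   rinf_acac = th[[5]], rinf_bhb = th[[6]],
                   pool_ratio_acac = th[[7]])
  r <- fn(best$par)
  names(r) <- c(paste0("m", 0:5), "rinf_acac", "rinf_bhb")
  structure(list(
    flux = fl, theta = th, ssr = best$ssr,
    dof = count_degrees_of_freedom(),
    residuals = r,
    converged = n_conv > 0L, n_starts_converged = n_conv,
    start_log = do.call(rbind, log_rows),
    measured = measured, protocol = protocol, cfg = cfg
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit result>  SSR = %.4g  (dof = %d, %d/%d starts converged)\n",
              x$ssr, x$dof, x$n_starts_converged, nrow(x$start_log)))
  print(x$flux)
  invisible(x)
}

# SSR of the fit with one quantity constrained to `value`, re-optimizing all
# remaining parameters. `flux_name` may be a free parameter or a derived
# disposal flux (in which case the paired appearance flux is eliminated via
# the node balance). Returns list(ssr, theta_start for continuation).
.profile_ssr <- function(fit, flux_name, value, start_theta = NULL) {
  cfg <- fit$cfg
  protocol <- fit$protocol
  y <- as.numeric(fit$measured)
  b <- .theta_bounds(cfg)
  th0 <- if (is.null(start_theta)) unname(fit$theta) else unname(start_theta)

  if (flux_name %in% .theta_names) {
    idx <- match(flux_name, .theta_names)
    free <- setdiff(seq_len(7L), idx)
    expand <- function(par) {
      th <- numeric(7L); th[free] <- par; th[idx] <- value; th
    }
  } else if (flux_name %in% c("rd_acac", "rd_bhb")) {
    # rd_acac = rinf_acac + ra_acac + ri_bhb - ri_acac  (eliminate ra_acac)
    # rd_bhb  = rinf_bhb  + ra_bhb  + ri_acac - ri_bhb  (eliminate ra_bhb)
    idx <- if (flux_name == "rd_acac") 1L else 2L
    free <- setdiff(seq_len(7L), idx)
    expand <- function(par) {
      th <- numeric(7L); th[free] <- par
      th[idx] <- if (flux_name == "rd_acac") {
        value - th[5] - th[4] + th[3]
      } else {
        value - th[6] - th[3] + th[4]
      }
      th
    }
  } else {
    stop("unknown flux name: ", flux_name, call. = FALSE)
  }
  fn <- function(par) {
    th <- expand(par)
    if (th[idx] < b$lower[idx] - 1e-12) return(rep(1e4, 8L))
    .keto_residuals(th, y, protocol, cfg)
  }
  start <- pmin(pmax(th0[free], b$lower[free]), pmin(b$upper[free], 1e6))
  res <- .run_lm(start, b$lower[free], b$upper[free], fn, cfg)
  if (is.null(res)) return(list(ssr = Inf, theta = NULL))
  th <- expand(res$par)
  names(th) <- .theta_names
  list(ssr = res$ssr, theta = th)
}

#' Profile-likelihood confidence interval for one flux
#'
#' Walks the named flux away from its best-fit value, re-optimizing all other
#' parameters at each step, until the weighted SSR exceeds
#' `best SSR + qchisq(level, 1)`; the crossing points are refined by
#' bisection. The lower bound is truncated at the flux lower bound. If a
#' bound cannot be bracketed within the step budget the interval is flagged
#' open on that side and the search limit is reported.
#'
#' @param fit a `fit_result` from [fit_fluxes()].
#' @param flux_name one of `ra_acac`, `ra_bhb`, `ri_acac`, `ri_bhb`,
#'   `rd_acac`, `rd_bhb`, `rinf_acac`, `rinf_bhb`, `pool_ratio_acac`.
#' @param cfg a [fit_config()]; defaults to the one stored in `fit`.
#' @return named numeric vector `c(lb, ub)` with attributes `open_lower` /
#'   `open_upper` set when the profile failed to bracket.
#' @export
profile_confidence_interval <- function(fit, flux_name, cfg = fit$cfg) {
  stopifnot(inherits(fit, "fit_result"))
  fit$cfg <- cfg
  est <- if (flux_name %in% .theta_names) {
    fit$theta[[flux_name]]
  } else if (flux_name %in% c("rd_acac", "rd_bhb")) {
    fit$flux[[flux_name]]
  } else {
    stop("unknown flux name: ", flux_name, call. = FALSE)
  }
  threshold <- fit$ssr + stats::qchisq(cfg$level, df = 1)
  hard_lower <- if (flux_name == "pool_ratio_acac") 1e-6 else cfg$lower
  hard_upper <- if (flux_name == "pool_ratio_acac") 1 - 1e-6 else Inf
  scale <- max(abs(est), fit$protocol$rinf_acac + fit$protocol$rinf_bhb)
  step0 <- if (flux_name == "pool_ratio_acac") 0.02 else 0.05 * scale

  search_bound <- function(direction) {
    open <- FALSE
    inner <- est
    inner_theta <- fit$theta
    step <- step0
    outer <- NA_real_
    for (k in seq_len(cfg$max_profile_steps)) {
      cand <- inner + direction * step
      clipped <- FALSE
      if (cand <= hard_lower) { cand <- hard_lower; clipped <- TRUE }
      if (cand >= hard_upper) { cand <- hard_upper; clipped <- TRUE }
      pr <- .profile_ssr(fit, flux_name, cand, inner_theta)
      if (pr$ssr > threshold) { outer <- cand; break }
      inner <- cand
      if (!is.null(pr$theta)) inner_theta <- pr$theta
      if (clipped) return(list(bound = cand, open = FALSE))  # SSR below threshold at hard bound
      step <- step * 1.6
    }
    if (is.na(outer)) {
      return(list(bound = inner, open = TRUE))
    }
    # bisection refine between inner (below threshold) and outer (above)
    for (k in seq_len(30L)) {
      if (abs(outer - inner) < 1e-5 * max(scale, 1)) break
      midpt <- (inner + outer) / 2
      pr <- .profile_ssr(fit, flux_name, midpt, inner_theta)
      if (pr$ssr > threshold) {
        outer <- midpt
      } else {
        inner <- midpt
        if (!is.null(pr$theta)) inner_theta <- pr$theta
      }
    }
    list(bound = (inner + outer) / 2, open = FALSE)
  }

  up <- search_bound(+1)
  dn <- search_bound(-1)
  out <- c(lb = min(dn$bound, est), ub = max(up$bound, est))
  attr(out, "open_lower") <- dn$open
  attr(out, "open_upper") <- up$open
  out
}

#' Profile confidence intervals and precision scores for a set of fluxes
#'
#' @param fit a `fit_result`.
#' @param fluxes character vector of flux names (default: the six net
#'   fluxes).
#' @param cfg a [fit_config()]; defaults to the one stored in `fit`.
#' @return data frame with columns `flux`, `estimate`, `lb`, `ub`,
#'   `precision`, `open_lower`, `open_upper`.
#' @export
fit_confidence_intervals <- function(fit,
                                     fluxes = c("ra_acac", "ra_bhb",
                                                "ri_acac", "ri_bhb",
                                                "rd_acac", "rd_bhb"),
                                     cfg = fit$cfg) {
  rows <- lapply(fluxes, function(fn) {
    ci <- profile_confidence_interval(fit, fn, cfg)
    est <- if (fn %in% .theta_names) fit$theta[[fn]] else fit$flux[[fn]]
    prec <- if (abs(est) > 0) precision_score(est, ci[["lb"]], ci[["ub"]]) else NA_real_
    data.frame(flux = fn, estimate = est, lb = ci[["lb"]], ub = ci[["ub"]],
               precision = prec,
               open_lower = isTRUE(attr(ci, "open_lower")),
               open_upper = isTRUE(attr(ci, "open_upper")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Precision score of a flux estimate
#'
#' Converts a confidence interval into a score in `(0, 1]`. The normalized
#' range is `r = min(u/|v|, v/|v| + 1) - max(l/|v|, v/|v| - 1)` and the score
#' `S = exp(-r/3)`; a zero-width interval scores exactly 1 and wider
#' intervals score strictly lower. For a non-negative flux with `l = 0` and
#' `u >= 2v` both terms cap and the score floors at `exp(-2/3)`.
#'
#' @param v flux estimate (nonzero).
#' @param l,u confidence bounds, `l <= v <= u`.
#' @return score in `(0, 1]`.
#' @examples
#' precision_score(10, 10, 10)   # 1
#' precision_score(10, 8, 12)    # exp(-0.4/3)
#' @export
precision_score <- function(v, l, u) {
  if (!is.finite(v) || v == 0) {
    stop("precision score is undefined for a zero flux estimate", call. = FALSE)
  }
  if (l > v + 1e-12 || u < v - 1e-12) {
    stop("confidence bounds must satisfy l <= v <= u", call. = FALSE)
  }
  av <- abs(v)
  r <- min(u / av, v / av + 1) - max(l / av, v / av - 1)
  exp(-r / 3)
}

#' Residual diagnostics and data-consistency verdict
#'
#' Reports the weighted residual of every regressed measurement, ranks them
#' by magnitude, and issues a consistency verdict. With zero degrees of
#' freedom a consistent data set admits an exact fit, so any best SSR above
#' a small numerical floor indicates a mismatch between the data and the
#' bounded model (for example an infusion rate that conflicts with the
#' observed dilution); the worst-fitting measurements point to the likely
#' culprit. With positive degrees of freedom the SSR is compared to the
#' upper `level` quantile of its chi-square distribution.
#'
#' @param fit a `fit_result`.
#' @param cfg a [fit_config()]; defaults to the one stored in `fit`.
#' @return object of class `residual_report`: list with `residuals` (named,
#'   weighted), `ranking` (data frame sorted by decreasing magnitude), `ssr`,
#'   `dof`, `threshold`, `verdict` (`"consistent"` or `"inconsistent"`) and
#'   `worst` (measurements whose magnitude is within 50% of the largest,
#'   when inconsistent).
#' @export
residual_report <- function(fit, cfg = fit$cfg) {
  stopifnot(inherits(fit, "fit_result"))
  r <- fit$residuals
  ranking <- data.frame(measurement = names(r), residual = as.numeric(r),
                        abs_residual = abs(as.numeric(r)),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$abs_residual), ]
  rownames(ranking) <- NULL
  if (fit$dof <= 0L) {
    threshold <- cfg$ssr_floor
  } else {
    threshold <- stats::qchisq(cfg$level, df = fit$dof)
  }
  inconsistent <- fit$ssr > threshold
  worst <- if (inconsistent) {
    ranking$measurement[ranking$abs_residual >= 0.5 * ranking$abs_residual[1]]
  } else {
    character(0)
  }
  structure(list(residuals = r, ranking = ranking, ssr = fit$ssr,
                 dof = fit$dof, threshold = threshold,
                 verdict = if (inconsistent) "inconsistent" else "consistent",
                 worst = worst),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual report>  SSR = %.4g (dof = %d, threshold %.4g): %s\n",
              x$ssr, x$dof, x$threshold, x$verdict))
  if (length(x$worst)) {
    cat("  worst-fitting measurements:", paste(x$worst, collapse = ", "), "\n")
  }
  print(utils::head(x$ranking, 4))
  invisible(x)
}
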