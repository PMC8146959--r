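#' Mass isotopomer distributions
#'
#' A `mid` is a numeric vector of isotopologue mol fractions indexed by nominal
#' mass shift M+0, M+1, ..., M+k. Fractions are non-negative and sum to one.
#' The combined ketone measurement of this package is a six-channel `mid`
#' (M+0...M+5) of beta-hydroxybutyrate after in situ reduction of acetoacetate
#' with sodium borodeuteride: even channels carry plasma BHB, odd channels
#' carry plasma AcAc shifted by the derivatization deuterium.
#'
#' @param fractions numeric vector of non-negative isotopologue fractions,
#'   position `i` corresponding to mass shift M+(i-1).
#' @param normalize logical; rescale to unit sum (default `TRUE`).
#' @return an object of class `mid`: a named numeric vector (`m0`, `m1`, ...)
#'   summing to one.
#' @examples
#' mid(c(2, 0, 0, 0, 0, 2))
#' @export
mid <- function(fractions, normalize = TRUE) {
  x <- as.numeric(fractions)
  if (length(x) < 1L || anyNA(x)) {
    stop("MID fractions must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("MID fractions must be non-negative", call. = FALSE)
  }
  s <- sum(x)
  if (s <= 0) {
    stop("degenerate MID: all fractions are zero", call. = FALSE)
  }
  if (normalize) x <- x / s
  names(x) <- paste0("m", seq_along(x) - 1L)
  structure(x, class = "mid")
}

#' @rdname mid
#' @param x object to test or normalize.
#' @export
is_mid <- function(x) inherits(x, "mid")

#' @rdname mid
#' @export
normalize_mid <- function(x) mid(unclass(x), normalize = TRUE)

#' @export
print.mid <- function(x, ...) {
  cat("<mid> ", paste0(names(x), "=", formatC(as.numeric(x), digits = 4, format = "fg"),
                       collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Elemental composition of the measured ion
#'
#' Describes the atoms of the analyte ion that contribute natural heavy-isotope
#' abundance to the measured MID. Each element carries a count, the abundance
#' of its (single dominant) heavy isotope and that isotope's nominal mass
#' shift (+1 for 13C/2H/15N, +2 for 18O). Tracer carbons and the
#' derivatization deuterium are part of the labeled skeleton and must be
#' excluded here.
#'
#' The default is the four-carbon ketone skeleton with the terrestrial 13C
#' abundance; hydrogen and oxygen contributions of the measured fragment can
#' be added via `counts`/`abundances`.
#'
#' @param counts named integer vector of atom counts, e.g. `c(C = 4)`.
#' @param abundances named numeric vector of heavy-isotope abundances per
#'   element (probabilities in `[0, 1)`); defaults are supplied for
#'   C, H, N, O.
#' @param shifts named integer vector of heavy-isotope mass shifts per
#'   element; defaults: C/H/N = 1, O = 2.
#' @return object of class `ion_formula`.
#' @examples
#' ion_formula()                     # C4 skeleton, carbon only
#' ion_formula(c(C = 4, H = 7, O = 3))
#' @export
ion_formula <- function(counts = c(C = 4),
                        abundances = NULL,
                        shifts = NULL) {
  default_ab <- c(C = 0.0107, H = 0.000115, N = 0.00364, O = 0.00205)
  default_sh <- c(C = 1L, H = 1L, N = 1L, O = 2L)
  counts <- round(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("`counts` must be a named vector of element counts", call. = FALSE)
  }
  if (any(counts < 0)) stop("element counts must be >= 0", call. = FALSE)
  els <- names(counts)
  ab <- default_ab[els]
  if (!is.null(abundances)) ab[names(abundances)] <- abundances
  sh <- default_sh[els]
  if (!is.null(shifts)) sh[names(shifts)] <- as.integer(shifts)
  ab[is.na(ab)] <- 0
  sh[is.na(sh)] <- 1L
  if (any(ab < 0 | ab >= 1)) stop("isotope abundances must lie in [0, 1)", call. = FALSE)
  structure(list(counts = counts, abundances = ab, shifts = as.integer(sh)),
            class = "ion_formula")
}

#' Theoretical natural-abundance isotope envelope of an ion formula
#'
#' Probability that the unlabeled ion carries a total natural mass shift of
#' 0, 1, 2, ... Computed by convolving per-element binomial distributions
#' (each heavy isotope contributes its nominal shift).
#'
#' @param formula an [ion_formula()].
#' @param tol envelope truncation: trailing masses with probability below
#'   `tol` are dropped (the vector always keeps mass 0).
#' @return numeric vector `p` with `p[i]` = probability of shift `i - 1`.
#' @export
isotope_envelope <- function(formula, tol = 1e-12) {
  stopifnot(inherits(formula, "ion_formula"))
  env <- 1
  for (i in seq_along(formula$counts)) {
    n <- formula$counts[[i]]
    a <- formula$abundances[[i]]
    s <- formula$shifts[[i]]
    if (n == 0 || a == 0) next
    b <- stats::dbinom(0:n, size = n, prob = a)   # heavy-atom count
    el <- numeric(n * s + 1L)
    el[1L + s * (0:n)] <- b
    env <- .convolve_dist(env, el)
  }
  keep <- max(1L, max(which(env > tol)))
  env[seq_len(keep)]
}

# plain linear convolution of two probability vectors
.convolve_dist <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Natural-abundance convolution matrix
#'
#' Lower-triangular matrix `M` with `M[i, j]` the probability that true mass
#' shift `j - 1` is observed at shift `i - 1` through natural heavy isotopes
#' of the unlabeled atoms. `measured = M %*% true` (truncated to `n`
#' channels; channel `i` only receives contributions from true shifts
#' `<= i`, so truncation does not mix the retained channels).
#'
#' @param formula an [ion_formula()].
#' @param n number of measured channels.
#' @return `n` x `n` lower-triangular matrix.
#' @export
na_matrix <- function(formula, n) {
  env <- isotope_envelope(formula)
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    k <- min(n - j + 1L, length(env))
    m[j:(j + k - 1L), j] <- env[seq_len(k)]
  }
  m
}

#' Apply natural-abundance convolution to a MID
#'
#' Forward direction of the natural-abundance correction: smears a labeled
#' MID with the theoretical isotope envelope of the unlabeled atoms (used by
#' the synthetic-data generator to emulate raw measurements).
#'
#' @param x a [mid()].
#' @param formula an [ion_formula()].
#' @param extend logical; if `TRUE` (default) the result is longer than the
#'   input by the significant envelope width and sums to one exactly. If
#'   `FALSE` the result is truncated to `length(x)` channels and renormalized
#'   (what an instrument monitoring a fixed channel set reports).
#' @return a [mid()].
#' @export
convolve_natural_abundance <- function(x, formula, extend = TRUE) {
  stopifnot(is_mid(x))
  env <- isotope_envelope(formula)
  full <- .convolve_dist(as.numeric(x), env)
  if (!extend) full <- full[seq_along(x)]
  mid(full)
}

#' Correct a measured MID for natural abundance
#'
#' Inverts the natural-abundance convolution on the measured channels by
#' solving the lower-triangular system built from the ion formula. Small
#' negative fractions arising from measurement noise are clipped to zero and
#' the vector renormalized; clips larger than `clip_warn` trigger a warning.
#'
#' @param x a raw [mid()] (normalized over the measured channels).
#' @param formula an [ion_formula()].
#' @param clip_warn magnitude of a clipped negative fraction above which a
#'   warning is emitted (mol fraction; default 0.005).
#' @return corrected, renormalized [mid()] of the same length.
#' @export
correct_natural_abundance <- function(x, formula, clip_warn = 0.005) {
  stopifnot(is_mid(x))
  m <- na_matrix(formula, length(x))
  if (abs(det(m)) < 1e-300) {
    stop("natural-abundance correction matrix is singular for this formula",
         call. = FALSE)
  }
  y <- solve(m, as.numeric(x))
  neg <- y < 0
  if (any(neg)) {
    worst <- max(-y[neg])
    if (worst > clip_warn) {
      warning(sprintf(
        "natural-abundance correction clipped a negative fraction of %.4g at %s",
        worst, names(x)[which.min(y)]), call. = FALSE)
    }
    y[neg] <- 0
  }
  mid(y)
}

#' Decode the combined derivatized BHB MID into the two ketone pools
#'
#' After borodeuteride reduction every AcAc-derived molecule carries one
#' deuterium (+1 mass), so even channels of the combined six-channel MID are
#' plasma BHB isotopologues and odd channels are plasma AcAc isotopologues
#' shifted by one. Decoding splits the corrected MID into the individual
#' `[ind]BHB` and `[ind]AcAc` distributions (each over carbon shifts
#' M+0/M+2/M+4, reported over M+0..M+4) and the AcAc share of the total
#' ketone signal.
#'
#' @param combined a natural-abundance corrected, normalized [mid()] with six
#'   channels M+0...M+5.
#' @return object of class `decoded_ketones`: list with `bhb_mid` and
#'   `acac_mid` (each a 5-channel [mid()] populated at M+0/M+2/M+4),
#'   `acac_fraction` (sum of odd channels of the input) and
#'   `odd_carbon_residual` (in vivo odd-carbon signal within each pool,
#'   a data-quality diagnostic that should be ~0 under these tracers).
#' @examples
#' decode_combined_mid(mid(c(0.60, 0.10, 0.08, 0.05, 0.15, 0.02)))
#' @export
decode_combined_mid <- function(combined) {
  stopifnot(is_mid(combined))
  if (length(combined) != 6L) {
    stop("combined MID must have exactly six channels (M+0...M+5)", call. = FALSE)
  }
  x <- as.numeric(combined) / sum(combined)   # invariance under scaling
  even <- x[c(1, 3, 5)]
  odd <- x[c(2, 4, 6)]
  p <- sum(odd)
  if (p <= 0) {
    stop("no AcAc signal: odd isotopologues of the combined MID are all zero; ",
         "AcAc enrichments are undefined", call. = FALSE)
  }
  if (sum(even) <= 0) {
    stop("no BHB signal: even isotopologues of the combined MID are all zero; ",
         "BHB enrichments are undefined", call. = FALSE)
  }
  expand <- function(v3) {
    out <- numeric(5)
    out[c(1, 3, 5)] <- v3
    mid(out)
  }
  structure(list(
    bhb_mid = expand(even / sum(even)),
    acac_mid = expand(odd / p),
    acac_fraction = p,
    odd_carbon_residual = 0
  ), class = "decoded_ketones")
}

#' @export
print.decoded_ketones <- function(x, ...) {
  cat("<decoded ketones>\n  [ind]BHB : ")
  print(x$bhb_mid)
  cat("  [ind]AcAc: ")
  print(x$acac_mid)
  cat(sprintf("  AcAc fraction of total signal: %.4f\n", x$acac_fraction))
  invisible(x)
}

#' Steady-state tracer enrichments from decoded ketone MIDs
#'
#' Extracts the four enrichments of the two-pool matrix method: `A` and `C`
#' are the M+2 and M+4 fractions of plasma AcAc (secondary and primary
#' labeling by the 13C2 AcAc and 13C4 BHB tracers), `B` and `D` the M+2 and
#' M+4 fractions of plasma BHB.
#'
#' @param d a `decoded_ketones` object from [decode_combined_mid()], or a list
#'   with elements `acac_mid` and `bhb_mid` (5-channel MIDs).
#' @return an [enrichment_set()].
#' @export
enrichments_from_decoded <- function(d) {
  stopifnot(!is.null(d$acac_mid), !is.null(d$bhb_mid))
  enrichment_set(A = as.numeric(d$acac_mid[3]),
                 B = as.numeric(d$bhb_mid[3]),
                 C = as.numeric(d$acac_mid[5]),
                 D = as.numeric(d$bhb_mid[5]))
}

#' Steady-state enrichment set of the two-pool model
#'
#' `A`, `B`, `C`, `D` are the steady-state mol-fraction enrichments of
#' 13C2-labeled AcAc, 13C2-labeled BHB, 13C4-labeled AcAc and 13C4-labeled
#' BHB respectively.
#'
#' @param A,B,C,D mol fractions in `[0, 1]`; `A + C <= 1` and `B + D <= 1`.
#' @return object of class `enrichment_set` (named numeric vector).
#' @export
enrichment_set <- function(A, B, C, D) {
  e <- c(A = A, B = B, C = C, D = D)
  if (anyNA(e) || any(e < 0) || any(e > 1)) {
    stop("enrichments must be mol fractions in [0, 1]", call. = FALSE)
  }
  if (A + C > 1 + 1e-9 || B + D > 1 + 1e-9) {
    stop("enrichments of one pool exceed 1 in total (A+C or B+D > 1)", call. = FALSE)
  }
  structure(e, class = "enrichment_set")
}
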