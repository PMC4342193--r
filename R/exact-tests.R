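#' Hardy-Weinberg likelihood ratio between adjacent heterozygote counts
#'
#' Under Hardy-Weinberg equilibrium with fixed allele margins `n1`, `n2`
#' (copies of each allele among `n = (n1+n2)/2` diploids), the ratio of the
#' likelihoods of observing `k + 2` versus `k` heterozygotes is
#' `(n1 - k)(n2 - k) / ((k + 1)(k + 2))`. This recurrence is what lets the
#' exact test run without evaluating any factorial.
#'
#' @param k heterozygote count; `k` and `k + 2` must both be valid for the
#'   margins (correct parity and range).
#' @param n1,n2 allele copy totals.
#' @return The likelihood ratio.
#' @export
hwe_ratio <- function(k, n1, n2) {
  if (n1 %% 1 != 0 || n2 %% 1 != 0 || k %% 1 != 0) stop("counts must be integers")
  if ((n1 + n2) %% 2 != 0) stop("n1 + n2 must be even")
  if (k %% 2 != n1 %% 2) stop("k does not share parity with n1")
  if (k < 0 || k > min(n1, n2)) stop("k is not a valid heterozygote count")
  (n1 - k) * (n2 - k) / ((k + 1) * (k + 2))
}

exact_result <- function(lst, midp) {
  structure(list(p = lst$p, midp = lst$midp, obs_mass = lst$obs_mass,
                 n_terms = lst$n_terms %||% NA_real_, midp_mode = midp),
            class = "exact_test_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exact_test_result <- function(x, ...) {
  cat(sprintf("exact test: p = %.10g, mid-p = %.10g (obs mass %.4g)\n",
              x$p, x$midp, x$obs_mass))
  invisible(x)
}

#' Hardy-Weinberg exact test with early termination
#'
#' Two-sided exact test for deviation from Hardy-Weinberg proportions.
#' Likelihoods of all heterozygote counts compatible with the allele
#' margins are accumulated as values relative to the most probable count,
#' moving outward from it with the [hwe_ratio()] recurrence; each tail stops
#' as soon as the newest term no longer changes any double-precision partial
#' sum, so only O(sqrt(n)) of the O(n) terms are ever touched and memory use
#' is constant. Tables whose null likelihood is at most the observed
#' table's count toward the p-value (ties included). The mid-p value
#' subtracts half of the observed table's probability.
#'
#' @param n_hom1,n_het,n_hom2 observed genotype counts.
#' @param midp logical; marks the returned object as mid-p mode (both plain
#'   and mid-p values are always computed).
#' @return An `exact_test_result` with fields `p`, `midp`, `obs_mass` and
#'   `n_terms` (likelihood evaluations used).
#' @export
hwe_exact <- function(n_hom1, n_het, n_hom2, midp = FALSE)
  exact_result(.hwe_exact_cpp(as.integer(n_hom1), as.integer(n_het),
                              as.integer(n_hom2)), midp)

#' @describeIn hwe_exact Full-summation reference in 80-bit extended
#'   precision; independent of the early-termination path, used to certify
#'   its accuracy.
#' @export
hwe_exact_full <- function(n_hom1, n_het, n_hom2, midp = FALSE)
  exact_result(.hwe_exact_full_cpp(as.integer(n_hom1), as.integer(n_het),
                                   as.integer(n_hom2)), midp)

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(nrow(table) == 2, ncol(table) == 2)
    as.integer(c(table[1, 1], table[1, 2], table[2, 1], table[2, 2]))
  } else {
    stopifnot(length(table) == 4)
    as.integer(table)
  }
}

#' Fisher's exact test on a 2x2 table, early termination
#'
#' Same mathematical structure as the Hardy-Weinberg exact test: the
#' hypergeometric family over the upper-left cell is swept outward from its
#' mode with an adjacent-table likelihood ratio recurrence, and each tail
#' sweep stops when its terms stop changing the partial sums. Two-sided:
#' tables at most as likely as the observed one count, ties included.
#'
#' @param table 2x2 integer matrix, or length-4 vector
#'   (a11, a12, a21, a22).
#' @param midp logical; see [hwe_exact()].
#' @return An `exact_test_result`.
#' @export
fisher_2x2 <- function(table, midp = FALSE) {
  t4 <- as_2x2(table)
  if (any(t4 < 0)) stop("negative cell count")
  if (sum(t4) == 0) stop("empty contingency table")
  exact_result(.fisher_2x2_cpp(t4[1], t4[2], t4[3], t4[4]), midp)
}

#' @describeIn fisher_2x2 Full-enumeration extended-precision reference.
#' @export
fisher_2x2_full <- function(table, midp = FALSE) {
  t4 <- as_2x2(table)
  exact_result(.fisher_2x2_full_cpp(t4[1], t4[2], t4[3], t4[4]), midp)
}

#' Range of 2x2 tables that can affect a double-precision p-value
#'
#' For the hypergeometric family with the given margins, returns the
#' smallest and largest upper-left cell values whose null frequency
#' (probability within the family, so the frequencies sum to 1) is at
#' least 2^-53. Tables outside this range underflow out of a naive
#' double-precision p-value denominator; their total mass is provably
#' negligible because the frequencies decay super-geometrically. The
#' frequencies are generated with the adjacent-table ratio recurrence in
#' log space - no factorials are evaluated.
#'
#' @param row1_sum top row sum.
#' @param col1_sum left column sum.
#' @param total grand total.
#' @return integer vector `c(min_cell, max_cell)`.
#' @export
relative_likelihood_support <- function(row1_sum, col1_sum, total) {
  R1 <- as.numeric(row1_sum); C1 <- as.numeric(col1_sum); N <- as.numeric(total)
  if (R1 < 0 || C1 < 0 || R1 > N || C1 > N) stop("impossible margins")
  xmin <- max(0, R1 + C1 - N)
  xmax <- min(R1, C1)
  if (xmin > xmax) stop("impossible margins")
  x <- xmin:xmax
  if (length(x) == 1L) return(as.integer(c(xmin, xmin)))
  # log ratio L(x+1)/L(x), accumulated, then normalised so the family's
  # frequencies sum to 1
  xs <- x[-length(x)]
  lr <- log((R1 - xs) * (C1 - xs)) - log((xs + 1) * (N - R1 - C1 + xs + 1))
  lrel <- c(0, cumsum(lr))
  lrel <- lrel - max(lrel)
  lfreq <- lrel - log(sum(exp(lrel)))
  inside <- which(lfreq >= -53 * log(2))
  as.integer(c(x[min(inside)], x[max(inside)]))
}

#' Fisher's exact test on a 2x3 table, region-restricted
#'
#' Two-sided exact test over the two-parameter lattice of 2x3 tables with
#' fixed margins. Likelihoods are generated by adjacent-table ratio
#' recurrences (no factorials): rows of the lattice are scanned outward from
#' the modal row and each row is swept outward from its conditional mode.
#' The denominator visits only the elliptical region of tables with
#' relative likelihood above 2^-53 of the maximum; the numerator only the
#' annulus within a factor 2^53 below the observed likelihood. Both
#' restrictions leave the p-value unchanged to well beyond 10 significant
#' digits because the neglected likelihoods decay super-geometrically.
#'
#' An all-zero column reduces the problem to [fisher_2x2()]; a zero row
#' margin admits a single table and returns p = 1.
#'
#' @param table 2x3 integer matrix (rows are the two groups).
#' @param midp logical; see [hwe_exact()].
#' @return An `exact_test_result`.
#' @export
fisher_2x3 <- function(table, midp = FALSE) {
  stopifnot(is.matrix(table), nrow(table) == 2, ncol(table) == 3)
  if (any(table < 0)) stop("negative cell count")
  if (sum(table) == 0) stop("empty contingency table")
  colsum <- colSums(table)
  if (any(colsum == 0)) {
    kept <- table[, colsum > 0, drop = FALSE]
    if (ncol(kept) >= 3) stop("internal: reduction failed")
    if (ncol(kept) <= 1 || any(rowSums(kept) == 0))
      return(exact_result(list(p = 1, midp = 0.5, obs_mass = 1), midp))
    return(fisher_2x2(kept, midp))
  }
  if (any(rowSums(table) == 0))
    return(exact_result(list(p = 1, midp = 0.5, obs_mass = 1), midp))
  exact_result(.fisher_2x3_cpp(as.integer(table[1, ]), as.integer(table[2, ])),
               midp)
}

#' @describeIn fisher_2x3 Exhaustive extended-precision enumeration over
#'   every margin-consistent table.
#' @export
fisher_2x3_full <- function(table, midp = FALSE) {
  stopifnot(is.matrix(table), nrow(table) == 2, ncol(table) == 3)
  exact_result(.fisher_2x3_full_cpp(as.integer(table[1, ]),
                                    as.integer(table[2, ])), midp)
}

#' Agreeing leading significant digits of two numbers
#'
#' @param x,y positive numbers; `y` is the reference.
#' @return Number of agreeing leading significant digits (capped at 16;
#'   0 when the values differ in magnitude or sign).
#' @export
matching_digits <- function(x, y) {
  if (is.na(x) || is.na(y)) return(0)
  if (x == y) return(16)
  if (y == 0) return(0)
  rel <- abs(x - y) / abs(y)
  if (rel <= 0) return(16)
  max(0, min(16, floor(-log10(rel))))
}
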