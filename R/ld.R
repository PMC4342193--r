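#' Genotype correlation between two variants
#'
#' Pearson correlation r of the dosage recodings v = x - 1, w = y - 1
#' (missing = 0, excluded via the intersection of called samples), with
#' every moment obtained from bit population counts on the packed rows and
#' the dot product from the 2-bit kernel ([dot_product_packed()]).
#'
#' @param x,y integer genotype vectors (0/1/2/`NA`) of equal length, or a
#'   `popgen_dataset` in `x` with variant indices in `y` (length 2).
#' @return list of class `ld_pair`: `n_obs`, `mean_v`, `mean_w`, `mean_v2`,
#'   `mean_w2`, `dot`, `r` and `valid` (`FALSE` when no overlap or zero
#'   variance makes r undefined).
#' @export
pair_r <- function(x, y) {
  if (inherits(x, "popgen_dataset") || inherits(x, "packed_genotypes")) {
    g <- genotypes(x)
    stopifnot(length(y) == 2)
    cmp <- .ld_pair_components_cpp(g$data, g$n_samples, g$n_variants,
                                   as.integer(y[1]) - 1L, as.integer(y[2]) - 1L)
  } else {
    pk <- pack_genotypes(cbind(as.integer(x), as.integer(y)))
    cmp <- .ld_pair_components_cpp(pk$data, pk$n_samples, 2L, 0L, 1L)
  }
  r_from_components(cmp)
}

# shared arithmetic so the general and precomputed-moment paths produce
# bitwise identical r
r_from_components <- function(cmp) {
  out <- list(n_obs = cmp$n_obs, mean_v = NA_real_, mean_w = NA_real_,
              mean_v2 = NA_real_, mean_w2 = NA_real_, dot = cmp$dot,
              r = NA_real_, valid = FALSE)
  if (cmp$n_obs == 0) return(structure(out, class = "ld_pair"))
  out$mean_v <- cmp$sum_x / cmp$n_obs
  out$mean_w <- cmp$sum_y / cmp$n_obs
  out$mean_v2 <- cmp$sum_x2 / cmp$n_obs
  out$mean_w2 <- cmp$sum_y2 / cmp$n_obs
  varv <- out$mean_v2 - out$mean_v^2
  varw <- out$mean_w2 - out$mean_w^2
  if (varv > 0 && varw > 0) {
    out$r <- (cmp$dot / cmp$n_obs - out$mean_v * out$mean_w) /
      sqrt(varv * varw)
    out$valid <- TRUE
  }
  structure(out, class = "ld_pair")
}

#' Per-variant moments for the no-missing fast path
#'
#' For all-pairs correlation scans, a variant's mean and second moment do
#' not depend on the partner variant when no data is missing, so they are
#' precomputed once (O(mn) total, O(m) space) instead of once per pair.
#' Variants with missing calls fall back to the general per-pair path.
#'
#' @param dataset a `popgen_dataset`.
#' @return data frame: `sum_v`, `sum_v2`, `n_called`, `no_missing`.
#' @export
precompute_nomissing_moments <- function(dataset) {
  g <- genotypes(dataset)
  cnt <- .genotype_count_matrix_cpp(g$data, g$n_samples, g$n_variants)
  data.frame(sum_v = cnt[3, ] - cnt[1, ],          # sums of dosage - 1
             sum_v2 = cnt[1, ] + cnt[3, ],
             n_called = g$n_samples - cnt[4, ],
             no_missing = cnt[4, ] == 0)
}

#' All-pairs genotype correlation matrix
#'
#' Uses the precomputed-moment fast path for variant pairs where neither
#' variant has missing data, and the general intersection path otherwise;
#' the two paths give bitwise identical r.
#'
#' @param dataset a `popgen_dataset`.
#' @return m x m matrix of r (`NA` where undefined).
#' @export
ld_r_matrix <- function(dataset) {
  g <- genotypes(dataset)
  m <- g$n_variants
  mom <- precompute_nomissing_moments(dataset)
  out <- matrix(NA_real_, m, m)
  varv <- mom$sum_v2 / pmax(mom$n_called, 1) -
    (mom$sum_v / pmax(mom$n_called, 1))^2
  diag(out) <- ifelse(mom$n_called > 0 & varv > 0, 1, NA_real_)
  if (m < 2) return(out)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    if (mom$no_missing[i] && mom$no_missing[j]) {
      cmp <- list(n_obs = as.numeric(g$n_samples),
                  sum_x = mom$sum_v[i], sum_y = mom$sum_v[j],
                  sum_x2 = mom$sum_v2[i], sum_y2 = mom$sum_v2[j],
                  dot = .ld_dot_cpp(g$data, g$n_samples, m, i - 1L, j - 1L))
      st <- r_from_components(cmp)
    } else {
      st <- pair_r(dataset, c(i, j))
    }
    out[i, j] <- out[j, i] <- st$r
  }
  out
}

#' Window-based LD pruning
#'
#' Within a sliding window of `window_size` variants (advanced by `step`),
#' while any remaining pair has r^2 above the threshold, the member of the
#' pair with the smaller minor allele frequency is removed (ties remove the
#' later-positioned variant); r^2 is never computed against a removed
#' variant, and windows never span chromosomes. On return no surviving
#' pair within any window exceeds the threshold.
#'
#' @param dataset a `popgen_dataset`.
#' @param window_size window width in variants.
#' @param step window shift in variants; `window_size > step >= 1`.
#' @param r2_threshold prune pairs with r^2 strictly above this.
#' @return list: `keep` / `prune` (variant ids), `keep_idx` / `prune_idx`.
#' @export
indep_pairwise <- function(dataset, window_size, step, r2_threshold) {
  stopifnot(window_size > step, step >= 1,
            r2_threshold > 0, r2_threshold < 1)
  m <- genotypes(dataset)$n_variants
  maf <- allele_frequencies(dataset)$maf
  chrom <- dataset$variants$chrom
  alive <- rep(TRUE, m)
  r2 <- function(i, j) {
    st <- pair_r(dataset, c(i, j))
    if (st$valid) st$r^2 else -Inf
  }
  for (chr in unique(chrom)) {
    cidx <- which(chrom == chr)
    for (s in seq(1L, max(1L, length(cidx)), by = step)) {
      win <- cidx[s:min(s + window_size - 1L, length(cidx))]
      if (length(win) >= 2) repeat {
        cur <- win[alive[win]]
        if (length(cur) < 2) break
        removed <- FALSE
        for (ii in 1:(length(cur) - 1)) for (jj in (ii + 1):length(cur)) {
          i <- cur[ii]; j <- cur[jj]
          if (!alive[i] || !alive[j]) next
          if (r2(i, j) > r2_threshold) {
            drop <- if (maf[i] < maf[j]) i
                    else if (maf[j] < maf[i]) j else max(i, j)
            alive[drop] <- FALSE
            removed <- TRUE
          }
        }
        if (!removed) break
      }
      if (s + window_size - 1L >= length(cidx)) break
    }
  }
  list(keep = dataset$variants$vid[alive],
       prune = dataset$variants$vid[!alive],
       keep_idx = which(alive), prune_idx = which(!alive))
}

#' 3x3 genotype-pair table for two variants
#'
#' @param x,y integer genotype vectors (a2 dosage 0/1/2/`NA`).
#' @return 3x3 matrix; cell (i+1, j+1) counts jointly called samples with
#'   i copies of a1 at the first variant and j at the second.
#' @export
diplotype_counts <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  tab <- table(factor(2 - x[ok], levels = 0:2),
               factor(2 - y[ok], levels = 0:2))
  matrix(as.numeric(tab), 3, 3)
}

# cell probabilities of the 3x3 genotype table under haplotype frequencies
# implied by (pA, pB, p11); cell (i+1, j+1) = i copies of A, j of B
diplotype_cell_probs <- function(pA, pB, p11) {
  f11 <- p11; f12 <- pA - p11; f21 <- pB - p11; f22 <- 1 - pA - pB + p11
  f11 <- max(f11, 0); f12 <- max(f12, 0); f21 <- max(f21, 0); f22 <- max(f22, 0)
  matrix(c(f22^2,        2 * f21 * f22,             f21^2,
           2 * f12 * f22, 2 * (f11 * f22 + f12 * f21), 2 * f11 * f21,
           f12^2,        2 * f11 * f12,             f11^2),
         3, 3, byrow = TRUE)
}

diplotype_loglik <- function(nij, pA, pB, p11) {
  P <- diplotype_cell_probs(pA, pB, p11)
  use <- nij > 0
  if (any(use & P <= 0)) return(-Inf)
  sum(nij[use] * log(P[use]))
}

# real roots of a3 x^3 + a2 x^2 + a1 x + a0 (closed form)
solve_cubic_real <- function(a3, a2, a1, a0) {
  if (abs(a3) < 1e-300) {
    if (abs(a2) < 1e-300) {
      if (abs(a1) < 1e-300) return(numeric(0))
      return(-a0 / a1)
    }
    disc <- a1^2 - 4 * a2 * a0
    if (disc < 0) return(numeric(0))
    return((-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2))
  }
  b <- a2 / a3; c1 <- a1 / a3; d <- a0 / a3
  p <- c1 - b^2 / 3
  q <- 2 * b^3 / 27 - b * c1 / 3 + d
  disc <- (q / 2)^2 + (p / 3)^3
  shift <- -b / 3
  if (disc > 0) {
    s <- sqrt(disc)
    u <- cbrt(-q / 2 + s); v <- cbrt(-q / 2 - s)
    return(u + v + shift)
  }
  if (abs(disc) <= 1e-30 * max(1, q^2)) {
    if (abs(q) < 1e-300 && abs(p) < 1e-300) return(shift)
    u <- cbrt(-q / 2)
    return(c(2 * u, -u) + shift)
  }
  # three real roots (casus irreducibilis)
  r <- sqrt(-p^3 / 27)
  phi <- acos(pmin(1, pmax(-1, -q / (2 * r))))
  2 * sqrt(-p / 3) * cos((phi + 2 * pi * 0:2) / 3) + shift
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Maximum-likelihood haplotype frequency for two variants (Hill cubic)
#'
#' Estimates the frequency p11 of the haplotype carrying the a1 allele at
#' both variants from unphased genotype counts. With the double-heterozygote
#' cell phase-ambiguous, the likelihood stationarity (EM fixed-point)
#' condition is a cubic in p11; it is solved in closed form, roots outside
#' `[max(0, pA + pB - 1), min(pA, pB)]` are discarded, and log-likelihoods
#' are compared only when several candidates are in range (interval
#' boundaries are always candidates).
#'
#' Lewontin's D' is `D / Dmax` with `D = p11 - pA pB` and
#' `Dmax = min(pA(1-pB), (1-pA)pB)` for positive D, else
#' `min(pA pB, (1-pA)(1-pB))`.
#'
#' @param counts 3x3 genotype-pair count matrix from [diplotype_counts()].
#' @return list: `p11`, `log_likelihood`, `D`, `dprime` (signed),
#'   `dprime_abs`, `pA`, `pB`, `n_roots_in_range`, `valid`.
#' @export
diplotype_mle <- function(counts) {
  nij <- as.matrix(counts)
  N <- sum(nij)
  if (N <= 0) return(list(valid = FALSE))
  pA <- sum(nij * matrix(0:2, 3, 3)) / (2 * N)       # a1 freq, variant 1
  pB <- sum(nij * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(list(valid = FALSE, pA = pA, pB = pB))
  # definite haplotype counts; d ambiguous double hets
  c11 <- 2 * nij[3, 3] + nij[3, 2] + nij[2, 3]
  d <- nij[2, 2]
  H <- 2 * N
  # (H p - c11) (2 p^2 + b1 p + b0) - d (p^2 + (1 - pA - pB) p) = 0
  b1 <- 1 - 2 * pA - 2 * pB
  b0 <- pA * pB
  roots <- solve_cubic_real(2 * H,
                            H * b1 - 2 * c11 - d,
                            H * b0 - c11 * b1 - d * (1 - pA - pB),
                            -c11 * b0)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  eps <- 1e-12
  inr <- roots[roots >= lo - eps & roots <= hi + eps]
  inr <- pmin(pmax(inr, lo), hi)
  if (length(inr) > 1) inr <- inr[!duplicated(round(inr, 10))]
  cand <- unique(c(inr, lo, hi))
  ll <- vapply(cand, function(p) diplotype_loglik(nij, pA, pB, p), numeric(1))
  best <- which.max(ll)
  p11 <- cand[best]
  D <- p11 - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (Dmax > 0) D / Dmax else 0
  list(p11 = p11, log_likelihood = ll[best], D = D,
       dprime = dprime, dprime_abs = abs(dprime), pA = pA, pB = pB,
       n_roots_in_range = length(inr), valid = TRUE)
}

# orient the table so the MLE D is non-negative (flip variant 2 alleles)
orient_counts <- function(nij, mle) {
  if (mle$dprime < 0) nij[, 3:1] else nij
}

# log-likelihoods at the 101-point |D'| grid (allele frequencies fixed at
# their MLEs, p11 implied by each grid value)
dprime_grid_loglik <- function(nij, pA, pB, dgrid = seq(0, 1, by = 0.01)) {
  Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  vapply(dgrid, function(d)
    diplotype_loglik(nij, pA, pB, pA * pB + d * Dmax), numeric(1))
}

#' Wall-Pritchard 90% confidence interval for |D'| and Gabriel class
#'
#' Relative likelihoods are evaluated at the 101 grid points |D'| = 0,
#' 0.01, ..., 1 (allele frequencies held at their MLEs, the table oriented
#' so D >= 0); `ci_low` is the largest grid value whose cumulative
#' normalised likelihood is at most 5%, `ci_high` the smallest reaching
#' 95%. Classification: `strong_LD` when `ci_low >= strong_low` and
#' `ci_high >= strong_high`; `recombination` when `ci_high < recomb_high`;
#' otherwise `inconclusive`.
#'
#' @param counts 3x3 genotype-pair count matrix.
#' @param strong_low,strong_high,recomb_high classification thresholds
#'   (defaults 0.70, 0.98, 0.90).
#' @return list of class `dprime_ci`: `dprime_mle`, `ci_low`, `ci_high`,
#'   `classification`, `valid`.
#' @export
dprime_ci <- function(counts, strong_low = 0.70, strong_high = 0.98,
                      recomb_high = 0.90) {
  mle <- diplotype_mle(counts)
  if (!isTRUE(mle$valid))
    return(list(valid = FALSE, classification = "undefined"))
  nij <- orient_counts(as.matrix(counts), mle)
  pA <- mle$pA
  pB <- if (mle$dprime < 0) 1 - mle$pB else mle$pB
  ll <- dprime_grid_loglik(nij, pA, pB)
  rel <- exp(ll - max(ll))
  cdf <- cumsum(rel) / sum(rel)
  dgrid <- seq(0, 1, by = 0.01)
  lowset <- which(cdf <= 0.05)
  ci_low <- if (length(lowset)) dgrid[max(lowset)] else 0
  ci_high <- dgrid[min(which(cdf >= 0.95))]
  cls <- if (ci_low >= strong_low && ci_high >= strong_high) "strong_LD"
         else if (ci_high < recomb_high) "recombination"
         else "inconclusive"
  structure(list(dprime_mle = mle$dprime_abs, ci_low = ci_low,
                 ci_high = ci_high, classification = cls, valid = TRUE),
            class = "dprime_ci")
}

#' Fast Gabriel classification of a variant pair
#'
#' Produces exactly the classification of [dprime_ci()] while usually
#' evaluating only two of the 101 grid likelihoods. When the Hill cubic has
#' a single stationary point (the usual case) the grid likelihood is
#' unimodal, so if the likelihood peak sits left of `recomb_high` and
#' `L(recomb_high) < L(peak) * 0.05 / k` (k = number of grid points at or
#' beyond `recomb_high`; k/0.05 = 220 with defaults), the rightmost k
#' likelihoods must sum to under 5% of the total and the pair is
#' `recombination` without further evaluation. Any other situation falls
#' back to the full grid, so the acceleration is lossless.
#'
#' @inheritParams dprime_ci
#' @return The classification string.
#' @export
classify_pair_fast <- function(counts, strong_low = 0.70, strong_high = 0.98,
                               recomb_high = 0.90) {
  mle <- diplotype_mle(counts)
  if (!isTRUE(mle$valid)) return("undefined")
  full <- function() dprime_ci(counts, strong_low, strong_high,
                               recomb_high)$classification
  if (mle$n_roots_in_range > 1) return(full()) # possibly multimodal
  if (strong_high < recomb_high) return(full()) # shortcut proof needs this
  nij <- orient_counts(as.matrix(counts), mle)
  pA <- mle$pA
  pB <- if (mle$dprime < 0) 1 - mle$pB else mle$pB
  dstar <- mle$dprime_abs
  if (dstar >= recomb_high - 0.011) return(full())
  Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  gridL <- function(d) diplotype_loglik(nij, pA, pB, pA * pB + d * Dmax)
  # grid peak is adjacent to the continuous peak; use the larger neighbour
  g1 <- floor(dstar * 100) / 100
  lpeak <- max(gridL(g1), gridL(min(1, g1 + 0.01)))
  k <- length(seq(recomb_high, 1, by = 0.01))
  lr <- gridL(recomb_high)
  if (is.finite(lpeak) && lr - lpeak < log(0.05 / k)) return("recombination")
  full()
}

#' Gabriel haplotype block estimation
#'
#' Identifies contiguous variant runs whose endpoint pair is in strong LD
#' and in which strong-LD informative pairs outnumber recombination pairs
#' by more than 19:1 (inconclusive pairs are not informative). Candidate
#' spans (within `max_span_kb`) are selected greedily by descending
#' base-pair span (ties: leftmost first), discarding overlaps. Variants
#' with MAF below `maf_min` are excluded beforehand. Pair classifications
#' are computed lazily with [classify_pair_fast()] and cached per
#' chromosome; with `skip_bound` a candidate's pair scan aborts as soon as
#' its recombination count provably breaks 19:1 even if every unseen pair
#' were strong - an output-preserving shortcut.
#'
#' @param dataset a `popgen_dataset`, variants sorted by (chrom, bp).
#' @param max_span_kb maximum block span in kilobases.
#' @param maf_min MAF pre-filter.
#' @param strong_low,strong_high,recomb_high see [dprime_ci()].
#' @param skip_bound apply the 19:1 early-skip bound.
#' @param use_fast use [classify_pair_fast()] (otherwise the full grid).
#' @return data frame, one row per block: `chrom`, `first`, `last`
#'   (variant indices in `dataset`), `bp_start`, `bp_end`, `n_variants`,
#'   `vids` (comma-separated).
#' @export
gabriel_blocks <- function(dataset, max_span_kb = 200, maf_min = 0.05,
                           strong_low = 0.70, strong_high = 0.98,
                           recomb_high = 0.90, skip_bound = TRUE,
                           use_fast = TRUE) {
  if (!is_position_sorted(dataset))
    stop("variants must be sorted by (chrom, bp)")
  fr <- allele_frequencies(dataset)
  eligible <- which(!is.na(fr$maf) & fr$maf >= maf_min)
  blocks <- list()
  for (chr in unique(dataset$variants$chrom[eligible])) {
    vidx <- eligible[dataset$variants$chrom[eligible] == chr]
    mv <- length(vidx)
    if (mv < 2) next
    bp <- dataset$variants$bp[vidx]
    cls_cache <- matrix(NA_character_, mv, mv)
    classify <- function(i, j) { # local indices
      if (!is.na(cls_cache[i, j])) return(cls_cache[i, j])
      x <- variant_dosages(dataset, vidx[i])
      y <- variant_dosages(dataset, vidx[j])
      cnt <- diplotype_counts(x, y)
      cl <- if (use_fast)
        classify_pair_fast(cnt, strong_low, strong_high, recomb_high)
      else dprime_ci(cnt, strong_low, strong_high, recomb_high)$classification
      cls_cache[i, j] <<- cl
      cl
    }
    # candidate spans: endpoints strong, 19:1 informative ratio inside
    cand <- list()
    for (i in 1:(mv - 1)) {
      for (j in (i + 1):mv) {
        if (bp[j] - bp[i] > max_span_kb * 1000) break
        if (classify(i, j) != "strong_LD") next
        npairs <- (j - i + 1) * (j - i) / 2
        strong <- 0; recomb <- 0; seen <- 0; ok <- TRUE
        for (u in i:(j - 1)) {
          for (v in (u + 1):j) {
            cl <- classify(u, v)
            seen <- seen + 1
            if (cl == "strong_LD") strong <- strong + 1
            else if (cl == "recombination") recomb <- recomb + 1
            if (skip_bound && (strong + (npairs - seen)) <= 19 * recomb) {
              ok <- FALSE; break
            }
          }
          if (!ok) break
        }
        if (ok && strong > 19 * recomb)
          cand[[length(cand) + 1]] <-
            list(i = i, j = j, span = bp[j] - bp[i])
      }
    }
    if (!length(cand)) next
    spans <- vapply(cand, `[[`, numeric(1), "span")
    lefts <- vapply(cand, `[[`, numeric(1), "i")
    ord <- order(-spans, lefts)
    used <- rep(FALSE, mv)
    for (k in ord) {
      i <- cand[[k]]$i; j <- cand[[k]]$j
      if (any(used[i:j])) next
      used[i:j] <- TRUE
      blocks[[length(blocks) + 1]] <- data.frame(
        chrom = chr, first = vidx[i], last = vidx[j],
        bp_start = bp[i], bp_end = bp[j], n_variants = j - i + 1,
        vids = paste(dataset$variants$vid[vidx[i:j]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks))
    return(data.frame(chrom = character(), first = integer(),
                      last = integer(), bp_start = integer(),
                      bp_end = integer(), n_variants = integer(),
                      vids = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, blocks)
  out[order(out$chrom, out$bp_start), , drop = FALSE]
}
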