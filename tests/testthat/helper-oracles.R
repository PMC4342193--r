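# Independent reference implementations used as oracles. Everything here is
# deliberately naive: per-element loops and textbook formulas, sharing no
# code with the kernels they check.

# scalar IBS loop (IBS0/IBS1/IBS2 tallies)
naive_ibs <- function(a, b) {
  ibs0 <- ibs1 <- ibs2 <- 0
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    if (a[i] == b[i]) ibs2 <- ibs2 + 1
    else if (abs(a[i] - b[i]) == 2) ibs0 <- ibs0 + 1
    else ibs1 <- ibs1 + 1
  }
  tot <- ibs0 + ibs1 + ibs2
  list(diff = 2 * ibs0 + ibs1, obs = 2 * tot,
       ibs = if (tot > 0) (0 * ibs0 + 1 * ibs1 + 2 * ibs2) / (2 * tot)
             else NA_real_)
}

naive_dot <- function(x, y) {
  v <- ifelse(is.na(x), 0, x - 1)
  w <- ifelse(is.na(y), 0, y - 1)
  sum(v * w)
}

naive_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok]))
}

# direct double-precision GRM (a1 dosages, per-genotype loop)
naive_grm <- function(ds, q = NULL) {
  G <- unpack_genotypes(ds)
  X <- 2 - G
  n <- nrow(X); m <- ncol(X)
  if (is.null(q)) q <- allele_frequencies(ds)$a1_freq
  acc <- matrix(0, n, n); den <- matrix(0, n, n)
  for (j in seq_len(m)) {
    ok <- !is.na(X[, j])
    x <- X[, j] - 2 * q[j]
    inc <- outer(x, x) / (2 * q[j] * (1 - q[j]))
    okm <- outer(ok, ok)
    acc <- acc + ifelse(okm, inc, 0)
    den <- den + okm
  }
  list(values = acc / den, denominators = den)
}

# naive O(n^3) complete linkage returning merge heights (sorted)
naive_complete_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# EM iteration for the two-locus haplotype frequency
em_p11 <- function(nij, iters = 10000) {
  N <- sum(nij)
  pA <- sum(nij * matrix(0:2, 3, 3)) / (2 * N)
  pB <- sum(nij * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  c11 <- 2 * nij[3, 3] + nij[3, 2] + nij[2, 3]
  d <- nij[2, 2]
  p <- pA * pB
  for (it in seq_len(iters)) {
    f11 <- p; f12 <- pA - p; f21 <- pB - p; f22 <- 1 - pA - pB + p
    den <- f11 * f22 + f12 * f21
    alpha <- if (den > 0) f11 * f22 / den else 0.5
    p <- (c11 + d * alpha) / (2 * N)
  }
  p
}

# non-streaming Gabriel reference: full-grid classification of every pair,
# exhaustive candidate enumeration, greedy by span
reference_gabriel <- function(ds, max_span_kb = 200, maf_min = 0.05) {
  fr <- allele_frequencies(ds)
  out <- NULL
  for (chr in unique(ds$variants$chrom)) {
    keep <- which(ds$variants$chrom == chr & !is.na(fr$maf) & fr$maf >= maf_min)
    mv <- length(keep)
    if (mv < 2) next
    bp <- ds$variants$bp[keep]
    G <- unpack_genotypes(ds)[, keep, drop = FALSE]
    cls <- matrix(NA_character_, mv, mv)
    for (i in 1:(mv - 1)) for (j in (i + 1):mv) {
      r <- dprime_ci(diplotype_counts(G[, i], G[, j]))
      cls[i, j] <- if (isTRUE(r$valid)) r$classification else "undefined"
    }
    cand <- NULL
    for (i in 1:(mv - 1)) for (j in (i + 1):mv) {
      if (bp[j] - bp[i] > max_span_kb * 1000) next
      if (cls[i, j] != "strong_LD") next
      sub <- cls[i:j, i:j]
      s <- sum(sub == "strong_LD", na.rm = TRUE)
      r <- sum(sub == "recombination", na.rm = TRUE)
      if (s > 19 * r)
        cand <- rbind(cand, data.frame(i = i, j = j, span = bp[j] - bp[i]))
    }
    if (is.null(cand)) next
    cand <- cand[order(-cand$span, cand$i), ]
    used <- rep(FALSE, mv)
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (any(used[i:j])) next
      used[i:j] <- TRUE
      out <- rbind(out, data.frame(chrom = chr, first = keep[i],
                                   last = keep[j], stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(out)
  out[order(out$chrom, out$first), , drop = FALSE]
}

# random dataset helpers
random_dataset <- function(n, m, missing_rate = 0.05, seed = 1) {
  sim <- simulate_dataset(sim_spec(n, m, missing_rate = missing_rate,
                                   seed = seed))
  sim$dataset
}

random_genotypes <- function(len, miss = 0.2) {
  g <- sample(c(0:2, NA), len, replace = TRUE,
              prob = c((1 - miss) / 3, (1 - miss) / 3, (1 - miss) / 3, miss))
  as.integer(g)
}
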