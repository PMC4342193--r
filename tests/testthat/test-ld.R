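test_that("pair_r matches the direct intersection correlation", {
  st <- pair_r(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L))
  expect_equal(st$r, 1)
  # intersection excludes the phi/0 pair, leaving perfect anticorrelation
  st <- pair_r(c(0L, 1L, 2L, NA), c(2L, 1L, 0L, 0L))
  expect_equal(st$r, -1)
  set.seed(501)
  for (rep in 1:60) {
    len <- sample(c(10, 33, 100, 500), 1)
    x <- random_genotypes(len, miss = ifelse(rep %% 2, 0, 0.2))
    y <- random_genotypes(len, miss = ifelse(rep %% 2, 0, 0.2))
    st <- pair_r(x, y)
    ref <- naive_r(x, y)
    if (st$valid && !is.na(ref))
      expect_lt(abs(st$r - ref) / max(abs(ref), 1e-3), 1e-12)
  }
  expect_false(pair_r(c(NA, NA, 0L), c(0L, 1L, NA))$valid)
})

test_that("no-missing fast path is bitwise equal to the general path", {
  ds <- random_dataset(40, 25, missing_rate = 0, seed = 11)
  rm1 <- ld_r_matrix(ds)
  rm2 <- outer(1:25, 1:25, Vectorize(function(i, j) {
    if (i == j) return(rm1[i, j])
    pair_r(ds, c(i, j))$r
  }))
  expect_identical(unname(rm1), unname(rm2))
  # mixed missingness: fallback used, values still equal the general path
  dsm <- random_dataset(40, 15, missing_rate = 0.1, seed = 12)
  rmm <- ld_r_matrix(dsm)
  for (k in 1:20) {
    i <- sample(15, 1); j <- sample(15, 1)
    if (i == j) next
    expect_identical(rmm[i, j], pair_r(dsm, c(i, j))$r)
  }
})

test_that("indep_pairwise leaves no surviving pair above the threshold", {
  # all pairs below threshold -> everything kept
  ds <- random_dataset(100, 12, missing_rate = 0, seed = 13)
  pr <- indep_pairwise(ds, 10, 2, 0.99)
  r2max <- max(ld_r_matrix(ds)[upper.tri(diag(12))]^2, na.rm = TRUE)
  if (r2max < 0.99) expect_equal(length(pr$prune), 0)
  # five identical variants -> one survivor
  g <- matrix(rep(random_genotypes(60, miss = 0), 5), ncol = 5)
  dsdup <- new_dataset(g)
  prd <- indep_pairwise(dsdup, 5, 2, 0.5)
  expect_equal(length(prd$keep), 1)
  # blocky fixture, standard parameters; verify the postcondition
  sim <- simulate_dataset(sim_spec(120, 200,
    ld_blocks = data.frame(size = c(25, 25, 25), r2 = c(0.9, 0.8, 0.95)),
    seed = 14))
  pr <- indep_pairwise(sim$dataset, 50, 5, 0.5)
  expect_gt(length(pr$prune), 0)
  keep <- pr$keep_idx
  for (s in seq(1, length(keep), by = 5)) {
    win <- keep[s:min(s + 49, length(keep))]
    # exhaustive within-window scan over survivors
    for (a in seq_along(win)) for (b in seq_len(a - 1)) {
      st <- pair_r(sim$dataset, c(win[b], win[a]))
      if (st$valid) expect_lte(st$r^2, 0.5)
    }
  }
})

test_that("diplotype MLE solves the Hill cubic to EM accuracy", {
  # zero double-hets: haplotypes countable directly
  nij <- matrix(0, 3, 3)
  nij[3, 3] <- 10; nij[1, 1] <- 10; nij[3, 1] <- 5; nij[2, 3] <- 4
  m <- diplotype_mle(nij)
  c11 <- 2 * nij[3, 3] + nij[3, 2] + nij[2, 3]
  expect_equal(m$p11, c11 / (2 * sum(nij)), tolerance = 1e-9)
  # complete coupling -> |D'| = 1
  cp <- matrix(0, 3, 3); cp[1, 1] <- 12; cp[3, 3] <- 8
  expect_equal(diplotype_mle(cp)$dprime_abs, 1)
  set.seed(502)
  for (rep in 1:80) {
    nij <- matrix(stats::rpois(9, sample(2:12, 1)), 3, 3)
    m <- diplotype_mle(nij)
    if (!isTRUE(m$valid)) next
    pe <- em_p11(nij)
    lle <- popgenkit:::diplotype_loglik(nij, m$pA, m$pB, pe)
    expect_gte(m$log_likelihood, lle - 1e-10)
  }
})

test_that("D' confidence intervals behave at the boundaries", {
  # perfect LD, large n: upper bound pinned at 1, strong LD
  cp <- matrix(0, 3, 3); cp[1, 1] <- 60; cp[3, 3] <- 40; cp[2, 2] <- 30
  ci <- dprime_ci(cp)
  expect_equal(ci$ci_high, 1)
  expect_equal(ci$classification, "strong_LD")
  # independent variants with many samples: recombination
  set.seed(503)
  x <- random_genotypes(800, miss = 0)
  y <- random_genotypes(800, miss = 0)
  ci2 <- dprime_ci(diplotype_counts(x, y))
  expect_lt(ci2$ci_high, 0.9)
  expect_equal(ci2$classification, "recombination")
  expect_true(ci2$ci_low <= ci2$ci_high)
})

test_that("fast classification equals the full grid everywhere", {
  set.seed(504)
  # dense sweep of small tables plus larger random tables
  small_mismatch <- 0
  for (rep in 1:400) {
    tot <- sample(4:30, 1)
    nij <- matrix(as.integer(stats::rmultinom(1, tot, runif(9))), 3, 3)
    cf <- classify_pair_fast(nij)
    r <- dprime_ci(nij)
    cs <- if (isTRUE(r$valid)) r$classification else "undefined"
    if (!identical(cf, cs)) small_mismatch <- small_mismatch + 1
  }
  expect_equal(small_mismatch, 0)
  for (rep in 1:300) {
    nij <- matrix(as.integer(stats::rmultinom(1, sample(50:2000, 1),
                                              runif(9))), 3, 3)
    cf <- classify_pair_fast(nij)
    r <- dprime_ci(nij)
    cs <- if (isTRUE(r$valid)) r$classification else "undefined"
    expect_identical(cf, cs)
  }
})

test_that("gabriel_blocks recovers constructed blocks and matches the reference", {
  sim <- simulate_dataset(sim_spec(300, 25,
    ld_blocks = data.frame(size = c(10, 10), r2 = c(0.95, 0.95)), seed = 21))
  bl <- gabriel_blocks(sim$dataset, max_span_kb = 200)
  expect_equal(nrow(bl), 2)
  expect_equal(bl$first, c(1, 11))
  expect_equal(bl$last, c(10, 20))
  # all variants mutually inconclusive/recombinant -> no blocks
  null_ds <- random_dataset(200, 12, missing_rate = 0, seed = 22)
  bl0 <- gabriel_blocks(null_ds, max_span_kb = 10000)
  expect_equal(nrow(bl0), 0)
  # streaming/fast path vs full-grid brute-force reference
  sim2 <- simulate_dataset(sim_spec(250, 40,
    ld_blocks = data.frame(size = c(8, 12, 6), r2 = c(0.9, 0.85, 0.95)),
    missing_rate = 0.02, seed = 23))
  bl2 <- gabriel_blocks(sim2$dataset, max_span_kb = 500)
  ref <- reference_gabriel(sim2$dataset, max_span_kb = 500)
  expect_equal(bl2$first, ref$first)
  expect_equal(bl2$last, ref$last)
  # early-skip and fast-classification toggles change nothing
  bl3 <- gabriel_blocks(sim2$dataset, max_span_kb = 500,
                        skip_bound = FALSE, use_fast = FALSE)
  expect_identical(bl2, bl3)
  # unsorted input is rejected
  dsu <- sim2$dataset
  dsu$variants$bp <- rev(dsu$variants$bp)
  expect_error(gabriel_blocks(dsu), "sorted")
})
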