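test_that("case codes match a per-marker scalar classifier", {
  # constant pairs give 20 copies of the matching case code
  r <- encode_case_codes(rep(2L, 20), rep(2L, 20)) # hom-major/hom-major
  expect_equal(r$codes, rep(6L, 20))
  r <- encode_case_codes(rep(0L, 20), rep(0L, 20)) # hom-minor/hom-minor
  expect_equal(r$codes, rep(0L, 20))
  # any missing call dominates
  r <- encode_case_codes(c(NA, 1L), c(0L, NA))
  expect_equal(r$codes, c(7L, 7L))
  # scalar classifier: case by unordered dosage pair
  classify1 <- function(x, y) {
    if (is.na(x) || is.na(y)) return(7L)
    key <- paste(sort(c(x, y)), collapse = "")
    c("00" = 0L, "01" = 2L, "02" = 3L, "11" = 4L, "12" = 5L, "22" = 6L)[[key]]
  }
  set.seed(401)
  for (rep in 1:25) {
    gx <- random_genotypes(20); gy <- random_genotypes(20)
    r <- encode_case_codes(gx, gy)
    expect_equal(r$codes, vapply(1:20, function(i)
      classify1(gx[i], gy[i]), integer(1)))
  }
})

test_that("partial-sum tables equal sums of single-case increments", {
  expect_equal(grm_partial_sum_table(rep(0.5, 5))[
    encode_case_codes(rep(1L, 5), rep(1L, 5))$indices[1] + 1], 0) # 1-2q = 0
  # all-missing index -> 0
  idx_missing <- sum(7 * 8^(0:4))
  set.seed(402)
  for (rep in 1:20) {
    q5 <- runif(5, 0.05, 0.95)
    tbl <- grm_partial_sum_table(q5)
    expect_equal(tbl[idx_missing + 1], 0)
    idx <- sample(0:(8^5 - 1), 40)
    for (ix in idx) {
      codes <- (ix %/% 8^(0:4)) %% 8
      direct <- sum(vapply(1:5, function(s)
        grm_case_increments(q5[s])[codes[s] + 1], numeric(1)))
      expect_equal(unname(tbl[ix + 1]), unname(direct), tolerance = 1e-12)
    }
  }
  expect_error(grm_partial_sum_table(c(0.5, 0)), "monomorphic")
})

test_that("single-marker increments match the printed formula", {
  # q = 0.5, both hom-major: (2-1)(2-1)/0.5 = 2; dosage a1 = 2 for hom a1
  inc <- grm_case_increments(0.5)
  expect_equal(unname(inc["hom1_hom1"]), 2)
  expect_equal(unname(inc["het_het"]), 0)
  q <- 0.3
  inc <- grm_case_increments(q)
  expect_equal(unname(inc["hom1_hom2"]),
               (2 - 2 * q) * (0 - 2 * q) / (2 * q * (1 - q)))
  expect_equal(unname(inc["missing"]), 0)
})

test_that("grm matches the direct per-genotype computation", {
  sim <- simulate_dataset(sim_spec(50, 200, missing_rate = 0.05, seed = 42))
  ds <- sim$dataset
  gr <- grm(ds)
  ref <- naive_grm(ds)
  expect_lt(max(abs(gr$values - ref$values) /
                  pmax(abs(ref$values), 1e-8)), 1e-12)
  expect_equal(unname(gr$denominators), unname(ref$denominators))
  expect_equal(gr$values, t(gr$values)) # symmetry
  # duplicate-sample property: A_ij = A_ii = A_jj when rows identical
  G <- unpack_genotypes(ds)[, 1:50]
  G[2, ] <- G[1, ]
  G[is.na(G)] <- 1L
  dsd <- new_dataset(G)
  frd <- allele_frequencies(dsd)
  poly <- which(frd$a1_freq > 0 & frd$a1_freq < 1)
  grd <- grm(subset_variants(dsd, poly))
  expect_equal(grd$values[1, 2], grd$values[1, 1])
  expect_equal(grd$values[1, 2], grd$values[2, 2])
})

test_that("partial-sum lookup and 20-lookup paths are bitwise identical", {
  ds <- random_dataset(30, 95, missing_rate = 0.08, seed = 5)
  expect_identical(grm(ds)$values, grm(ds, lookup = FALSE)$values)
})

test_that("row chunks concatenate exactly to the full matrix", {
  ds <- random_dataset(41, 60, missing_rate = 0.03, seed = 6)
  full_g <- grm(ds)$values
  full_i <- ibs_matrix(ds)$ibs
  for (K in c(2, 3, 7)) {
    parts_g <- do.call(rbind, lapply(1:K, function(k)
      grm(ds, row_chunk = c(k, K))$values))
    parts_i <- do.call(rbind, lapply(1:K, function(k)
      ibs_matrix(ds, row_chunk = c(k, K))$ibs))
    expect_identical(unname(parts_g), unname(full_g))
    expect_identical(unname(parts_i), unname(full_i))
  }
})

test_that("ibs_matrix agrees with the scalar loop and handles edge cases", {
  ds <- random_dataset(19, 37, missing_rate = 0.1, seed = 8)
  im <- ibs_matrix(ds)
  G <- unpack_genotypes(ds)
  for (pair in list(c(1, 2), c(3, 17), c(19, 19), c(5, 11))) {
    ref <- naive_ibs(G[pair[1], ], G[pair[2], ])
    expect_equal(im$ibs[pair[1], pair[2]], ref$ibs)
  }
  expect_true(all(diag(im$ibs) == 1))
  # identical duplicates -> off-diagonal exactly 1; opposite homs -> 0
  G2 <- rbind(rep(0L, 10), rep(0L, 10), rep(2L, 10))
  im2 <- ibs_matrix(new_dataset(G2))$ibs
  expect_equal(im2[1, 2], 1)
  expect_equal(im2[1, 3], 0)
})

test_that("grm of simulated unrelateds is centred correctly", {
  sim <- simulate_dataset(sim_spec(60, 2000, seed = 77))
  # true-frequency centring: off-diagonals are unbiased around 0
  gv <- grm(sim$dataset, q = sim$truth$maf)$values
  offd <- gv[upper.tri(gv)]
  diagv <- diag(gv)
  expect_lt(abs(mean(offd) - 0), 4 * sd(offd) / sqrt(length(offd)) + 1e-3)
  expect_lt(abs(mean(diagv) - 1), 4 * sd(diagv) / sqrt(length(diagv)) + 5e-3)
  # sample-frequency centring obeys the exact sum-to-zero identity:
  # with no missingness every row of the increment matrix sums to 0
  fr <- allele_frequencies(sim$dataset)
  gs <- grm(sim$dataset)
  rowsum0 <- rowSums(gs$values * gs$denominators)
  expect_lt(max(abs(rowsum0)) / ncol(gs$values), 1e-8)
})

test_that("complete linkage reproduces naive and hclust hierarchies", {
  # hand-checkable instance
  d <- matrix(c(0, 1, 5, 1, 0, 4, 5, 4, 0), 3, 3)
  hc <- complete_linkage(d)
  expect_equal(hc$height, c(1, 5))
  expect_equal(hc$merge[1, ], c(-1, -2))
  # equal distances: all heights equal
  d4 <- matrix(1, 4, 4); diag(d4) <- 0
  expect_equal(complete_linkage(d4)$height, rep(1, 3))
  set.seed(403)
  for (rep in 1:10) {
    n <- sample(8:40, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    d <- as.matrix(dist(X))
    hc <- complete_linkage(d)
    expect_true(all(diff(hc$height) >= -1e-12))
    expect_equal(sort(hc$height), sort(naive_complete_heights(d)))
    ref <- stats::hclust(as.dist(d), method = "complete")
    expect_lt(max(abs(as.matrix(stats::cophenetic(hc)) -
                        as.matrix(stats::cophenetic(ref)))), 1e-9)
  }
  expect_error(complete_linkage(matrix(c(0, NA, NA, 0), 2, 2)), "finite")
})
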