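test_that("the heterozygote likelihood ratio matches its factorial form", {
  expect_equal(hwe_ratio(2, 10, 190), (8 * 188) / (3 * 4))
  expect_equal(hwe_ratio(10, 10, 190), 0) # k = n1 -> zero numerator
  # exact rational check against the factorial-form likelihood ratio
  lik <- function(k, n1, n2) {
    n <- (n1 + n2) / 2
    exp(k * log(2) + lgamma(n + 1) - lgamma((n1 - k) / 2 + 1) -
          lgamma(k + 1) - lgamma((n2 - k) / 2 + 1))
  }
  set.seed(301)
  for (rep in 1:50) {
    n1 <- sample(2:60, 1) * 2
    n2 <- sample(2:60, 1) * 2
    k <- sample(seq(0, min(n1, n2) - 2, by = 2), 1)
    expect_equal(hwe_ratio(k, n1, n2), lik(k + 2, n1, n2) / lik(k, n1, n2),
                 tolerance = 1e-10)
  }
  expect_error(hwe_ratio(3, 10, 190), "parity")
  expect_error(hwe_ratio(-2, 10, 190), "parity|valid")
})

test_that("early-termination HWE p equals full enumeration to 10+ digits", {
  # degenerate margins: single possible table
  expect_equal(hwe_exact(0, 0, 25)$p, 1)
  r <- hwe_exact(3, 5, 2)
  rf <- hwe_exact_full(3, 5, 2)
  expect_gte(matching_digits(r$p, rf$p), 10)
  set.seed(302)
  for (rep in 1:60) {
    n <- sample(10:2000, 1)
    h1 <- sample(0:n, 1)
    het <- sample(0:(n - h1), 1)
    r <- hwe_exact(h1, het, n - h1 - het)
    rf <- hwe_exact_full(h1, het, n - h1 - het)
    expect_gte(matching_digits(r$p, rf$p), 10)
    if (rf$p > 0) expect_lt(abs(r$p - rf$p) / rf$p, 1e-9)
  }
  expect_error(hwe_exact(0, 0, 0), "empty")
})

test_that("mid-p subtracts half the observed mass and stays in [0, p]", {
  set.seed(303)
  for (rep in 1:40) {
    h1 <- sample(0:30, 1); het <- sample(0:30, 1); h2 <- sample(0:30, 1)
    if (h1 + het + h2 == 0) next
    r <- hwe_exact(h1, het, h2)
    expect_equal(r$midp, r$p - r$obs_mass / 2)
    expect_gte(r$midp, 0)
    expect_lte(r$midp, r$p)
    t4 <- sample(0:25, 4, replace = TRUE)
    if (sum(t4) == 0) next
    f <- fisher_2x2(t4)
    expect_equal(f$midp, f$p - f$obs_mass / 2, tolerance = 1e-12)
    expect_lte(f$midp, f$p)
  }
})

test_that("2x2 Fisher agrees with enumeration and the FEXACT cross-check", {
  # zero margin -> single table
  expect_equal(fisher_2x2(c(0, 0, 5, 7))$p, 1)
  t <- matrix(c(1, 9, 11, 3), 2, 2, byrow = TRUE)
  expect_gte(matching_digits(fisher_2x2(t)$p, fisher_2x2_full(t)$p), 10)
  # symmetry of the hypergeometric family
  p0 <- fisher_2x2(t)$p
  expect_equal(fisher_2x2(t[2:1, ])$p, p0)
  expect_equal(fisher_2x2(t[, 2:1])$p, p0)
  expect_equal(fisher_2x2(t(t))$p, p0)
  set.seed(304)
  for (rep in 1:80) {
    t4 <- as.integer(rmultinom(1, sample(20:2000, 1), runif(4, 0.05, 1)))
    r <- fisher_2x2(t4)
    rf <- fisher_2x2_full(t4)
    expect_gte(matching_digits(r$p, rf$p), 10)
    # independent cross-check: R's FEXACT network algorithm
    ft <- stats::fisher.test(matrix(t4, 2, 2, byrow = TRUE))$p.value
    expect_equal(r$p, ft, tolerance = 1e-6)
  }
})

test_that("the 2^-53 frequency support range matches a log enumeration", {
  expect_identical(relative_likelihood_support(1000, 40000, 100000),
                   c(278L, 526L))
  # margins admitting a single table
  expect_identical(relative_likelihood_support(0, 5, 10), c(0L, 0L))
  set.seed(305)
  for (rep in 1:30) {
    N <- sample(50:500, 1)
    R1 <- sample(1:(N - 1), 1)
    C1 <- sample(1:(N - 1), 1)
    got <- relative_likelihood_support(R1, C1, N)
    # direct log-space enumeration with lchoose
    x <- max(0, R1 + C1 - N):min(R1, C1)
    ll <- lchoose(C1, x) + lchoose(N - C1, R1 - x)
    lf <- ll - max(ll) - log(sum(exp(ll - max(ll))))
    expect_identical(got, c(min(x[lf >= -53 * log(2)]),
                            max(x[lf >= -53 * log(2)])))
  }
  expect_error(relative_likelihood_support(10, 5, 8), "impossible")
})

test_that("2x3 Fisher matches exhaustive enumeration and reduces cleanly", {
  # all-zero column reduces to the 2x2 test
  t23 <- rbind(c(3, 0, 7), c(5, 0, 2))
  expect_equal(fisher_2x3(t23)$p, fisher_2x2(t23[, c(1, 3)])$p)
  # zero row margin: single table
  expect_equal(fisher_2x3(rbind(c(0, 0, 0), c(1, 2, 3)))$p, 1)
  t <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_gte(matching_digits(fisher_2x3(t)$p, fisher_2x3_full(t)$p), 10)
  set.seed(306)
  for (rep in 1:40) {
    t6 <- matrix(as.integer(rmultinom(1, sample(15:800, 1),
                                      runif(6, 0.05, 1))), 2, 3)
    r <- fisher_2x3(t6)
    rf <- fisher_2x3_full(t6)
    expect_gte(matching_digits(r$p, rf$p), 10)
    expect_equal(r$midp, r$p - r$obs_mass / 2, tolerance = 1e-12)
  }
})

test_that("early termination visits O(sqrt(n)) terms", {
  visits <- vapply(c(1e2, 1e4, 1e6), function(n) {
    n1 <- round(0.3 * 2 * n)
    if (n1 %% 2 == 1) n1 <- n1 + 1
    het <- round(n1 * (2 * n - n1) / (2 * n))
    het <- het - (het - n1 %% 2) %% 2
    hwe_exact((n1 - het) / 2, het, n - (n1 + het) / 2)$n_terms
  }, numeric(1))
  slope <- coef(lm(log(visits) ~ log(c(1e2, 1e4, 1e6))))[2]
  expect_gt(slope, 0.35)
  expect_lt(slope, 0.65)
  # and far fewer terms than the full family size
  expect_lt(visits[3], 1e4)
})

test_that("the HWE test is conservative on equilibrium fixtures", {
  sim <- simulate_dataset(sim_spec(150, 1500, seed = 99))
  cnt <- popgenkit:::.genotype_count_matrix_cpp(
    sim$dataset$genotypes$data, 150L, 1500L)
  p <- vapply(seq_len(1500), function(j)
    hwe_exact(cnt[1, j], cnt[2, j], cnt[3, j])$p, numeric(1))
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 1500)
  expect_lte(rate, 0.05 + 3 * se)
})
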