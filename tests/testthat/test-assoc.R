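test_that("allelic count tables match a scalar counting loop", {
  # het case + hom-a1 control -> [[1,1],[2,0]]
  tab <- allelic_counts(c(1L, 0L), c(1, 0))
  expect_equal(unname(tab), matrix(c(1, 1, 2, 0), 2, 2, byrow = TRUE))
  # all cases -> control row zero
  tab <- allelic_counts(c(0L, 1L, 2L), c(1, 1, 1))
  expect_equal(unname(tab["control", ]), c(0, 0))
  set.seed(601)
  ds <- random_dataset(80, 20, missing_rate = 0.1, seed = 31)
  st <- sample(c(0L, 1L, NA), 80, replace = TRUE)
  ac <- allelic_counts(ds, st)
  G <- unpack_genotypes(ds)
  for (j in sample(20, 8)) {
    x <- G[, j]
    ok <- !is.na(x) & !is.na(st)
    a1 <- 2 - x
    expect_equal(unname(ac[, j]),
                 c(sum(a1[ok & st == 1]), sum((2 - a1)[ok & st == 1]),
                   sum(a1[ok & st == 0]), sum((2 - a1)[ok & st == 0])))
  }
})

test_that("the trend statistic matches the textbook formula and is symmetric", {
  t23 <- rbind(c(10, 20, 30), c(30, 20, 10))
  mine <- trend_statistic(t23)
  # suppressed: prop.trend.test warns about its internal anova on this
  # perfectly balanced table
  ref <- suppressWarnings(
    stats::prop.trend.test(t23[1, ], colSums(t23), score = 0:2))
  expect_equal(mine, unname(ref$statistic), tolerance = 1e-12)
  # label swap and weight reversal invariance
  expect_equal(trend_statistic(t23[2:1, ]), mine)
  expect_equal(trend_statistic(t23[, 3:1]), mine)
  # identical distributions -> 0; degenerate margins -> NA
  expect_equal(trend_statistic(rbind(c(5, 6, 7), c(5, 6, 7))), 0)
  expect_true(is.na(trend_statistic(rbind(c(0, 0, 0), c(1, 2, 3)))))
  expect_true(is.na(trend_statistic(rbind(c(3, 0, 0), c(4, 0, 0)))))
})

test_that("max(T) reports are deterministic and internally consistent", {
  sim <- simulate_dataset(sim_spec(120, 25, case_fraction = 0.5, seed = 32))
  ds <- sim$dataset
  for (tst in c("trend", "allelic", "fisher")) {
    r1 <- max_t(ds, test = tst, R = 300, seed = 9)
    r2 <- max_t(ds, test = tst, R = 300, seed = 9)
    expect_identical(r1$table, r2$table)
    expect_true(all(r1$table$emp_corrected >= r1$table$emp_pointwise))
    expect_true(all(r1$table$emp_pointwise >= 1 / 301))
    expect_true(all(r1$table$emp_corrected <= 1))
  }
  r3 <- max_t(ds, test = "trend", R = 300, seed = 10)
  expect_false(identical(r1$table$emp_pointwise, r3$table$emp_pointwise))
  expect_error(max_t(ds, phenotype = rep(1, 120)), "constant")
})

test_that("single-variant max(T) has corrected p equal to pointwise p", {
  sim <- simulate_dataset(sim_spec(100, 1, case_fraction = 0.4, seed = 33))
  r <- max_t(sim$dataset, test = "trend", R = 500, seed = 3)
  expect_equal(r$table$emp_corrected, r$table$emp_pointwise)
})

test_that("sampled permutation p converges to the exhaustive enumeration", {
  # 6 phenotyped samples, 3 cases: 20 distinct case assignments
  g <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L,
                2L, 1L, 0L, 2L, 0L, 1L,
                1L, 1L, 1L, 0L, 0L, 2L), 6, 3)
  ds <- new_dataset(g)
  status <- c(1, 1, 1, 0, 0, 0)
  r <- max_t(ds, phenotype = status, test = "trend", R = 20000, seed = 4)
  combs <- utils::combn(6, 3)
  stat_for <- function(caseix, j) {
    st <- rep(0, 6); st[caseix] <- 1
    t23 <- rbind(table(factor(g[st == 1, j], levels = 0:2)),
                 table(factor(g[st == 0, j], levels = 0:2)))
    s <- trend_statistic(t23)
    if (is.na(s)) 0 else s
  }
  for (j in 1:3) {
    obs <- stat_for(1:3, j)
    exact <- mean(apply(combs, 2, function(ci) stat_for(ci, j)) >= obs - 1e-9)
    tol <- 4 * sqrt(exact * (1 - exact) / 20000) + 2e-3
    expect_lt(abs(r$table$emp_pointwise[j] - exact), tol)
  }
})

test_that("a planted association is detected with corrected significance", {
  hits <- 0
  for (seed in 1:5) {
    sim <- simulate_dataset(sim_spec(400, 20, case_fraction = 0.5,
      effects = data.frame(variant = 7, or = 2.5), seed = 100 + seed))
    r <- max_t(sim$dataset, test = "trend", R = 2000, seed = seed)
    if (r$table$emp_corrected[7] <= 0.01) hits <- hits + 1
  }
  expect_gte(hits, 4) # power > 0.9 at this effect size
})
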