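test_that("separated tiny samples give the exact enumerated p-value", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(mw$u, 0)
  expect_equal(mw$p_value, 0.1)  # 2 of the 20 rank arrangements
  expect_identical(mw$method, "exact")
})

test_that("identical samples give central U and p near 1", {
  x <- c(2, 5, 9, 11)
  mw <- mann_whitney_u(x, x)
  expect_equal(mw$u, length(x)^2 / 2)
  expect_gte(mw$p_value, 0.9)
})

test_that("U and p are invariant under strictly monotone transforms", {
  set.seed(1)
  x <- rnorm(15)
  y <- rnorm(18, 0.6)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(exp(x), exp(y))
  expect_identical(a$u, b$u)
  expect_identical(a$p_value, b$p_value)
})

test_that("swapping groups mirrors U and keeps p", {
  set.seed(2)
  x <- rpois(12, 6)
  y <- rpois(9, 8)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(y, x)
  expect_equal(a$u + b$u, length(x) * length(y))
  expect_equal(a$p_value, b$p_value)
})

test_that("fully tied data return p = 1 with a degenerate flag", {
  mw <- mann_whitney_u(rep(3, 5), rep(3, 7))
  expect_true(mw$degenerate)
  expect_identical(mw$p_value, 1)
})

test_that("exact enumeration matches base R and the normal approximation", {
  set.seed(3)
  for (n in 8:12) {
    x <- rnorm(n)
    y <- rnorm(n, 0.4)
    exact <- mann_whitney_u(x, y, exact_limit = 2 * n)
    approx <- mann_whitney_u(x, y, exact_limit = 0)
    expect_identical(exact$method, "exact")
    expect_identical(approx$method, "normal_approx")
    expect_lt(abs(exact$p_value - approx$p_value), 0.01)
    # independent oracle: base R's rank-sum test
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = TRUE)
    expect_equal(exact$u, unname(ref$statistic))
    expect_equal(exact$p_value, ref$p.value, tolerance = 1e-12)
  }
  # tie-corrected approximation against base R on tied data
  set.seed(4)
  x <- sample(1:6, 40, replace = TRUE)
  y <- sample(2:7, 35, replace = TRUE)
  mine <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("compare_groups reports group stats, U, and exact tier mapping", {
  set.seed(5)
  tb <- tibble::tibble(
    par_strong = c(rnorm(80), rnorm(90, 2)),
    par_null = rnorm(170),
    genotype = rep(c("MUT", "WT"), c(80, 90)))
  cmp <- compare_groups(tb, genotype = "genotype")
  expect_identical(nrow(cmp), 2L)
  strong <- cmp[cmp$parameter == "par_strong", ]
  expect_identical(strong$tier, "***")
  expect_identical(strong$n_MUT, 80L)
  expect_lt(abs(strong$mean_WT - 2), 0.5)
  # tier thresholds are exact
  expect_identical(significance_tier(c(0.5, 0.009, 0.0009, 0.00009)),
                   c("ns", "*", "**", "***"))
  expect_identical(significance_tier(c(0.01, 0.001, 0.0001)),
                   c("ns", "*", "**"))
})

test_that("an empty group is an error naming the parameter", {
  tb <- tibble::tibble(p1 = c(1, 2, NA, NA),
                       genotype = c("MUT", "MUT", "WT", "WT"))
  expect_error(compare_groups(tb, genotype = "genotype"), "p1")
})

test_that("null p-values are calibrated", {
  # p-values from rank tests are discrete, so check empirical rejection
  # rates at fixed thresholds rather than a continuous-uniformity test
  set.seed(6)
  ps <- vapply(1:200, function(i)
    mann_whitney_u(rnorm(30), rnorm(30))$p_value, 0)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.06)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.1)
})
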