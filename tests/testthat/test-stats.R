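test_that("group summaries match a brute-force recomputation", {
  s <- group_summary(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$sd, 1)
  expect_equal(s$median, 2); expect_equal(c(s$min, s$max), c(1, 3))
  one <- group_summary(7.5)
  expect_equal(one$mean, 7.5); expect_equal(one$sd, 0)
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(sample(2:40, 1))
    s <- group_summary(x)
    n <- length(x)
    expect_equal(s$mean, sum(x) / n, tolerance = 1e-12)
    expect_equal(s$sd, sqrt(sum((x - sum(x) / n)^2) / (n - 1)),
                 tolerance = 1e-12)
    xs <- sort(x)
    med <- if (n %% 2) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
    expect_equal(s$median, med, tolerance = 1e-12)
    expect_equal(unclass(group_summary(sample(x))), unclass(s),
                 tolerance = 1e-12)
  }
  expect_error(group_summary(numeric(0)), "empty")
})

test_that("percent difference uses the truncation display convention", {
  expect_equal(percent_difference(3.1, 1.87), 100 * (3.1 - 1.87) / 1.87)
  expect_equal(percent_difference(3.1, 1.87, display = TRUE), 65)
  expect_equal(percent_difference(3.23, 1.45, display = TRUE), 122)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(1, -2, display = TRUE), -150)
  expect_error(percent_difference(1, 0), "nonzero")
})

test_that("normality screen separates normal from exponential samples", {
  pass <- 0
  for (s in 1:100) {
    set.seed(s)
    if (normality_test(rnorm(200))$p_value > 0.05) pass <- pass + 1
  }
  expect_gte(pass, 90)
  reject <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    if (normality_test(rexp(500))$p_value < 0.05) reject <- reject + 1
  }
  expect_gte(reject, 95)
  set.seed(2)
  d <- normality_test(rnorm(50))$statistic
  expect_gte(d, 0); expect_lte(d, 1)
  expect_error(normality_test(rep(3, 10)), "identical")
  expect_error(normality_test(c(1, 2, 3)), "at least 4")
})

test_that("t branch is symmetric and null on identical samples", {
  x <- c(1.2, 2.5, 3.1, 4.8, 2.2)
  r <- compare_groups(x, x, "normal")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(8)
  y <- rnorm(12, 1)
  a <- compare_groups(x, y, "normal")
  b <- compare_groups(y, x, "normal")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
})

test_that("small-sample Mann-Whitney equals exact enumeration", {
  set.seed(31)
  for (i in 1:8) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- round(rnorm(n1, sd = 2), 2)
    y <- round(rnorm(n2, mean = i %% 3, sd = 2), 2)
    if (anyDuplicated(c(x, y))) next
    got <- compare_groups(x, y, "nonnormal")
    expect_match(got$note, "exact")
    expect_equal(got$p_value, mw_enum_p(x, y), tolerance = 1e-12)
  }
  # swap symmetry of the two-sided p (approximate branch, with ties)
  set.seed(32)
  x <- sample(1:10, 20, replace = TRUE)
  y <- sample(3:12, 25, replace = TRUE)
  expect_equal(compare_groups(x, y, "nonnormal")$p_value,
               compare_groups(y, x, "nonnormal")$p_value, tolerance = 1e-12)
})

test_that("simple OLS reports R-squared consistent with Pearson correlation", {
  x <- 1:10
  exact <- suppressWarnings(linreg_r2(x, 3 + 2 * x))  # perfect-fit warning
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)
  set.seed(44)
  x <- rnorm(200); y <- 1 + 0.5 * x + rnorm(200)
  r <- linreg_r2(x, y)
  expect_equal(r$r_squared, cor(x, y)^2, tolerance = 1e-12)
  perm <- linreg_r2(x, sample(y))
  expect_lt(perm$r_squared, 0.05)
  expect_error(linreg_r2(rep(1, 10), rnorm(10)), "constant")
})

test_that("noncentral-t power matches a Monte-Carlo oracle", {
  expect_equal(power_two_sample_t(0, 38, 36), 0.05, tolerance = 1e-12)
  p <- vapply(c(0.2, 0.5, 0.8, 1.2), power_two_sample_t, numeric(1),
              n1 = 38, n2 = 36)
  expect_true(all(diff(p) > 0))
  expect_gt(power_two_sample_t(0.66, 76, 72), power_two_sample_t(0.66, 38, 36))
  # 1e5 simulated pooled t-tests at d = 0.66
  set.seed(424242)
  n1 <- 38; n2 <- 36; d <- 0.66; B <- 1e5
  x <- matrix(rnorm(n1 * B), n1); y <- matrix(rnorm(n2 * B, mean = d), n2)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colSums((x - rep(m1, each = n1))^2)
  v2 <- colSums((y - rep(m2, each = n2))^2)
  sp <- sqrt((v1 + v2) / (n1 + n2 - 2))
  tt <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  mc <- mean(abs(tt) > qt(0.975, n1 + n2 - 2))
  expect_equal(power_two_sample_t(d, n1, n2), mc, tolerance = 0.01)
})
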