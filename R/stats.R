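# Statistical battery ---------------------------------------------------------

#' Summary statistics for one variable in one group
#'
#' Sample mean, SD (n-1 denominator), median (mean of the middle two for even
#' n), min and max — the "mean +/- SD (median, min-max)" presentation.
#'
#' @param values non-empty numeric vector.
#' @return list of class `"group_summary"`: `n, mean, sd, median, min, max`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0) stop("empty input")
  stopifnot(is.numeric(values), !anyNA(values))
  structure(list(n = length(values), mean = mean(values),
                 sd = if (length(values) > 1) sd(values) else 0,
                 median = median(values), min = min(values),
                 max = max(values)),
            class = "group_summary")
}

#' @export
format.group_summary <- function(x, digits = 2, ...) {
  sprintf("%.*f +/- %.*f (%.*f, %.*f-%.*f)", digits, x$mean, digits, x$sd,
          digits, x$median, digits, x$min, digits, x$max)
}

#' @export
print.group_summary <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Percent difference between two group means
#'
#' `100 * (a - b) / b`. The display convention truncates toward zero to an
#' integer (65.77 prints as 65, 122.75 as 122).
#'
#' @param a,b numeric scalars; `b` must be nonzero.
#' @param display return the truncated-integer display value.
#' @return percent difference.
#' @export
percent_difference <- function(a, b, display = FALSE) {
  if (b == 0) stop("reference value b must be nonzero")
  p <- 100 * (a - b) / b
  if (display) trunc(p) else p
}

#' Normality screen
#'
#' Estimated-parameter Kolmogorov-Smirnov (Lilliefors) test by default —
#' what applied "KS normality" screens virtually always mean — via
#' `nortest::lillie.test()`. The naive fully-specified KS against
#' N(mean(x), sd(x)) is available with `method = "ks"` (its p-values are
#' conservative when parameters are estimated).
#'
#' @param values numeric vector, n >= 4, not all identical.
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @return list of class `"test_result"`: `test`, `statistic`, `p_value`,
#'   `note`.
#' @export
normality_test <- function(values, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  if (length(values) < 4) stop("need at least 4 observations")
  if (sd(values) == 0) stop("all values identical; normality undefined")
  if (method == "lilliefors") {
    t <- nortest::lillie.test(values)
    test_result("Lilliefors (KS, estimated parameters)",
                unname(t$statistic), t$p.value,
                "D against normal with estimated mean/SD")
  } else {
    t <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
    test_result("Kolmogorov-Smirnov (estimated parameters plugged in)",
                unname(t$statistic), t$p.value,
                "naive plug-in variant; p conservative")
  }
}

test_result <- function(test, statistic, p_value, note = "") {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 note = note), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n  %s\n",
              x$test, x$statistic, x$p_value, x$note))
  invisible(x)
}

#' Two-group comparison
#'
#' `distributional = "normal"` runs the pooled-variance (Student) two-sample
#' t-test; `"nonnormal"` runs the Mann-Whitney U (Wilcoxon rank-sum) test —
#' exact when both groups have at most 8 observations and no ties, otherwise
#' the normal approximation with continuity and tie correction. Two-sided.
#'
#' @param x,y numeric vectors, each with n >= 2.
#' @param distributional `"normal"` or `"nonnormal"`.
#' @return a `"test_result"`; for the t branch `statistic` is t, for the
#'   Mann-Whitney branch it is U (the `wilcox.test` W for `x` vs `y`).
#' @export
compare_groups <- function(x, y, distributional = c("nonnormal", "normal")) {
  distributional <- match.arg(distributional)
  if (length(x) < 2 || length(y) < 2) stop("both groups need n >= 2")
  if (distributional == "normal") {
    t <- t.test(x, y, var.equal = TRUE)
    test_result("two-sample t (pooled variance)", unname(t$statistic),
                t$p.value, "chosen because both groups passed normality")
  } else {
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    t <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    test_result("Mann-Whitney U", unname(t$statistic), t$p.value,
                if (exact) "exact enumeration (small n, no ties)"
                else "normal approximation with continuity and tie correction")
  }
}

#' Simple linear regression with R-squared
#'
#' Ordinary least squares of `y` on `x`; `R^2 = 1 - SSres/SStot`; p-value
#' from the slope's t-test.
#'
#' @param x,y numeric vectors, n >= 3; `x` must not be constant.
#' @return list `slope, intercept, r_squared, p_value, n`.
#' @export
linreg_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0) stop("x is constant; regression undefined")
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2, 4]), n = length(x))
}

#' Power of the two-sided two-sample t-test
#'
#' Analytic power via the noncentral t distribution with noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom
#' (allows unequal group sizes, unlike `power.t.test`).
#'
#' @param d Cohen's d (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided significance level.
#' @return power in `[alpha, 1]`.
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(d >= 0, n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}
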