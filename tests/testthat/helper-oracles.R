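# Independent oracles used across the suite.

# Closed-form moments of the truncated normal on [lo, hi].
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
# U counts pairs (x_i, y_j) with x_i > y_j (+1/2 for ties).
mw_enum_p <- function(x, y) {
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) +
    0.5 * sum(outer(xx, yy, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- u_stat(x, y)
  centre <- n1 * length(y) / 2
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
}

# Trapezoidal mean of a dose profile over an organ extent.
trapz_mean_dose <- function(profile_fun, extent, n = 1e4) {
  z <- seq(extent[1], extent[2], length.out = n)
  d <- profile_fun(z)
  sum((d[-1] + d[-n]) / 2 * diff(z)) / (extent[2] - extent[1])
}

# Standard processed cohort for reuse in tests.
processed_cohort <- function(seed = 1, spec = default_cohort_spec()) {
  add_lar(add_organ_doses(fill_dose_indices(generate_cohort(spec, seed = seed))))
}
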