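rt <- load_risk_table()

test_that("risk-table fixture satisfies its structural invariants", {
  for (sx in c("male", "female")) {
    expect_true(all(rt[[sx]]$value >= 0))
    expect_true(all(diff(rt[[sx]]$value) <= 0))
  }
  expect_true(all(rt$female$value >= rt$male$value))
  # tampered tables are rejected by the loader
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- do.call(rbind, lapply(names(rt), function(sx)
    data.frame(sex = sx, age_at_exposure = rt[[sx]]$age,
               lar_per_100k_per_0.1Gy = rt[[sx]]$value)))
  bad$lar_per_100k_per_0.1Gy[bad$sex == "male" & bad$age_at_exposure == 40] <- 99
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_risk_table(path), "non-increasing")
})

test_that("interpolation is exact at knots, linear between, clamped outside", {
  for (sx in c("male", "female"))
    expect_equal(interp_coefficient(rt, sx, rt[[sx]]$age), rt[[sx]]$value)
  expect_equal(interp_coefficient(rt, "female", 25),
               (interp_coefficient(rt, "female", 20) +
                interp_coefficient(rt, "female", 30)) / 2)
  expect_equal(interp_coefficient(rt, "male", 95),
               rt$male$value[rt$male$age == 80])
  # brute-force two-knot bracketing oracle
  set.seed(17)
  ages <- runif(1e4, 0, 100)
  for (sx in c("male", "female")) {
    knots <- rt[[sx]]$age; vals <- rt[[sx]]$value
    oracle <- vapply(ages, function(a) {
      if (a <= knots[1]) return(vals[1])
      if (a >= knots[length(knots)]) return(vals[length(vals)])
      i <- max(which(knots <= a))
      vals[i] + (vals[i + 1] - vals[i]) * (a - knots[i]) /
        (knots[i + 1] - knots[i])
    }, numeric(1))
    expect_equal(interp_coefficient(rt, sx, ages), oracle, tolerance = 1e-12)
  }
})

test_that("table backend is linear-no-threshold in dose", {
  expect_equal(lar_point(rt, 0, 35, "female"), 0)
  # a 100 mGy (0.1 Gy) dose at a knot age returns the knot value itself
  expect_equal(lar_point(rt, 100, 30, "male"), 9)
  set.seed(5)
  d <- runif(20, 0, 50); a <- runif(20, 18, 79)
  expect_equal(lar_point(rt, 2 * d, a, "female"),
               2 * lar_point(rt, d, a, "female"), tolerance = 1e-12)
  expect_error(lar_point(rt, -1, 30, "male"), "non-negative")
})

test_that("lifetable backend reduces to the closed-form sum in flat cases", {
  # cap at 30 so e* = 0 at the late exposure ages used here
  err0 <- err_model(latency = 0, a_max = 100, e_star_cap = 30)
  flat_lt <- data.frame(age = 0:100, survival = 1)
  lam <- function(a) rep(2e-5, length(a))
  k <- 6
  got <- lar_lifetable(err0, flat_lt, dose_Gy = 0.003, age = 100 - k,
                       sex = "female", baseline = lam)
  expect_equal(got, (k + 1) * 1.05 * 0.003 * 2e-5 * 1e5, tolerance = 1e-12)
  # linear in the baseline rate
  rect_lt <- data.frame(age = 0:100, survival = as.numeric(0:100 < 80))
  half <- function(a) lam(a) / 2
  e <- 40
  expect_equal(lar_lifetable(err0, rect_lt, 0.003, e, "male", baseline = half),
               lar_lifetable(err0, rect_lt, 0.003, e, "male", baseline = lam) / 2,
               tolerance = 1e-12)
  expect_equal(lar_lifetable(err0, flat_lt, 0, 30, "male"), 0)
  expect_error(lar_lifetable(err0, rect_lt, 0.003, 85, "male", baseline = lam),
               "survival")
  expect_error(lar_lifetable(err0, flat_lt, -0.1, 30, "male"), "non-negative")
})

test_that("LAR declines with age at exposure and is higher for females", {
  lt <- synthetic_lifetable()
  err <- default_err_model()
  curve <- lar_age_curve(2.6, ages = 18:79, backend = "table", table = rt)
  for (sx in c("male", "female")) {
    v <- curve$lar_per_100k[curve$sex == sx]
    expect_true(all(diff(v) <= 1e-12))
  }
  wide <- merge(curve[curve$sex == "female", c("age", "lar_per_100k")],
                curve[curve$sex == "male", c("age", "lar_per_100k")],
                by = "age")
  expect_true(all(wide$lar_per_100k.x >= wide$lar_per_100k.y))
  # lifetable backend: same monotonicity (gamma <= 0) and sex ordering
  lt_curve <- lar_age_curve(2.6, ages = seq(18, 79, by = 3),
                            backend = "lifetable", err = err, lifetable = lt)
  for (sx in c("male", "female")) {
    v <- lt_curve$lar_per_100k[lt_curve$sex == sx]
    expect_true(all(diff(v) <= 1e-12))
  }
  wide2 <- merge(lt_curve[lt_curve$sex == "female", c("age", "lar_per_100k")],
                 lt_curve[lt_curve$sex == "male", c("age", "lar_per_100k")],
                 by = "age")
  expect_true(all(wide2$lar_per_100k.x >= wide2$lar_per_100k.y))
})

test_that("lifetable backend is linear in dose and bounded by survival", {
  lt <- synthetic_lifetable()
  err <- default_err_model()
  a <- lar_lifetable(err, lt, 0.0025, 40, "male")
  b <- lar_lifetable(err, lt, 0.0050, 40, "male")
  expect_equal(b, 2 * a, tolerance = 1e-12)
  # dropping the survival ratio can only increase the projection
  flat <- lt; flat$survival <- rep(1, nrow(flat))
  base <- synthetic_thyroid_incidence("male", lt)
  expect_gte(lar_lifetable(err, flat, 0.0025, 40, "male", baseline = base), a)
})

test_that("the two backends rank (age, sex) exposures consistently", {
  grid <- lar_age_curve(2.6, ages = seq(18, 79, by = 2), backend = "table",
                        table = rt)
  grid_lt <- lar_age_curve(2.6, ages = seq(18, 79, by = 2),
                           backend = "lifetable")
  expect_gt(cor(grid$lar_per_100k, grid_lt$lar_per_100k,
                method = "spearman"), 0.95)
})

test_that("record-level dispatch tags its backend", {
  rec <- list(thyroid_dose_mGy = 2.7, age = 20, sex = "female")
  r1 <- lar_for_record(rec, backend = "table", table = rt)
  r2 <- lar_for_record(rec, backend = "lifetable")
  expect_equal(r1$backend, "table")
  expect_equal(r2$backend, "lifetable")
  expect_equal(r1$lar_per_100k, interp_coefficient(rt, "female", 20) * 2.7 / 100)
  expect_error(lar_for_record(list(age = 20, sex = "male")), "thyroid_dose")
})

test_that("synthetic lifetable and incidence fixtures are coherent", {
  lt <- synthetic_lifetable()
  expect_equal(lt$survival[1], 1)
  expect_true(all(diff(lt$survival) <= 0))
  ex <- sum(lt$survival)  # life expectancy within a few years of 78
  expect_gt(ex, 70); expect_lt(ex, 90)
  lam_f <- synthetic_thyroid_incidence("female", lt)
  lam_m <- synthetic_thyroid_incidence("male", lt)
  crude <- function(lam) sum(lam(lt$age) * lt$survival) / sum(lt$survival)
  expect_equal(crude(lam_f), 4.7e-5, tolerance = 1e-10)
  expect_equal(crude(lam_m), 1.5e-5, tolerance = 1e-10)
})
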