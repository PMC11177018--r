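test_that("dose profile has a plateau and an exponential scatter tail", {
  iv <- irradiated_interval("axial", 14, 10, 1)
  sm <- scatter_model(A = 0.3, mu = 0.23)
  D <- dose_profile(50, iv, sm)
  expect_equal(D(7), 50)            # plateau midpoint
  expect_equal(D(0), 50)            # edge is in-field
  expect_equal(D(14 + 7) / 50, 0.3 * exp(-0.23 * 7), tolerance = 1e-12)
  expect_lt(D(14 + 80), 1e-6)       # tail vanishes far away
  expect_equal(D(-3) / 50, 0.3 * exp(-0.23 * 3), tolerance = 1e-12)
})

test_that("closed-form organ mean dose matches numerical integration", {
  sm <- scatter_model(0.3, 0.23)
  iv <- irradiated_interval("axial", 14, 10, 1)
  expect_equal(organ_mean_dose(50, iv, sm, c(2, 9)), 50)  # fully in-field
  d1 <- 3; d2 <- 8
  expect_equal(organ_mean_dose(50, iv, sm, 14 + c(d1, d2)),
               50 * 0.3 * (exp(-0.23 * d1) - exp(-0.23 * d2)) /
                 (0.23 * (d2 - d1)),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    ctdi <- runif(1, 10, 80)
    sm_i <- scatter_model(runif(1, 0.05, 1), runif(1, 0.05, 1))
    iv_i <- irradiated_interval(sample(c("axial", "helical"), 1),
                                runif(1, 8, 20), 10, runif(1, 0.5, 1.5))
    ext <- sort(runif(2, iv_i$start - 12, iv_i$end + 12))
    if (diff(ext) < 0.5) ext[2] <- ext[1] + 0.5
    closed <- organ_mean_dose(ctdi, iv_i, sm_i, ext)
    numeric <- trapz_mean_dose(dose_profile(ctdi, iv_i, sm_i), ext, n = 2e4)
    # the trapezoid rule is O(h) across the profile's edge discontinuity,
    # so randomized straddling extents only agree to ~1e-3
    expect_equal(closed, numeric, tolerance = 2e-3)
  }
  # smooth case at spec tolerance: extent strictly inside one tail
  iv_s <- irradiated_interval("axial", 14, 10, 1)
  sm_s <- scatter_model(0.4, 0.3)
  closed <- organ_mean_dose(60, iv_s, sm_s, c(17, 22))
  expect_equal(closed, trapz_mean_dose(dose_profile(60, iv_s, sm_s),
                                       c(17, 22), n = 1e4),
               tolerance = 1e-6)
})

test_that("thyroid dose respects geometry and acquisition mode orderings", {
  model <- default_dose_model()
  rec <- function(sex, mode, pitch = 1, mAs = 200, len = 14)
    list(sex = sex, scanner = "SSE", kvp = 110, mAs = mAs, pitch = pitch,
         scan_mode = mode, scan_length_cm = len, beam_width_mm = 10,
         ctdivol_mGy = 45)
  f <- thyroid_dose(rec("female", "axial"), model = model)
  m <- thyroid_dose(rec("male", "axial"), model = model)
  expect_gt(f, m)   # shorter female neck sits the thyroid closer to the field
  hel <- thyroid_dose(rec("male", "helical"), model = model)
  expect_gt(hel, m) # over-ranging moves the caudal edge toward the thyroid
  # linearity in mAs propagates through the profile
  r1 <- rec("male", "axial"); r1$ctdivol_mGy <- NA
  r2 <- r1; r2$mAs <- 2 * r1$mAs
  expect_equal(thyroid_dose(r2, model = model),
               2 * thyroid_dose(r1, model = model), tolerance = 1e-12)
  # organ dose never exceeds CTDIvol
  expect_lt(f, 45)
})

test_that("vectorised cohort thyroid dose equals the per-record computation", {
  model <- default_dose_model()
  co <- fill_dose_indices(generate_cohort(seed = 4))
  co <- add_organ_doses(co, model)
  per_record <- vapply(seq_len(nrow(co)), function(i)
    thyroid_dose(co[i, ], model = model), numeric(1))
  expect_equal(co$thyroid_dose_mGy, per_record, tolerance = 1e-12)
  expect_true(all(co$thyroid_dose_mGy <= co$ctdivol_mGy))
})

test_that("tissue-weighted effective dose behaves like a weighted mean", {
  w <- icrp103_tissue_weights()
  expect_equal(sum(w$weight), 1)
  doses <- setNames(rep(0, nrow(w)), w$organ)
  doses["thyroid"] <- 2.5
  expect_equal(effective_dose_tissue(doses, quiet = TRUE), 0.04 * 2.5)
  uniform <- setNames(rep(3.7, nrow(w)), w$organ)
  expect_equal(effective_dose_tissue(uniform, quiet = TRUE), 3.7)
  shuffled <- uniform[sample(names(uniform))]
  expect_equal(effective_dose_tissue(shuffled, quiet = TRUE), 3.7)
  bad <- w; bad$weight[1] <- -0.1
  expect_error(effective_dose_tissue(uniform, bad), "non-negative")
  expect_message(effective_dose_tissue(c(thyroid = 1)), "contribute 0")
})

test_that("effective dose is linear in CTDIvol at fixed geometry", {
  model <- default_dose_model()
  co <- fill_dose_indices(generate_cohort(seed = 4))
  a <- add_organ_doses(co, model)
  co2 <- co; co2$ctdivol_mGy <- 2 * co$ctdivol_mGy
  b <- add_organ_doses(co2, model)
  expect_equal(b$effective_dose_mSv, 2 * a$effective_dose_mSv,
               tolerance = 1e-12)
})

test_that("organ dose map feeds the same ED as the vectorised backend", {
  model <- default_dose_model()
  co <- fill_dose_indices(generate_cohort(seed = 6))
  co <- add_organ_doses(co, model)
  for (i in c(1, 20, 60)) {
    ed <- effective_dose_tissue(organ_dose_map(co[i, ], model), quiet = TRUE)
    expect_equal(ed, co$effective_dose_mSv[i], tolerance = 1e-12)
  }
})

test_that("k-factor backend cross-checks the tissue backend at cohort level", {
  expect_equal(effective_dose_k(0, 0.0021), 0)
  expect_equal(effective_dose_k(700, 0.0021), 1.47)
  co <- add_organ_doses(fill_dose_indices(generate_cohort(seed = 8)))
  ed_k <- effective_dose_k(co$dlp_mGycm)
  expect_lt(abs(mean(ed_k) - mean(co$effective_dose_mSv)) /
              mean(co$effective_dose_mSv), 0.25)
})

test_that("the shipped model passes its own configuration invariants", {
  model <- default_dose_model()
  expect_s3_class(model, "dose_model")
  expect_true(model$scatter$A > 0 && model$scatter$A <= 1)
  expect_true(model$scatter$mu >= 0.05 && model$scatter$mu <= 1)
  ed_f <- model$geometry$female$neck_cm + model$geometry$female$thyroid_offset_cm
  ed_m <- model$geometry$male$neck_cm + model$geometry$male$thyroid_offset_cm
  expect_lte(ed_f, ed_m)
  expect_lt(model$fit$rms, 0.05)
})

test_that("dose model JSON serialisation round-trips", {
  model <- default_dose_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_dose_model(model, path)
  back <- read_dose_model(path)
  expect_equal(back$scatter, model$scatter, tolerance = 1e-12)
  expect_equal(back$profiles$SSE$ctdiw_ref, model$profiles$SSE$ctdiw_ref,
               tolerance = 1e-12)
  expect_equal(back$distributed_factor, model$distributed_factor,
               tolerance = 1e-12)
})
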