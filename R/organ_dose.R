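# Organ dose and effective dose ----------------------------------------------
#
# Out-of-field organ dose is modelled with a one-dimensional longitudinal
# dose profile: a plateau at CTDIvol across the irradiated interval and
# exponential scatter tails beyond the field edges,
#
#   D(z) = CTDIvol                          inside the interval
#   D(z) = CTDIvol * A * exp(-mu * d)       at distance d beyond an edge.
#
# This is a transparent stand-in for Monte-Carlo CT organ dosimetry: the free
# constants (A, mu, per-scanner reference CTDIw, thyroid-extent offsets, the
# distributed-tissue plateau factor) are recovered by calibration against
# printed reference-cohort means, see calibrate_dose_model().

#' Scatter-tail model
#'
#' @param A tail amplitude as a fraction of CTDIvol at the field edge,
#'   0 < A <= 1 (the profile is continuous only at A = 1).
#' @param mu effective tissue attenuation of the scatter tail (1/cm), > 0.
#' @return object of class `"scatter_model"`.
#' @export
scatter_model <- function(A, mu) {
  stopifnot(A > 0, A <= 1, mu > 0)
  structure(list(A = A, mu = mu), class = "scatter_model")
}

#' Sex-specific phantom geometry
#'
#' Stylised adult phantoms: male 170 cm / 70 kg with a 9 cm neck, female
#' 160 cm / 60 kg with an 8 cm neck. The head scan ends at the C1 lamina
#' (z = nominal scan end); the thyroid's caudal edge sits one neck length
#' below C1, plus a calibrated offset, with a 4 cm cranio-caudal extent.
#' The shorter female neck puts the female thyroid closer to the field edge.
#'
#' @param sex `"male"` or `"female"`.
#' @param neck_cm neck length (cm); defaults 9 (male) / 8 (female).
#' @param thyroid_extent_cm cranio-caudal thyroid extent (cm).
#' @param thyroid_offset_cm additional caudal shift of the thyroid (cm);
#'   a calibration by-product, default 0.
#' @return object of class `"phantom_geometry"` with fields `sex`,
#'   `height_cm`, `weight_kg`, `neck_cm`, `thyroid_extent_cm`,
#'   `thyroid_offset_cm`.
#' @export
phantom_geometry <- function(sex = c("male", "female"), neck_cm = NULL,
                             thyroid_extent_cm = 4, thyroid_offset_cm = 0) {
  sex <- match.arg(sex)
  if (is.null(neck_cm)) neck_cm <- if (sex == "male") 9 else 8
  stopifnot(neck_cm > 0, thyroid_extent_cm > 0)
  structure(list(sex = sex,
                 height_cm = if (sex == "male") 170 else 160,
                 weight_kg = if (sex == "male") 70 else 60,
                 neck_cm = neck_cm,
                 thyroid_extent_cm = thyroid_extent_cm,
                 thyroid_offset_cm = thyroid_offset_cm),
            class = "phantom_geometry")
}

#' Longitudinal dose profile
#'
#' @param ctdivol plateau dose (mGy), >= 0.
#' @param interval an [irradiated_interval()].
#' @param model a [scatter_model()].
#' @return a vectorised function `D(z)` returning mGy.
#' @export
dose_profile <- function(ctdivol, interval, model) {
  stopifnot(ctdivol >= 0, inherits(interval, "irradiated_interval"),
            inherits(model, "scatter_model"))
  l0 <- interval$start; l1 <- interval$end
  A <- model$A; mu <- model$mu
  function(z) {
    d <- pmax(l0 - z, z - l1, 0)
    ifelse(d == 0, ctdivol, ctdivol * A * exp(-mu * d))
  }
}

#' Mean dose over an organ extent (closed form)
#'
#' Integrates the piecewise plateau/exponential profile exactly over
#' `[start, end]`. For the portion overlapping the plateau the integral is
#' `ctdivol * length`; for a tail portion at distances `[d1, d2]` beyond an
#' edge it is `ctdivol * A * (exp(-mu d1) - exp(-mu d2)) / mu`. No numerical
#' quadrature is involved.
#'
#' @param ctdivol plateau dose (mGy).
#' @param interval an [irradiated_interval()].
#' @param model a [scatter_model()].
#' @param extent numeric length-2 `(start, end)` in the same patient-axis
#'   coordinates as the interval, `start < end`.
#' @return mean dose in mGy.
#' @export
organ_mean_dose <- function(ctdivol, interval, model, extent) {
  stopifnot(length(extent) == 2, extent[1] < extent[2])
  s <- extent[1]; e <- extent[2]
  l0 <- interval$start; l1 <- interval$end
  A <- model$A; mu <- model$mu
  plateau <- max(0, min(e, l1) - max(s, l0))
  left <- 0
  if (s < l0) {
    b <- min(e, l0)   # z in [s, b], distance d = l0 - z
    left <- A / mu * (exp(-mu * (l0 - b)) - exp(-mu * (l0 - s)))
  }
  right <- 0
  if (e > l1) {
    a <- max(s, l1)   # z in [a, e], distance d = z - l1
    right <- A / mu * (exp(-mu * (a - l1)) - exp(-mu * (e - l1)))
  }
  ctdivol * (plateau + left + right) / (e - s)
}

# Vectorised fast path: organ band entirely beyond the caudal edge, at
# distances [d1, d2] (cm). Used for thyroid dose over whole cohorts.
tail_band_mean <- function(ctdivol, A, mu, d1, d2) {
  ctdivol * A * (exp(-mu * d1) - exp(-mu * d2)) / (mu * (d2 - d1))
}

#' Thyroid organ dose for one scan
#'
#' Composes [irradiated_interval()], [dose_profile()] and [organ_mean_dose()]
#' over the sex-specific thyroid extent: the thyroid occupies
#' `[L + neck - extent + offset, L + neck + offset]` on the patient axis,
#' where `L` is the nominal scan end (C1 lamina). Helical over-ranging moves
#' the caudal field edge toward the thyroid, so helical scans give a higher
#' thyroid dose than axial scans at equal CTDIvol and scan length; the
#' shorter female neck does the same for female records.
#'
#' @param record one-row cohort `data.frame` (needs `ctdivol_mGy` or enough
#'   tube parameters to compute it), or a list with the same fields.
#' @param geometry a [phantom_geometry()]; default derived from `record$sex`
#'   and `model`.
#' @param model a `dose_model` (see [default_dose_model()]); supplies the
#'   scatter constants, over-range multiplier and scanner profile.
#' @return thyroid dose in mGy.
#' @export
thyroid_dose <- function(record, geometry = NULL, model = default_dose_model()) {
  ct <- record$ctdivol_mGy
  if (is.null(ct) || is.na(ct)) {
    prof <- model$profiles[[record$scanner]]
    if (is.null(prof)) stop("no scanner profile for ", record$scanner)
    ct <- compute_ctdivol(prof, record$kvp, record$mAs, record$pitch)
  }
  if (is.null(geometry)) {
    g <- model$geometry[[record$sex]]
    geometry <- phantom_geometry(record$sex, neck_cm = g$neck_cm,
                                 thyroid_extent_cm = g$thyroid_extent_cm,
                                 thyroid_offset_cm = g$thyroid_offset_cm)
  }
  iv <- irradiated_interval(record$scan_mode, record$scan_length_cm,
                            record$beam_width_mm, record$pitch,
                            model$overrange_mult)
  ext <- record$scan_length_cm + geometry$neck_cm + geometry$thyroid_offset_cm +
    c(-geometry$thyroid_extent_cm, 0)
  organ_mean_dose(ct, iv, model$scatter, ext)
}

# ICRP-103 tissue weighting ---------------------------------------------------

#' ICRP-103 tissue weighting factors
#'
#' The full weighting set (sums to 1; thyroid 0.04). The `class` column is the
#' package's head-scan exposure classification used to assign plateau factors:
#' `in_field` organs see the full CTDIvol, `distributed` tissues a shared
#' calibrated fraction, `far` organs effectively none, and the thyroid is
#' modelled explicitly through the dose profile.
#'
#' @return `data.frame` with columns `organ`, `weight`, `class`.
#' @export
icrp103_tissue_weights <- function() {
  w <- data.frame(
    organ = c("red_bone_marrow", "colon", "lung", "stomach", "breast",
              "remainder", "gonads", "bladder", "oesophagus", "liver",
              "thyroid", "bone_surface", "brain", "salivary_glands", "skin"),
    weight = c(0.12, 0.12, 0.12, 0.12, 0.12, 0.12, 0.08, 0.04, 0.04, 0.04,
               0.04, 0.01, 0.01, 0.01, 0.01),
    class = c("distributed", "far", "far", "far", "far",
              "distributed", "far", "far", "distributed", "far",
              "thyroid", "distributed", "in_field", "in_field", "distributed"),
    stringsAsFactors = FALSE
  )
  stopifnot(abs(sum(w$weight) - 1) < 1e-12)
  w
}

#' Effective dose from an organ dose map (tissue-weight backend)
#'
#' `ED = sum_T w_T * H_T`, with equivalent dose `H_T` (mSv) equal to the
#' absorbed organ dose (mGy) because the radiation weighting factor for
#' photons is 1. Organs present in the weight set but missing from the dose
#' map contribute 0 (a message lists them).
#'
#' @param organ_doses named numeric vector of organ absorbed doses (mGy).
#' @param weights `data.frame` with `organ` and `weight` columns
#'   (default [icrp103_tissue_weights()]); weights must be non-negative and
#'   sum to 1.
#' @param quiet suppress the missing-organ message.
#' @return effective dose in mSv.
#' @export
effective_dose_tissue <- function(organ_doses, weights = icrp103_tissue_weights(),
                                  quiet = FALSE) {
  if (any(weights$weight < 0)) stop("tissue weights must be non-negative")
  if (abs(sum(weights$weight) - 1) > 1e-8)
    stop("tissue weights must sum to 1 (got ", sum(weights$weight), ")")
  stopifnot(all(organ_doses >= 0))
  missing <- setdiff(weights$organ, names(organ_doses))
  if (length(missing) && !quiet)
    message("organs absent from dose map contribute 0: ",
            paste(missing, collapse = ", "))
  h <- organ_doses[weights$organ]
  h[is.na(h)] <- 0
  sum(weights$weight * h)
}

#' Effective dose from DLP (k-factor backend)
#'
#' The conventional shortcut `ED = k * DLP` with the adult-head conversion
#' coefficient; serves as a cross-check on the tissue-weight backend.
#'
#' @param dlp dose-length product (mGy*cm), >= 0.
#' @param k_head conversion coefficient in mSv/(mGy*cm); default from the
#'   shipped model configuration (literature adult-head value 0.0021).
#' @return effective dose in mSv.
#' @export
effective_dose_k <- function(dlp, k_head = default_dose_model()$k_head) {
  stopifnot(all(dlp >= 0), k_head >= 0)
  dlp * k_head
}

#' Organ dose map for one scan record
#'
#' Builds the full ICRP-103 organ dose vector used by the tissue-weight
#' effective-dose backend: in-field organs at CTDIvol, distributed tissues at
#' the calibrated shared fraction of CTDIvol, far organs at 0, thyroid from
#' the scatter-tail profile.
#'
#' @param record one-row cohort `data.frame`.
#' @param model a `dose_model`.
#' @return named numeric vector of organ doses (mGy).
#' @export
organ_dose_map <- function(record, model = default_dose_model()) {
  ct <- record$ctdivol_mGy
  if (is.null(ct) || is.na(ct)) {
    prof <- model$profiles[[record$scanner]]
    ct <- compute_ctdivol(prof, record$kvp, record$mAs, record$pitch)
  }
  w <- model$tissue_weights
  fac <- c(in_field = 1, distributed = model$distributed_factor, far = 0)
  doses <- setNames(ifelse(w$class == "thyroid", NA_real_,
                           ct * fac[w$class]), w$organ)
  doses["thyroid"] <- thyroid_dose(record, model = model)
  doses
}

#' Add thyroid dose and effective dose columns to a cohort
#'
#' Vectorised pipeline stage: requires filled `ctdivol_mGy` (see
#' [fill_dose_indices()]); appends `thyroid_dose_mGy` and
#' `effective_dose_mSv`.
#'
#' @param cohort cohort `data.frame` with dose indices filled.
#' @param model a `dose_model`.
#' @param ed_backend `"tissue"` (ICRP-103 weighting, default) or `"k"`
#'   (DLP times k-factor).
#' @return the augmented cohort.
#' @export
add_organ_doses <- function(cohort, model = default_dose_model(),
                            ed_backend = c("tissue", "k")) {
  ed_backend <- match.arg(ed_backend)
  if (nrow(cohort) == 0) {
    cohort$thyroid_dose_mGy <- numeric(0)
    cohort$effective_dose_mSv <- numeric(0)
    return(cohort)
  }
  if (any(is.na(cohort$ctdivol_mGy)))
    stop("ctdivol_mGy must be filled before organ doses; run fill_dose_indices()")
  cohort$thyroid_dose_mGy <- thyroid_dose_vec(cohort, model)
  w <- model$tissue_weights
  w_in <- sum(w$weight[w$class == "in_field"])
  w_dist <- sum(w$weight[w$class == "distributed"])
  w_thy <- w$weight[w$class == "thyroid"]
  cohort$effective_dose_mSv <- if (ed_backend == "tissue") {
    cohort$ctdivol_mGy * (w_in + w_dist * model$distributed_factor) +
      w_thy * cohort$thyroid_dose_mGy
  } else {
    effective_dose_k(cohort$dlp_mGycm, model$k_head)
  }
  attr(cohort, "ed_backend") <- ed_backend
  cohort
}

# Vectorised thyroid dose over a cohort. Fast closed-form band when the
# thyroid lies fully beyond the caudal edge (the usual head-scan geometry);
# falls back to the general piecewise integral otherwise.
thyroid_dose_vec <- function(cohort, model) {
  geom_off <- vapply(model$geometry, `[[`, numeric(1), "thyroid_offset_cm")
  neck <- vapply(model$geometry, `[[`, numeric(1), "neck_cm")
  ext_len <- vapply(model$geometry, `[[`, numeric(1), "thyroid_extent_cm")
  sx <- cohort$sex
  overrange <- ifelse(cohort$scan_mode == "helical",
                      model$overrange_mult * cohort$pitch *
                        cohort$beam_width_mm / 10, 0)
  d2 <- neck[sx] + geom_off[sx] - overrange          # caudal thyroid edge
  d1 <- d2 - ext_len[sx]                             # cranial thyroid edge
  out <- numeric(nrow(cohort))
  fast <- d1 > 0
  out[fast] <- tail_band_mean(cohort$ctdivol_mGy[fast], model$scatter$A,
                              model$scatter$mu, d1[fast], d2[fast])
  for (i in which(!fast)) {
    out[i] <- thyroid_dose(cohort[i, , drop = FALSE], model = model)
  }
  out
}
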