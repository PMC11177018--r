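# Synthetic cohort generation ------------------------------------------------
#
# The generator emulates a three-scanner adult head-CT service: per-scanner
# record counts by sex, fixed acquisition settings (kVp, pitch, mode, beam
# width, rotation time) and truncated-normal draws for the continuous
# parameters (mAs, scan length) and for patient age.

#' Build one scanner arm of a cohort specification
#'
#' @param name scanner short name.
#' @param n_male,n_female record counts for this scanner.
#' @param mas_mean,mas_sd tube current-time product per rotation (mAs);
#'   `mas_sd = 0` means every record gets exactly `mas_mean`.
#' @param mas_range numeric length-2; hard truncation bounds for mAs, normally
#'   the scanner's tube-current range times the rotation time.
#' @param kvp fixed tube potential (kV).
#' @param scan_length_mean,scan_length_sd nominal scan length (cm). Draws are
#'   truncated to mean +/- 3 SD (floored at 1 cm).
#' @param pitch table pitch; must be exactly 1 for axial mode.
#' @param scan_mode `"axial"` or `"helical"`.
#' @param rotation_time_s gantry rotation time (s).
#' @param beam_width_mm total collimated beam width (mm).
#' @return a list of class `"scanner_arm"`.
#' @export
scanner_arm <- function(name, n_male, n_female, mas_mean, mas_sd, mas_range,
                        kvp, scan_length_mean, scan_length_sd, pitch,
                        scan_mode = c("axial", "helical"),
                        rotation_time_s, beam_width_mm) {
  scan_mode <- match.arg(scan_mode)
  for (nm in c("n_male", "n_female", "mas_mean", "mas_sd", "kvp",
               "scan_length_mean", "scan_length_sd", "pitch",
               "rotation_time_s", "beam_width_mm"))
    assign(nm, as.numeric(get(nm)))
  stopifnot(n_male >= 0, n_female >= 0, mas_sd >= 0, scan_length_sd >= 0,
            pitch > 0, kvp > 0, beam_width_mm > 0, rotation_time_s > 0,
            length(mas_range) == 2, mas_range[1] < mas_range[2])
  if (scan_mode == "axial" && pitch != 1)
    stop("axial mode requires pitch = 1 exactly")
  structure(list(
    name = name, n_male = n_male, n_female = n_female,
    mas_mean = mas_mean, mas_sd = mas_sd, mas_range = as.numeric(mas_range),
    kvp = kvp,
    scan_length_mean = scan_length_mean, scan_length_sd = scan_length_sd,
    scan_length_range = c(max(1, scan_length_mean - 3 * scan_length_sd),
                          scan_length_mean + 3 * scan_length_sd + 1e-9),
    pitch = pitch, scan_mode = scan_mode,
    rotation_time_s = rotation_time_s, beam_width_mm = beam_width_mm
  ), class = "scanner_arm")
}

#' Cohort specification
#'
#' Bundles scanner arms with per-sex age distributions (truncated normal,
#' integer-rounded after sampling).
#'
#' @param scanners named list of [scanner_arm()] objects.
#' @param ages list with elements `male` and `female`, each
#'   `list(mean=, sd=, range=c(lo, hi))` in years.
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(scanners, ages) {
  spec <- structure(list(scanners = scanners, ages = ages),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the structural invariants: non-negative counts and SDs, positive
#' pitch, age ranges with `min < max` and a minimum of 18 years (adults only).
#'
#' @param spec a `cohort_spec`.
#' @return `spec`, invisibly; errors otherwise.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"), length(spec$scanners) >= 1)
  for (arm in spec$scanners) {
    if (!inherits(arm, "scanner_arm")) stop("scanners must be scanner_arm objects")
  }
  for (sx in c("male", "female")) {
    a <- spec$ages[[sx]]
    if (is.null(a)) stop("missing age distribution for ", sx)
    stopifnot(a$sd >= 0, a$range[1] < a$range[2], a$range[1] >= 18)
  }
  invisible(spec)
}

#' Default cohort specification (74-patient three-scanner service)
#'
#' Encodes the reference survey conditions: Siemens Somatom Emotion ("SSE",
#' 15 M / 13 F, 205.04 +/- 55.65 mAs, 110 kVp, 13.18 +/- 1.6 cm, axial pitch 1,
#' 1 s rotation, 10 mm beam), Philips Ingenuity Flex ("PI", 12 M / 15 F,
#' 188.39 +/- 4.86 mAs, 120 kVp, 15.8 +/- 1.7 cm, helical pitch 0.563, 0.5 s,
#' 10 mm) and Toshiba Alexion ("TA", 11 M / 8 F, 160 +/- 0 mAs, 120 kVp,
#' 14.24 +/- 0.98 cm, helical pitch 1, 1.5 s, 9.6 mm). Ages: male
#' N(43, 19^2) truncated to \[18, 78\]; female N(46, 17^2) truncated to
#' \[18, 79\]. Totals 38 males + 36 females = 74 records.
#'
#' mAs truncation bounds come from each scanner's tube-current range times its
#' rotation time (SSE 20-345, PI 10-250, TA 15-450 mAs).
#'
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function() {
  cohort_spec(
    scanners = list(
      SSE = scanner_arm("SSE", 15, 13, 205.04, 55.65, c(20, 345), 110,
                        13.18, 1.6, 1, "axial", 1, 10),
      PI  = scanner_arm("PI", 12, 15, 188.39, 4.86, c(10, 250), 120,
                        15.8, 1.7, 0.563, "helical", 0.5, 10),
      TA  = scanner_arm("TA", 11, 8, 160, 0, c(15, 450), 120,
                        14.24, 0.98, 1, "helical", 1.5, 9.6)
    ),
    ages = list(male   = list(mean = 43, sd = 19, range = c(18, 78)),
                female = list(mean = 46, sd = 17, range = c(18, 79)))
  )
}

#' Scale the record counts of a cohort specification
#'
#' Multiplies every per-scanner, per-sex count by `factor`; distributions are
#' untouched. Used for large-n convergence checks and calibration.
#'
#' @param spec a `cohort_spec`.
#' @param factor positive integer multiplier.
#' @return the scaled `cohort_spec`.
#' @export
scale_cohort_spec <- function(spec, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  for (nm in names(spec$scanners)) {
    spec$scanners[[nm]]$n_male <- spec$scanners[[nm]]$n_male * factor
    spec$scanners[[nm]]$n_female <- spec$scanners[[nm]]$n_female * factor
  }
  spec
}

#' Truncated-normal sampling by inverse-CDF
#'
#' Draws from N(mean, sd^2) conditioned on `[lower, upper]` by mapping
#' uniforms through the truncated quantile function
#' `qnorm(runif(n, pnorm(lower), pnorm(upper)))` (inverse-CDF, not rejection:
#' cost is O(n) and independent of how extreme the truncation is).
#' With `sd = 0` the point mass at `mean` is returned, provided it lies inside
#' the bounds.
#'
#' Uses the global RNG stream; callers wanting reproducibility seed it
#' (as [generate_cohort()] does).
#'
#' @param n number of draws.
#' @param mean,sd untruncated moments; `sd >= 0`.
#' @param lower,upper truncation bounds, `lower < upper`.
#' @return numeric vector of length `n`, all values in `[lower, upper]`.
#' @export
rtrunc_normal <- function(n, mean, sd, lower, upper) {
  stopifnot(n >= 0, sd >= 0, lower < upper)
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate distribution: mean ", mean, " outside [",
           lower, ", ", upper, "]")
    return(rep(mean, n))
  }
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  pmin(pmax(qnorm(p, mean, sd), lower), upper)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic scan-record cohort
#'
#' Record counts per scanner and sex match the spec exactly (counts are never
#' stochastic); fixed acquisition settings are copied from the scanner arm;
#' mAs, scan length and age are truncated-normal draws ([rtrunc_normal()]).
#' Ages are rounded to integer years after sampling. Dose-index columns
#' (`ctdivol_mGy`, `dlp_mGycm`) are left `NA` for [fill_dose_indices()].
#'
#' Identical `(spec, seed)` give identical cohorts; the caller's RNG state is
#' restored on exit.
#'
#' @param spec a `cohort_spec`; defaults to [default_cohort_spec()].
#' @param seed integer RNG seed.
#' @return `data.frame` with columns `patient_id, sex, age, scanner, kvp, mAs,
#'   pitch, scan_mode, scan_length_cm, beam_width_mm, rotation_time_s,
#'   ctdivol_mGy, dlp_mGycm`.
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed = 1L) {
  validate_cohort_spec(spec)
  with_seed(seed, {
    parts <- list()
    for (nm in names(spec$scanners)) {
      arm <- spec$scanners[[nm]]
      for (sx in c("male", "female")) {
        n <- if (sx == "male") arm$n_male else arm$n_female
        if (n == 0) next
        mas <- rtrunc_normal(n, arm$mas_mean, arm$mas_sd,
                             arm$mas_range[1], arm$mas_range[2])
        len <- rtrunc_normal(n, arm$scan_length_mean, arm$scan_length_sd,
                             arm$scan_length_range[1], arm$scan_length_range[2])
        agd <- spec$ages[[sx]]
        age <- round(rtrunc_normal(n, agd$mean, agd$sd,
                                   agd$range[1], agd$range[2]))
        parts[[paste(nm, sx)]] <- data.frame(
          patient_id = sprintf("%s-%s-%04d", nm,
                               toupper(substr(sx, 1, 1)), seq_len(n)),
          sex = sx, age = as.integer(age), scanner = nm, kvp = arm$kvp,
          mAs = mas, pitch = arm$pitch, scan_mode = arm$scan_mode,
          scan_length_cm = len, beam_width_mm = arm$beam_width_mm,
          rotation_time_s = arm$rotation_time_s,
          ctdivol_mGy = NA_real_, dlp_mGycm = NA_real_,
          stringsAsFactors = FALSE, check.names = FALSE
        )
      }
    }
    cohort <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
    validate_cohort(cohort)
    cohort
  })
}

cohort_columns <- c("patient_id", "sex", "age", "scanner", "kvp", "mAs",
                    "pitch", "scan_mode", "scan_length_cm", "beam_width_mm",
                    "rotation_time_s", "ctdivol_mGy", "dlp_mGycm")

#' Validate scan records
#'
#' Enforces the record invariants: adult ages (>= 18), positive mAs and scan
#' length, kVp drawn from the supported set, pitch 1 for axial acquisitions.
#'
#' @param cohort cohort `data.frame`.
#' @param supported_kvp allowed tube potentials (kV).
#' @return `cohort`, invisibly; errors on violation.
#' @export
validate_cohort <- function(cohort,
                            supported_kvp = c(80, 100, 110, 120, 130, 140)) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cohort) == 0) return(invisible(cohort))
  stopifnot(all(cohort$sex %in% c("male", "female")),
            all(cohort$age >= 18),
            all(cohort$mAs > 0),
            all(cohort$scan_length_cm > 0),
            all(cohort$pitch > 0),
            all(cohort$scan_mode %in% c("axial", "helical")))
  if (!all(cohort$kvp %in% supported_kvp))
    stop("unsupported kVp value(s): ",
         paste(unique(setdiff(cohort$kvp, supported_kvp)), collapse = ", "))
  if (any(cohort$scan_mode == "axial" & cohort$pitch != 1))
    stop("axial records must have pitch exactly 1")
  invisible(cohort)
}

# Cohort CSV dialect ----------------------------------------------------------

#' Write a cohort CSV
#'
#' UTF-8, dot decimal, header fixed to the cohort schema; absent dose indices
#' become empty strings. Optional `#`-prefixed comment lines carry provenance.
#'
#' @param cohort cohort `data.frame`.
#' @param path output file.
#' @param comments character vector of provenance lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, comments = NULL) {
  stopifnot(all(cohort_columns %in% names(cohort)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.csv(cohort[, cohort_columns], con, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path file written by [write_cohort_csv()] (comment lines starting
#'   with `#` are skipped). Empty dose-index cells load as `NA`.
#' @param drop_missing_dose if `TRUE`, drop records lacking a measured/filled
#'   CTDIvol or DLP (reader-level analogue of excluding scans without a dose
#'   report page).
#' @return cohort `data.frame`.
#' @export
read_cohort_csv <- function(path, drop_missing_dose = FALSE) {
  cohort <- read.csv(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE,
                     colClasses = c(patient_id = "character"))
  for (col in c("ctdivol_mGy", "dlp_mGycm"))
    cohort[[col]] <- as.numeric(cohort[[col]])
  if (drop_missing_dose)
    cohort <- cohort[!is.na(cohort$ctdivol_mGy) & !is.na(cohort$dlp_mGycm), ,
                     drop = FALSE]
  validate_cohort(cohort)
  cohort
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  for (nm in names(x$scanners)) {
    a <- x$scanners[[nm]]
    cat(sprintf("  %-4s %2d M / %2d F  %6.1f+/-%-5.1f mAs  %d kVp  %s (pitch %.3g)\n",
                nm, a$n_male, a$n_female, a$mas_mean, a$mas_sd, a$kvp,
                a$scan_mode, a$pitch))
  }
  cat(sprintf("  ages: M %g+/-%g [%g,%g]  F %g+/-%g [%g,%g]\n",
              x$ages$male$mean, x$ages$male$sd,
              x$ages$male$range[1], x$ages$male$range[2],
              x$ages$female$mean, x$ages$female$sd,
              x$ages$female$range[1], x$ages$female$range[2]))
  invisible(x)
}
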