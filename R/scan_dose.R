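# Scan-level dose indices -----------------------------------------------------
#
# CTDIvol follows the standard parameter laws: linear in mAs (through the
# origin), a kVp power law (default exponent 2), and inverse pitch. DLP is
# CTDIvol times scan length; scan length is recoverable as DLP/CTDIvol.

#' Scanner physics profile
#'
#' @param name scanner short name.
#' @param ctdiw_ref reference weighted CTDI in mGy per 100 mAs at `kvp_ref`
#'   (16 cm head-phantom convention). A calibration constant, not a physics
#'   derivation; see [calibrate_dose_model()].
#' @param kvp_ref reference tube potential (kV).
#' @param kvp_exponent power-law exponent for the kVp dependence; the dose is
#'   approximately proportional to the square of kVp, so the default is 2
#'   and the allowed range \[1.5, 3.5\].
#' @param beam_width_mm total beam width (mm).
#' @param supported_kvp tube potentials the scanner offers (kV).
#' @param modes supported scan modes.
#' @param mas_range usable mAs range (tube-current range times rotation time).
#' @return object of class `"scanner_profile"`.
#' @export
scanner_profile <- function(name, ctdiw_ref, kvp_ref = 120, kvp_exponent = 2,
                            beam_width_mm, supported_kvp = c(110, 120, 130),
                            modes = c("axial", "helical"),
                            mas_range = c(10, 500)) {
  stopifnot(ctdiw_ref > 0, kvp_exponent >= 1.5, kvp_exponent <= 3.5,
            beam_width_mm > 0)
  structure(list(name = name, ctdiw_ref = ctdiw_ref, kvp_ref = kvp_ref,
                 kvp_exponent = kvp_exponent, beam_width_mm = beam_width_mm,
                 supported_kvp = supported_kvp, modes = modes,
                 mas_range = as.numeric(mas_range)),
            class = "scanner_profile")
}

#' Volumetric CT dose index from tube parameters
#'
#' `CTDIvol = ctdiw_ref * (mAs/100) * (kvp/kvp_ref)^n / pitch`: linear in the
#' tube current-time product, power-law in tube potential, inverse in pitch.
#' mAs is the per-rotation current-time product; the pitch division converts
#' it to an effective-mAs dose scaling.
#'
#' @param profile a [scanner_profile()].
#' @param kvp tube potential (kV); a warning is raised if outside the
#'   scanner's supported set.
#' @param mAs tube current-time product per rotation (>= 0).
#' @param pitch table pitch (> 0).
#' @return CTDIvol in mGy (vectorised over `kvp`, `mAs`, `pitch`).
#' @export
compute_ctdivol <- function(profile, kvp, mAs, pitch) {
  stopifnot(inherits(profile, "scanner_profile"))
  if (any(pitch <= 0)) stop("pitch must be positive")
  if (any(mAs < 0)) stop("mAs must be non-negative")
  if (any(kvp <= 0)) stop("kvp must be positive")
  if (!all(kvp %in% profile$supported_kvp))
    warning("kVp outside supported set for scanner ", profile$name, ": ",
            paste(unique(setdiff(kvp, profile$supported_kvp)), collapse = ", "))
  profile$ctdiw_ref * (mAs / 100) * (kvp / profile$kvp_ref)^profile$kvp_exponent /
    pitch
}

#' Dose-length product
#'
#' @param ctdivol CTDIvol (mGy), >= 0.
#' @param scan_length_cm irradiated scan length (cm), >= 0.
#' @return DLP in mGy*cm.
#' @export
compute_dlp <- function(ctdivol, scan_length_cm) {
  stopifnot(all(ctdivol >= 0), all(scan_length_cm >= 0))
  ctdivol * scan_length_cm
}

#' Scan length from DLP and CTDIvol
#'
#' The dose-report inversion `length = DLP / CTDIvol`.
#'
#' @param dlp dose-length product (mGy*cm), >= 0.
#' @param ctdivol CTDIvol (mGy), strictly positive.
#' @return scan length in cm.
#' @export
infer_scan_length <- function(dlp, ctdivol) {
  if (any(ctdivol <= 0)) stop("ctdivol must be positive to infer scan length")
  stopifnot(all(dlp >= 0))
  dlp / ctdivol
}

#' Irradiated interval along the patient axis
#'
#' Patient-axis coordinate z in cm, 0 at the (cranial) scan start, increasing
#' caudally. Axial acquisitions irradiate exactly the nominal range; helical
#' acquisitions over-range by `overrange_mult * pitch * beam_width` at each
#' end (beam width converted mm -> cm), the extra rotations required for
#' interpolation at the volume boundaries.
#'
#' @param scan_mode `"axial"` or `"helical"`.
#' @param scan_length_cm nominal scan length (cm), > 0.
#' @param beam_width_mm total beam width (mm), > 0.
#' @param pitch table pitch (> 0); ignored for axial.
#' @param overrange_mult per-side over-range multiplier (default 0.5).
#' @return list of class `"irradiated_interval"` with `start`, `end` (cm),
#'   `nominal` and `overrange` (per side, cm).
#' @export
irradiated_interval <- function(scan_mode, scan_length_cm, beam_width_mm,
                                pitch = 1, overrange_mult = 0.5) {
  stopifnot(scan_length_cm > 0, beam_width_mm > 0, pitch > 0)
  scan_mode <- match.arg(scan_mode, c("axial", "helical"))
  overrange <- if (scan_mode == "helical")
    overrange_mult * pitch * beam_width_mm / 10 else 0
  structure(list(start = -overrange, end = scan_length_cm + overrange,
                 nominal = scan_length_cm, overrange = overrange),
            class = "irradiated_interval")
}

#' Fill missing CTDIvol / DLP columns of a cohort
#'
#' Computes CTDIvol from tube parameters where absent and DLP from
#' (possibly just-computed) CTDIvol and scan length; measured values already
#' present are never overwritten unless `overwrite = TRUE`.
#'
#' @param cohort cohort `data.frame` (see [generate_cohort()]).
#' @param profiles named list of [scanner_profile()]s covering every scanner
#'   in the cohort (default: profiles of the shipped calibrated model).
#' @param overwrite recompute even where measured values exist.
#' @return the cohort with `ctdivol_mGy` and `dlp_mGycm` filled.
#' @export
fill_dose_indices <- function(cohort, profiles = NULL, overwrite = FALSE) {
  if (is.null(profiles)) profiles <- default_dose_model()$profiles
  unknown <- setdiff(unique(cohort$scanner), names(profiles))
  if (length(unknown))
    stop("no scanner profile for: ", paste(unknown, collapse = ", "))
  if (nrow(cohort) == 0) return(cohort)
  need_c <- overwrite | is.na(cohort$ctdivol_mGy)
  for (nm in unique(cohort$scanner[need_c])) {
    i <- need_c & cohort$scanner == nm
    cohort$ctdivol_mGy[i] <- compute_ctdivol(profiles[[nm]], cohort$kvp[i],
                                             cohort$mAs[i], cohort$pitch[i])
  }
  need_d <- overwrite | is.na(cohort$dlp_mGycm)
  cohort$dlp_mGycm[need_d] <- compute_dlp(cohort$ctdivol_mGy[need_d],
                                          cohort$scan_length_cm[need_d])
  cohort
}
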