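# Pipeline orchestration and file-level interface -----------------------------
#
# Each stage is append-only on the cohort CSV schema; (spec, seed, config)
# fully determine every output byte. The thin command-line wrapper at
# inst/cli/headctrisk.R dispatches to these functions.

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  unname(tools::md5sum(tmp))
}

model_digest <- function(model) {
  config_hash(list(
    profiles = lapply(model$profiles, function(p)
      p[c("name", "ctdiw_ref", "kvp_ref", "kvp_exponent")]),
    scatter = model$scatter[c("A", "mu")], geometry = model$geometry,
    distributed_factor = model$distributed_factor, k_head = model$k_head,
    overrange_mult = model$overrange_mult))
}

#' Simulate a cohort to CSV
#'
#' @param out output CSV path.
#' @param spec a `cohort_spec`, or a path to a JSON spec file
#'   (see [write_cohort_spec_json()]); default [default_cohort_spec()].
#' @param seed RNG seed.
#' @param quiet suppress the per-scanner count log.
#' @return the cohort `data.frame`, invisibly.
#' @export
cli_simulate <- function(out, spec = NULL, seed = 1L, quiet = FALSE) {
  if (is.null(spec)) spec <- default_cohort_spec()
  if (is.character(spec)) spec <- read_cohort_spec_json(spec)
  cohort <- generate_cohort(spec, seed = seed)
  if (!quiet) {
    counts <- table(cohort$scanner, cohort$sex)
    message("simulated ", nrow(cohort), " records (seed ", seed, "):")
    for (nm in rownames(counts))
      message(sprintf("  %-4s %d male / %d female", nm,
                      counts[nm, "male"], counts[nm, "female"]))
  }
  write_cohort_csv(cohort, out, comments = sprintf("seed: %d", seed))
  invisible(cohort)
}

#' Fill dose columns of a cohort CSV
#'
#' Fills `ctdivol_mGy`/`dlp_mGycm` where absent (measured values untouched
#' unless `overwrite`), then appends `thyroid_dose_mGy` and
#' `effective_dose_mSv`. Input columns and order are preserved; a provenance
#' comment (model hash, package version) heads the output.
#'
#' @param input,out CSV paths.
#' @param model a `dose_model` (default the shipped calibrated model).
#' @param ed_backend `"tissue"` or `"k"`.
#' @param overwrite recompute measured dose indices.
#' @return the augmented cohort, invisibly.
#' @export
cli_dose <- function(input, out, model = default_dose_model(),
                     ed_backend = "tissue", overwrite = FALSE) {
  cohort <- read_cohort_csv(input)
  if (nrow(cohort) == 0) warning("empty cohort: ", input)
  cohort <- fill_dose_indices(cohort, model$profiles, overwrite = overwrite)
  cohort <- add_organ_doses(cohort, model, ed_backend = ed_backend)
  write_augmented_csv(cohort, out, model, extra = c(
    sprintf("ed_backend: %s", ed_backend)))
  invisible(cohort)
}

#' Add the LAR column to a dosed cohort CSV
#'
#' @param input,out CSV paths; input must carry `thyroid_dose_mGy`.
#' @param backend `"table"` or `"lifetable"`.
#' @param model dose model recorded in provenance.
#' @return the augmented cohort, invisibly.
#' @export
cli_risk <- function(input, out, backend = "table",
                     model = default_dose_model()) {
  cohort <- read_augmented_csv(input)
  if (!"thyroid_dose_mGy" %in% names(cohort))
    stop("input lacks thyroid_dose_mGy; run the dose stage first (cli_dose)")
  cohort <- add_lar(cohort, backend = backend)
  write_augmented_csv(cohort, out, model, extra = c(
    sprintf("lar_backend: %s", backend)))
  invisible(cohort)
}

#' Write the comparison report files
#'
#' Emits the per-sex parameter table, the sex-by-mode thyroid contrast, the
#' per-sex dose/risk table with tests, regression summaries and a JSON run
#' manifest (seed, model hash, package version, backends).
#'
#' @param input processed cohort CSV (all derived columns present).
#' @param outdir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @param model dose model (for the manifest hash).
#' @return the `comparison_report`, invisibly.
#' @export
cli_report <- function(input, outdir, seed = NA_integer_,
                       model = default_dose_model()) {
  cohort <- read_augmented_csv(input)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rep <- run_full_analysis(cohort)
  wr <- function(df, nm) write.csv(df, file.path(outdir, nm), row.names = FALSE)
  wr(rep$parameters, "parameters_by_sex.csv")
  wr(rep$parameter_tests, "parameter_tests.csv")
  wr(rep$dose_risk, "dose_risk_by_sex.csv")
  wr(rep$dose_risk_tests, "dose_risk_tests.csv")
  wr(rep$mode_contrast, "mode_contrast.csv")
  wr(rep$regressions, "regressions.csv")
  manifest <- list(seed = seed, package = "headctrisk",
                   version = as.character(packageVersion("headctrisk")),
                   model_hash = model_digest(model),
                   n_records = nrow(cohort),
                   power = rep$power, footer = rep$footer)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Run the whole pipeline
#'
#' simulate -> dose -> risk -> report, all under `outdir`. Deterministic:
#' equal (spec, seed, model) reproduce identical files.
#'
#' @param outdir output directory.
#' @param seed RNG seed.
#' @param spec cohort specification (default the 74-record service).
#' @param model dose model.
#' @param lar_backend `"table"` or `"lifetable"`.
#' @param ed_backend `"tissue"` or `"k"`.
#' @param quiet suppress logs.
#' @return the `comparison_report`, invisibly.
#' @export
run_pipeline <- function(outdir, seed = 1L, spec = NULL,
                         model = default_dose_model(),
                         lar_backend = "table", ed_backend = "tissue",
                         quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(nm) file.path(outdir, nm)
  cli_simulate(p("cohort.csv"), spec = spec, seed = seed, quiet = quiet)
  cli_dose(p("cohort.csv"), p("cohort_dosed.csv"), model = model,
           ed_backend = ed_backend)
  cli_risk(p("cohort_dosed.csv"), p("cohort_risk.csv"), backend = lar_backend,
           model = model)
  cli_report(p("cohort_risk.csv"), p("report"), seed = seed, model = model)
}

# Augmented-CSV helpers: cohort schema plus derived columns, provenance in
# '#' comments.
augmented_columns <- function(cohort)
  c(cohort_columns, intersect(c("thyroid_dose_mGy", "effective_dose_mSv",
                                "lar_per_100k"), names(cohort)))

write_augmented_csv <- function(cohort, path, model, extra = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", c(
    sprintf("headctrisk %s", as.character(packageVersion("headctrisk"))),
    sprintf("model_hash: %s", model_digest(model)), extra)), con)
  write.csv(cohort[, augmented_columns(cohort)], con, row.names = FALSE,
            na = "", quote = FALSE)
  invisible(path)
}

read_augmented_csv <- function(path) {
  cohort <- read.csv(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE,
                     colClasses = c(patient_id = "character"))
  for (col in intersect(c("ctdivol_mGy", "dlp_mGycm", "thyroid_dose_mGy",
                          "effective_dose_mSv", "lar_per_100k"),
                        names(cohort)))
    cohort[[col]] <- as.numeric(cohort[[col]])
  validate_cohort(cohort)
  cohort
}

#' Serialise / load a cohort specification as JSON
#'
#' @param spec a `cohort_spec`.
#' @param path JSON path.
#' @return `path` (write) or the `cohort_spec` (read).
#' @export
write_cohort_spec_json <- function(spec, path) {
  validate_cohort_spec(spec)
  x <- list(scanners = lapply(spec$scanners, unclass), ages = spec$ages)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec_json
#' @export
read_cohort_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$scanners) || is.null(x$ages))
    stop("malformed cohort spec '", path, "': needs 'scanners' and 'ages'")
  arms <- lapply(x$scanners, function(a) {
    need <- c("name", "n_male", "n_female", "mas_mean", "mas_sd", "mas_range",
              "kvp", "scan_length_mean", "scan_length_sd", "pitch",
              "scan_mode", "rotation_time_s", "beam_width_mm")
    miss <- setdiff(need, names(a))
    if (length(miss))
      stop("malformed cohort spec: scanner entry missing field(s): ",
           paste(miss, collapse = ", "))
    scanner_arm(a$name, a$n_male, a$n_female, a$mas_mean, a$mas_sd,
                a$mas_range, a$kvp, a$scan_length_mean, a$scan_length_sd,
                a$pitch, a$scan_mode, a$rotation_time_s, a$beam_width_mm)
  })
  cohort_spec(arms, x$ages)
}
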