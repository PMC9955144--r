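#' Write a cohort to CSV
#'
#' Serializes the long-format measurement table and the per-patient metadata
#' table of an `avs_cohort` to two CSV files. Units are fixed by convention
#' (cortisol ug/dL, aldosterone pg/mL); no conversion is applied.
#'
#' @param cohort An `avs_cohort` (see [draw_cohort()] or [read_cohort()]).
#' @param measurements_file,meta_file Output paths.
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(cohort, measurements_file, meta_file) {
  stopifnot(inherits(cohort, "avs_cohort"))
  utils::write.csv(cohort$measurements, measurements_file, row.names = FALSE)
  utils::write.csv(cohort$meta, meta_file, row.names = FALSE)
  invisible(c(measurements_file, meta_file))
}

parse_numeric_col <- function(df, col, file, allow_na = FALSE) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  raw_na <- is.na(df[[col]]) | df[[col]] == "" | toupper(df[[col]]) == "NA"
  bad <- which(is.na(x) & !raw_na)
  if (length(bad)) {
    abort_avs("avs_parse_error",
              sprintf("%s: malformed numeric in column `%s` at row %s",
                      file, col, paste(bad, collapse = ", ")))
  }
  if (!allow_na && any(raw_na)) {
    abort_avs("avs_parse_error",
              sprintf("%s: missing value in column `%s` at row %s",
                      file, col, paste(which(raw_na), collapse = ", ")))
  }
  x
}

parse_logical_col <- function(df, col, file) {
  x <- df[[col]]
  out <- rep(NA, length(x))
  out[toupper(x) %in% c("TRUE", "T", "1")] <- TRUE
  out[toupper(x) %in% c("FALSE", "F", "0")] <- FALSE
  bad <- which(is.na(out) & !(is.na(x) | x == "" | toupper(x) == "NA"))
  if (length(bad)) {
    abort_avs("avs_parse_error",
              sprintf("%s: malformed logical in column `%s` at row %s",
                      file, col, paste(bad, collapse = ", ")))
  }
  out
}

#' Read and validate a cohort from CSV
#'
#' Counterpart of [write_cohort()]. Validation is strict and errors name the
#' offending row (1-based, excluding the header) and column: unknown site or
#' phase strings, malformed numerics, duplicated (patient, site, phase)
#' triples, non-positive cortisol or negative aldosterone, and measurement
#' patients absent from the metadata table are all rejected.
#'
#' @param measurements_file CSV with columns `patient_id`, `site`, `phase`,
#'   `cortisol`, `aldosterone`.
#' @param meta_file CSV keyed by `patient_id` with eligibility flags and any
#'   additional per-patient fields.
#' @return An object of class `avs_cohort`.
#' @export
read_cohort <- function(measurements_file, meta_file) {
  for (f in c(measurements_file, meta_file)) {
    if (!file.exists(f)) abort_avs("avs_parse_error", sprintf("file not found: %s", f))
  }
  mm <- utils::read.csv(measurements_file, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("patient_id", "site", "phase", "cortisol", "aldosterone")
  absent <- setdiff(need, names(mm))
  if (length(absent)) {
    abort_avs("avs_parse_error",
              sprintf("%s: missing column(s) %s", measurements_file,
                      paste(absent, collapse = ", ")))
  }
  bad_site <- which(!mm$site %in% avs_sites())
  if (length(bad_site)) {
    abort_avs("avs_parse_error",
              sprintf("%s: unknown site '%s' at row %s", measurements_file,
                      mm$site[bad_site[1]], paste(bad_site, collapse = ", ")))
  }
  bad_phase <- which(!mm$phase %in% avs_phases())
  if (length(bad_phase)) {
    abort_avs("avs_parse_error",
              sprintf("%s: unknown phase '%s' at row %s", measurements_file,
                      mm$phase[bad_phase[1]], paste(bad_phase, collapse = ", ")))
  }
  mm$cortisol <- parse_numeric_col(mm, "cortisol", measurements_file)
  mm$aldosterone <- parse_numeric_col(mm, "aldosterone", measurements_file)
  bad_c <- which(mm$cortisol <= 0)
  if (length(bad_c)) {
    abort_avs("avs_parse_error",
              sprintf("%s: non-positive cortisol at row %s", measurements_file,
                      paste(bad_c, collapse = ", ")))
  }
  bad_a <- which(mm$aldosterone < 0)
  if (length(bad_a)) {
    abort_avs("avs_parse_error",
              sprintf("%s: negative aldosterone at row %s", measurements_file,
                      paste(bad_a, collapse = ", ")))
  }
  key <- paste(mm$patient_id, mm$site, mm$phase, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort_avs("avs_parse_error",
              sprintf("%s: duplicate (patient, site, phase) at row %s",
                      measurements_file, paste(dup, collapse = ", ")))
  }

  meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"patient_id" %in% names(meta)) {
    abort_avs("avs_parse_error", sprintf("%s: missing column patient_id", meta_file))
  }
  for (col in intersect(c("rt_sampling_complete", "surgery_done_if_uapa",
                          "postop_bp_normal", "followup_available"),
                        names(meta))) {
    meta[[col]] <- parse_logical_col(meta, col, meta_file)
  }
  for (col in intersect(c("pac", "pra", "arr", "postop_arr", "modified_li",
                          "conventional_li"), names(meta))) {
    meta[[col]] <- parse_numeric_col(meta, col, meta_file, allow_na = TRUE)
  }
  orphan <- setdiff(unique(mm$patient_id), meta$patient_id)
  if (length(orphan)) {
    abort_avs("avs_parse_error",
              sprintf("%s: patient(s) %s absent from metadata", measurements_file,
                      paste(orphan, collapse = ", ")))
  }
  structure(list(measurements = mm, meta = meta), class = "avs_cohort")
}

#' Convert a wide measurement table to an `avs_cohort`
#'
#' Convenience importer for the one-row-per-patient layout, with measurement
#' columns named `<site>_<hormone>_<phase>` (for example
#' `lt_adv_cortisol_post_acth`). Remaining columns are carried into the
#' metadata table unchanged.
#'
#' @param wide Data frame with a `patient_id` column and wide measurement
#'   columns.
#' @return An object of class `avs_cohort`.
#' @export
cohort_from_wide <- function(wide) {
  stopifnot(is.data.frame(wide), "patient_id" %in% names(wide))
  grid <- expand.grid(site = avs_sites(), phase = avs_phases(),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    site <- grid$site[i]; phase <- grid$phase[i]
    ccol <- sprintf("%s_cortisol_%s", site, phase)
    acol <- sprintf("%s_aldosterone_%s", site, phase)
    if (!all(c(ccol, acol) %in% names(wide))) return(NULL)
    data.frame(patient_id = wide$patient_id, site = site, phase = phase,
               cortisol = wide[[ccol]], aldosterone = wide[[acol]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    abort_avs("avs_parse_error", "no `<site>_<hormone>_<phase>` columns found")
  }
  used <- unlist(lapply(seq_len(nrow(grid)), function(i) {
    sprintf("%s_%s_%s", grid$site[i], c("cortisol", "aldosterone"), grid$phase[i])
  }))
  meta <- wide[, setdiff(names(wide), used), drop = FALSE]
  o <- order(match(rows$patient_id, wide$patient_id))
  structure(list(measurements = rows[o, ], meta = meta), class = "avs_cohort")
}
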