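# Cohort CSV schema, validation, inclusion filtering and metrics output.
# Dialect is fixed: comma-separated, UTF-8, dot decimal, header required.

.sex_levels <- c("female", "male")
.region_levels <- c("abdomen_pelvis", "chest")
.phantom_levels <- c("body32", "head16")

#' Cohort CSV schema
#'
#' Column names (and order) of the versioned cohort input schema. One row
#' per examination; `exclusion_flags` is a semicolon-separated list of
#' image-review exclusion codes (e.g. `"ascites"`), empty when none apply.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("exam_id", "sex", "age_years", "weight_kg", "height_cm", "ap_mm",
    "lat_mm", "topogram_length_mm", "scan_length_mm", "ctdi_vol_mGy",
    "dlp_mGycm", "region", "phantom", "exclusion_flags")
}

.numeric_cols <- function() {
  c("age_years", "weight_kg", "height_cm", "ap_mm", "lat_mm",
    "topogram_length_mm", "scan_length_mm", "ctdi_vol_mGy", "dlp_mGycm")
}

# Row-level validation; returns tibble(row, field, message) of problems.
.validate_rows <- function(df) {
  problems <- list()
  note <- function(rows, field, message) {
    if (length(rows) > 0) {
      problems[[length(problems) + 1]] <<-
        tibble::tibble(row = rows, field = field, message = message)
    }
  }
  for (col in setdiff(.numeric_cols(), "age_years")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    note(bad, col, "must be a positive number")
  }
  note(which(!is.finite(df$age_years) | df$age_years < 0),
       "age_years", "must be a non-negative number")
  note(which(!df$sex %in% .sex_levels), "sex",
       sprintf("must be one of: %s", paste(.sex_levels, collapse = ", ")))
  note(which(!df$region %in% .region_levels), "region",
       sprintf("must be one of: %s", paste(.region_levels, collapse = ", ")))
  note(which(!df$phantom %in% .phantom_levels), "phantom",
       sprintf("must be one of: %s", paste(.phantom_levels, collapse = ", ")))
  # body regions are referenced to the 32-cm body phantom
  note(which(df$region %in% c("abdomen_pelvis", "chest") &
               df$phantom %in% .phantom_levels & df$phantom != "body32"),
       "phantom", "body regions must use the body32 reference phantom")
  dup <- which(duplicated(df$exam_id) | duplicated(df$exam_id, fromLast = TRUE))
  note(dup, "exam_id", "must be unique")
  if (length(problems) == 0) {
    tibble::tibble(row = integer(), field = character(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(problems), .data$row)
  }
}

#' Read and validate a cohort CSV
#'
#' Reads a cohort file in the [cohort_columns()] schema, validates every
#' row (positivity, enum levels, phantom/region consistency, unique exam
#' ids) and returns the valid records. Malformed rows are collected with
#' their row numbers in the `"row_errors"` attribute rather than silently
#' dropped; a missing column is a hard error.
#'
#' @param path Path to a CSV file.
#' @return A tibble of valid records with attribute `row_errors`, a tibble
#'   with columns `row` (data row number, header excluded), `field`,
#'   `message`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing) > 0) {
    stop(sprintf("cohort file is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[cohort_columns()]
  df$exclusion_flags[is.na(df$exclusion_flags)] <- ""
  parse_problems <- list()
  for (col in .numeric_cols()) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0) {
      parse_problems[[col]] <- tibble::tibble(
        row = bad, field = col,
        message = sprintf("unparseable numeric value '%s'", raw[bad]))
    }
    num[bad] <- NA_real_
    df[[col]] <- num
  }
  errors <- dplyr::bind_rows(c(parse_problems, list(.validate_rows(df))))
  errors <- dplyr::arrange(errors, .data$row)
  valid <- df[!seq_len(nrow(df)) %in% errors$row, , drop = FALSE]
  attr(valid, "row_errors") <- errors
  valid
}

#' Inclusion policy for a dose audit
#'
#' The study-style inclusion rules: adults within a BMI window (closed
#' interval, default 18-35 kg/m^2) and free of image-review exclusion
#' flags. Flags such as `"ascites"`, `"motion_artifact"` or
#' `"major_surgery"` cannot be evaluated from tabular data and are taken
#' from the `exclusion_flags` column as caller-supplied codes.
#'
#' @param bmi_min,bmi_max Closed BMI interval in kg/m^2.
#' @param adult_min_age Minimum age in years.
#' @return An `inclusion_policy` object.
#' @export
inclusion_policy <- function(bmi_min = 18, bmi_max = 35, adult_min_age = 18) {
  stopifnot(bmi_min < bmi_max, adult_min_age >= 0)
  structure(list(bmi_min = bmi_min, bmi_max = bmi_max,
                 adult_min_age = adult_min_age),
            class = "inclusion_policy")
}

#' Apply inclusion rules to a cohort
#'
#' Retains records with `bmi_min <= BMI <= bmi_max` (closed interval),
#' `age >= adult_min_age` and an empty `exclusion_flags` field. Each
#' excluded record is counted under its first matching reason, so exclusion
#' counts plus the retained count always equal the input count. Filtering
#' is idempotent.
#'
#' @param records A validated cohort tibble.
#' @param policy An [inclusion_policy()].
#' @return The retained records, with attribute `exclusions`: a tibble of
#'   `reason`, `n` (one row per reason observed, including flag codes).
#' @export
apply_inclusion <- function(records, policy = inclusion_policy()) {
  stopifnot(inherits(policy, "inclusion_policy"))
  bmi <- compute_bmi(records$weight_kg, records$height_cm)
  flags <- trimws(records$exclusion_flags)
  first_flag <- vapply(strsplit(flags, ";", fixed = TRUE), function(x) {
    x <- trimws(x[nzchar(trimws(x))])
    if (length(x) == 0) NA_character_ else x[1]
  }, character(1))
  reason <- dplyr::case_when(
    records$age_years < policy$adult_min_age ~ "underage",
    bmi < policy$bmi_min ~ "bmi_below_min",
    bmi > policy$bmi_max ~ "bmi_above_max",
    !is.na(first_flag) ~ first_flag,
    TRUE ~ NA_character_
  )
  retained <- records[is.na(reason), , drop = FALSE]
  tb <- table(reason[!is.na(reason)])
  excl <- tibble::tibble(reason = names(tb), n = as.integer(tb))
  if (nrow(retained) == 0) {
    message("inclusion filter retained no records")
  }
  attr(retained, "exclusions") <- excl
  attr(retained, "row_errors") <- NULL
  retained
}

#' Write per-examination metrics alongside their records
#'
#' Joins the cohort records with their [compute_dose_metrics()] output and
#' writes one CSV row per examination: the full input schema followed by
#' the derived columns at full precision, then report-rounded copies
#' (2 decimals for mGy/mSv quantities) with a `_2dp` suffix. Column order
#' is stable across calls; an empty cohort yields a header-only file.
#'
#' @param records Cohort tibble.
#' @param metrics Output of [compute_dose_metrics()] for the same records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, metrics, path) {
  stopifnot(setequal(records$exam_id, metrics$exam_id))
  derived <- c("bmi", "deff_mm", "k", "ssde_mGy", "ed_mSv", "dlp_ss_mGycm",
               "ed_ss_mSv", "ctdi_bias", "scan_length_change_mm",
               "scan_length_change_pct")
  out <- dplyr::left_join(records,
                          metrics[, c("exam_id", derived), drop = FALSE],
                          by = "exam_id")
  for (col in c("ssde_mGy", "ed_mSv", "dlp_ss_mGycm", "ed_ss_mSv")) {
    out[[paste0(col, "_2dp")]] <- round(out[[col]], 2)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
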