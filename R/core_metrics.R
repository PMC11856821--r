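# Per-examination dose arithmetic: BMI, effective diameter, SSDE, ED and
# the size-specific whole-scan indices DLPss = DLP * k, EDss = DLPss * f.

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

#' Body mass index
#'
#' `BMI = weight (kg) / height (m)^2`, with height supplied in cm as stored
#' in scan-header records.
#'
#' @param weight_kg Body weight in kg.
#' @param height_cm Standing height in cm.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(100, 200) # 25
compute_bmi <- function(weight_kg, height_cm) {
  .check_positive(weight_kg, "weight_kg")
  .check_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' Effective diameter from AP and LAT dimensions
#'
#' Geometric mean of the anteroposterior and lateral cross-sectional
#' dimensions, `sqrt(AP * LAT)`, conventionally measured on the largest
#' transverse slice of the scanned volume.
#'
#' @param ap_mm Anteroposterior dimension in mm.
#' @param lat_mm Lateral dimension in mm.
#' @return Effective diameter in mm.
#' @export
#' @examples
#' compute_deff(240.63, 350.30)
compute_deff <- function(ap_mm, lat_mm) {
  .check_positive(ap_mm, "ap_mm")
  .check_positive(lat_mm, "lat_mm")
  sqrt(ap_mm * lat_mm)
}

#' Size-specific dose estimate
#'
#' `SSDE = CTDIvol * k`: the single-rotation dose index corrected for
#' patient size via the AAPM-204 conversion factor.
#'
#' @param ctdi_vol CTDIvol in mGy (phantom-referenced).
#' @param k Conversion factor from [k_factor()].
#' @return SSDE in mGy.
#' @export
compute_ssde <- function(ctdi_vol, k) {
  .check_positive(ctdi_vol, "ctdi_vol")
  .check_positive(k, "k")
  ctdi_vol * k
}

#' Region-specific DLP-to-effective-dose coefficients
#'
#' The conversion coefficients \eqn{f} (mSv per mGy·cm) mapping a
#' dose-length product to effective dose. Abdomen/pelvis uses 0.015 per
#' AAPM Report 96; chest defaults to 0.014 (same convention). Both are
#' overridable, e.g. for site-specific or ICRP-103-based coefficients.
#'
#' @param abdomen_pelvis,chest Coefficients in mSv/(mGy·cm).
#' @param ... Further named `region = f` pairs.
#' @return Named numeric vector of coefficients.
#' @export
region_coefficients <- function(abdomen_pelvis = 0.015, chest = 0.014, ...) {
  f <- c(abdomen_pelvis = abdomen_pelvis, chest = chest, ...)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("all region coefficients must be positive", call. = FALSE)
  }
  f
}

.lookup_f <- function(region, coeffs) {
  unknown <- setdiff(unique(region), names(coeffs))
  if (length(unknown) > 0) {
    stop(sprintf("no f coefficient registered for region(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  unname(coeffs[region])
}

#' Effective dose from DLP
#'
#' `ED = DLP * f(region)`, the conventional whole-scan effective-dose
#' estimate referenced to a standard-size patient.
#'
#' @param dlp Dose-length product in mGy·cm.
#' @param region Body region, e.g. `"abdomen_pelvis"` or `"chest"`.
#' @param coeffs Named coefficient vector, see [region_coefficients()].
#' @return Effective dose in mSv.
#' @export
#' @examples
#' compute_ed(514.88, "abdomen_pelvis") # 7.72 mSv
compute_ed <- function(dlp, region, coeffs = region_coefficients()) {
  .check_positive(dlp, "dlp")
  dlp * .lookup_f(region, coeffs)
}

#' Size-specific dose-length product
#'
#' `DLPss = DLP * k`: the whole-scan dose index corrected for patient size
#' with the same conversion factor that turns CTDIvol into SSDE.
#'
#' @param dlp Dose-length product in mGy·cm.
#' @param k Conversion factor from [k_factor()].
#' @return DLPss in mGy·cm.
#' @export
compute_dlpss <- function(dlp, k) {
  .check_positive(dlp, "dlp")
  .check_positive(k, "k")
  dlp * k
}

#' Size-specific effective dose
#'
#' `EDss = DLPss * f(region)`: the size-corrected effective dose, the
#' headline per-patient risk metric of the size-specific family.
#'
#' @param dlp_ss Size-specific dose-length product in mGy·cm.
#' @inheritParams compute_ed
#' @return EDss in mSv.
#' @export
#' @examples
#' compute_edss(627.83, "abdomen_pelvis") # 9.42 mSv
compute_edss <- function(dlp_ss, region, coeffs = region_coefficients()) {
  .check_positive(dlp_ss, "dlp_ss")
  dlp_ss * .lookup_f(region, coeffs)
}

#' Percent increase of one value over another
#'
#' `100 * (new - old) / old`; used to express how much the size-specific
#' indices exceed their traditional counterparts.
#'
#' @param new_value,old_value Numeric; `old_value` must be positive.
#' @return Percent difference.
#' @export
percent_increase <- function(new_value, old_value) {
  .check_positive(old_value, "old_value")
  stopifnot(is.numeric(new_value), all(is.finite(new_value)))
  100 * (new_value - old_value) / old_value
}

#' Stochastic-risk increment for an effective dose
#'
#' Linear no-threshold scaling of stochastic radiation effects at 5% per
#' sievert: a 10 mSv examination raises the probability of a stochastic
#' effect by 0.05 percentage points.
#'
#' @param ed_msv Effective dose in mSv (non-negative).
#' @return Risk increment in percent.
#' @export
#' @examples
#' stochastic_risk_increment(10) # 0.05
stochastic_risk_increment <- function(ed_msv) {
  if (!is.numeric(ed_msv) || any(!is.finite(ed_msv)) || any(ed_msv < 0)) {
    stop("`ed_msv` must be non-negative and finite", call. = FALSE)
  }
  (ed_msv / 1000) * 5
}

#' Compute the full set of per-examination dose metrics
#'
#' Runs the whole per-record chain on a validated cohort table: BMI,
#' effective diameter, conversion factor, SSDE, ED, DLPss, EDss, the
#' fractional CTDIvol bias and the scan-length change (diagnostic minus
#' topogram). The outputs satisfy the algebraic identities
#' `dlp_ss/dlp = ssde/ctdi_vol = ed_ss/ed = k` exactly.
#'
#' @param records A cohort tibble in the [cohort_columns()] schema (e.g.
#'   from [read_cohort()] or [generate_cohort()]).
#' @param model A [conversion_model()].
#' @param coeffs Region coefficients, see [region_coefficients()].
#' @param clamp Passed to [k_factor()].
#' @return A tibble with one row per record: `exam_id`, `sex`, `region`,
#'   `bmi`, `deff_mm`, `k`, `ssde_mGy`, `ed_mSv`, `dlp_ss_mGycm`,
#'   `ed_ss_mSv`, `ctdi_bias`, `scan_length_change_mm`,
#'   `scan_length_change_pct`.
#' @export
compute_dose_metrics <- function(records,
                                 model = conversion_model(),
                                 coeffs = region_coefficients(),
                                 clamp = TRUE) {
  required <- c("exam_id", "sex", "weight_kg", "height_cm", "ap_mm", "lat_mm",
                "topogram_length_mm", "scan_length_mm", "ctdi_vol_mGy",
                "dlp_mGycm", "region")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop(sprintf("records are missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- withCallingHandlers(
    {
      bmi <- compute_bmi(records$weight_kg, records$height_cm)
      deff <- compute_deff(records$ap_mm, records$lat_mm)
      k <- k_factor(deff, model, clamp = clamp)
      tibble::tibble(
        exam_id = records$exam_id,
        sex = records$sex,
        region = records$region,
        bmi = bmi,
        deff_mm = deff,
        k = k,
        ssde_mGy = compute_ssde(records$ctdi_vol_mGy, k),
        ed_mSv = compute_ed(records$dlp_mGycm, records$region, coeffs),
        dlp_ss_mGycm = compute_dlpss(records$dlp_mGycm, k),
        ed_ss_mSv = compute_edss(compute_dlpss(records$dlp_mGycm, k),
                                 records$region, coeffs),
        ctdi_bias = 1 - 1 / k,
        scan_length_change_mm = records$scan_length_mm - records$topogram_length_mm,
        scan_length_change_pct = 100 *
          (records$scan_length_mm - records$topogram_length_mm) /
          records$topogram_length_mm
      )
    },
    error = function(e) {
      stop(sprintf("dose-metric computation failed for cohort (first exam_id: %s): %s",
                   records$exam_id[1], conditionMessage(e)), call. = FALSE)
    }
  )
  out
}
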