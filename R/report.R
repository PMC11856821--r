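# Report renderer: the six audit tables (mean / female / male / p layout)
# as CSV or Markdown, plus the two standard figures.

.fmt_table <- function(df, digits = 2) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, digits))
  df
}

.write_table <- function(df, path_base, format) {
  if (format == "csv") {
    path <- paste0(path_base, ".csv")
    readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  } else {
    path <- paste0(path_base, ".md")
    df <- .fmt_table(df)
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  path
}

#' Stratified mean/female/male/p table for a set of variables
#'
#' One row per variable: overall and per-sex mean +/- SD plus the
#' female-vs-male p-value from the normality-gated comparison
#' ([compare_groups()]). Comparison columns are `NA` when a sex stratum
#' has fewer than 3 records (e.g. a single-sex cohort).
#'
#' @param data Tibble with a `sex` column and the variables.
#' @param variables Character vector of numeric columns.
#' @param alpha Significance level for the comparisons.
#' @return Tibble: `variable`, `mean`, `sd`, `mean_female`, `sd_female`,
#'   `mean_male`, `sd_male`, `p_value`, `test_used`.
#' @export
stratified_table <- function(data, variables, alpha = 0.05) {
  summ <- summarize_cohort(data, variables, by = "sex")
  rows <- lapply(variables, function(v) {
    g <- function(stratum, col) {
      x <- summ[summ$variable == v & summ$stratum == stratum, ][[col]]
      if (length(x) == 0) NA_real_ else x
    }
    f <- data[[v]][data$sex == "female"]
    m <- data[[v]][data$sex == "male"]
    cmp <- if (sum(is.finite(f)) >= 3 && sum(is.finite(m)) >= 3) {
      compare_groups(f, m, alpha = alpha)
    } else NULL
    tibble::tibble(
      variable = v,
      mean = g("all", "mean"), sd = g("all", "sd"),
      mean_female = g("female", "mean"), sd_female = g("female", "sd"),
      mean_male = g("male", "mean"), sd_male = g("male", "sd"),
      p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
      test_used = if (is.null(cmp)) NA_character_ else cmp$test_used
    )
  })
  dplyr::bind_rows(rows)
}

#' Render the audit report
#'
#' Writes the six cohort tables to `output_dir`: anthropometrics, scan
#' lengths, cross-sectional dimensions, the CTDIvol correlation panel and
#' the traditional-vs-size-specific DLP and ED comparisons, plus the
#' scan-length audit and effective-diameter census summaries. Optionally
#' renders two figures (BMI vs Deff scatter with the Spearman rho
#' annotated; census bar chart). No multiple-testing correction is
#' applied: each comparison is reported at its own alpha, as is standard
#' in dose-audit reporting, and the report states so.
#'
#' @param metrics Cohort records joined with [compute_dose_metrics()]
#'   columns (e.g. `end_to_end_fixture()$metrics`).
#' @param output_dir Directory to write into (created if needed).
#' @param format `"csv"` (default) or `"md"`.
#' @param figures Render PNG figures (default `TRUE`).
#' @param reference_mm Census reference diameter.
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(metrics, output_dir, format = c("csv", "md"),
                          figures = TRUE, reference_mm = 320) {
  format <- match.arg(format)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  tab <- function(df, name) {
    .write_table(df, file.path(output_dir, name), format)
  }

  paths <- c(paths, tab(
    stratified_table(metrics, c("age_years", "weight_kg", "height_cm", "bmi")),
    "table1_anthropometrics"))
  paths <- c(paths, tab(
    stratified_table(metrics, c("topogram_length_mm", "scan_length_mm",
                                "scan_length_change_mm")),
    "table2_scan_length"))
  paths <- c(paths, tab(
    stratified_table(metrics, c("lat_mm", "ap_mm", "deff_mm")),
    "table3_dimensions"))
  paths <- c(paths, tab(
    correlation_panel(metrics,
                      c("age_years", "weight_kg", "height_cm", "bmi",
                        "lat_mm", "ap_mm", "deff_mm", "scan_length_mm"),
                      "ctdi_vol_mGy"),
    "table4_ctdivol_correlations"))
  cmp <- size_specific_comparison(metrics)
  paths <- c(paths, tab(
    cmp[, c("region", "stratum", "n", "dlp_mean", "dlpss_mean",
            "dlp_increase_pct", "p_sex_dlpss")],
    "table5_dlp_vs_dlpss"))
  paths <- c(paths, tab(
    cmp[, c("region", "stratum", "n", "ed_mean", "edss_mean",
            "ed_increase_pct", "p_sex_edss")],
    "table6_ed_vs_edss"))

  audit <- scan_length_audit(metrics)
  audit_df <- tibble::tibble(
    quantity = c("reduced_pct", "increased_pct", "unchanged_pct",
                 "mean_change_mm", "sd_change_mm", "mean_change_pct"),
    value = c(audit$fractions, audit$overall$change_mm[["mean"]],
              audit$overall$change_mm[["sd"]],
              audit$overall$change_pct[["mean"]])
  )
  paths <- c(paths, tab(audit_df, "scan_length_audit"))

  census <- deff_census(metrics$deff_mm, reference_mm)
  census_df <- tibble::tibble(
    quantity = c("fraction_below_pct", "fraction_not_below_pct",
                 "mean_deff_mm", "deviation_vs_reference_pct",
                 "deviation_vs_mean_pct"),
    value = c(census$fraction_below_pct, census$fraction_not_below_pct,
              census$mean_deff_mm, census$mean_deviation_pct[["vs_reference"]],
              census$mean_deviation_pct[["vs_mean"]])
  )
  paths <- c(paths, tab(census_df, "deff_census"))
  writeLines(
    "Each comparison is tested at its own alpha; no multiple-testing correction is applied.",
    file.path(output_dir, "NOTES.txt"))
  paths <- c(paths, file.path(output_dir, "NOTES.txt"))

  if (figures) {
    rho <- stats::cor(metrics$bmi, metrics$deff_mm, method = "spearman")
    p1 <- ggplot2::ggplot(metrics,
                          ggplot2::aes(x = .data$bmi, y = .data$deff_mm,
                                       colour = .data$sex)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.5, colour = "grey30") +
      ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                        label = sprintf("Spearman rho = %.2f", rho)) +
      ggplot2::labs(x = expression(BMI ~ (kg / m^2)),
                    y = "Effective diameter (mm)") +
      ggplot2::theme_minimal()
    f1 <- file.path(output_dir, "fig_bmi_deff.png")
    ggplot2::ggsave(f1, p1, width = 6, height = 4, dpi = 120)
    census_bar <- tibble::tibble(
      bin = factor(c("below reference", "at or above"),
                   levels = c("below reference", "at or above")),
      pct = c(census$fraction_below_pct, census$fraction_not_below_pct))
    p2 <- ggplot2::ggplot(census_bar, ggplot2::aes(x = .data$bin, y = .data$pct)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = sprintf("Deff vs %g mm reference", reference_mm),
                    y = "Examinations (%)") +
      ggplot2::theme_minimal()
    f2 <- file.path(output_dir, "fig_deff_census.png")
    ggplot2::ggsave(f2, p2, width = 4, height = 4, dpi = 120)
    paths <- c(paths, f1, f2)
  }
  invisible(paths)
}
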