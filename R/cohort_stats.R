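# Cohort-level analyses: stratified summaries, normality-gated two-group
# comparisons, Spearman correlation panels, the scan-length audit, the
# effective-diameter census and traditional-vs-size-specific comparisons.

#' Sex-stratified summary table
#'
#' Mean, SD, min and max per variable, overall and per stratum (Table-style
#' mean/female/male layout). A stratum with a single record reports its
#' mean with SD marked unavailable (`NA`); an empty stratum is emitted as
#' an explicit row with `n = 0` and all statistics `NA`, never as zeros.
#'
#' @param data Tibble holding the variables (cohort records, metrics, or a
#'   join of both).
#' @param variables Character vector of numeric columns to summarise.
#' @param by Optional stratification column (default `"sex"`); `NULL`
#'   summarises the whole table only.
#' @return Tibble with columns `variable`, `stratum` (`"all"` plus the
#'   levels of `by`), `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_cohort <- function(data, variables, by = "sex") {
  stopifnot(all(variables %in% names(data)))
  strata <- list(all = rep(TRUE, nrow(data)))
  if (!is.null(by)) {
    stopifnot(by %in% names(data))
    for (lev in sort(unique(stats::na.omit(data[[by]])))) {
      strata[[lev]] <- data[[by]] == lev
    }
  }
  rows <- lapply(variables, function(v) {
    dplyr::bind_rows(lapply(names(strata), function(s) {
      x <- data[[v]][strata[[s]]]
      x <- x[is.finite(x)]
      n <- length(x)
      tibble::tibble(
        variable = v, stratum = s, n = n,
        mean = if (n > 0) mean(x) else NA_real_,
        sd = if (n > 1) stats::sd(x) else NA_real_,
        min = if (n > 0) min(x) else NA_real_,
        max = if (n > 0) max(x) else NA_real_
      )
    }))
  })
  dplyr::bind_rows(rows)
}

#' Normality-gated two-group comparison
#'
#' The study protocol's comparison rule: Shapiro-Wilk on each group, then a
#' two-sided Welch t-test if both groups are compatible with normality at
#' `alpha`, otherwise a two-sided Mann-Whitney U test. A group with zero
#' variance cannot be tested for normality and routes to the rank test.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @param alpha Significance level used both for the normality gate and
#'   reported alongside the result (default 0.05).
#' @return One-row tibble: `test_used` (`"student_t"` or
#'   `"mann_whitney_u"`), `statistic`, `p_value`, `normality_p_a`,
#'   `normality_p_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("compare_groups needs at least 3 finite values per group",
         call. = FALSE)
  }
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    stats::shapiro.test(x)$p.value
  }
  pa <- shapiro_p(values_a)
  pb <- shapiro_p(values_b)
  normal <- !is.na(pa) && !is.na(pb) && pa >= alpha && pb >= alpha
  if (normal) {
    ht <- stats::t.test(values_a, values_b)  # Welch form
    test_used <- "student_t"
  } else if (stats::sd(c(values_a, values_b)) == 0) {
    # both groups constant at the same value: no evidence of a difference
    ht <- list(statistic = c(W = 0), p.value = 1)
    test_used <- "mann_whitney_u"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE))
    test_used <- "mann_whitney_u"
  }
  tibble::tibble(
    test_used = test_used,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    normality_p_a = pa, normality_p_b = pb,
    n_a = length(values_a), n_b = length(values_b),
    mean_a = mean(values_a), mean_b = mean(values_b),
    sd_a = stats::sd(values_a), sd_b = stats::sd(values_b)
  )
}

#' Spearman correlation panel
#'
#' Spearman rank correlations of each variable in `x_vars` against
#' `y_var`, overall and optionally per stratum (Table-4 layout: CTDIvol
#' against each anthropometric parameter, by sex). Uses the exact p-value
#' method below n = 30 and the large-sample approximation otherwise. A
#' constant variable yields `rho = NA` with `flag = "constant"`.
#'
#' @param data Tibble holding the variables.
#' @param x_vars Character vector of predictor columns.
#' @param y_var Single response column.
#' @param by Optional stratification column (default `"sex"`; `NULL` for
#'   overall only).
#' @return Tibble: `x`, `y`, `stratum`, `n`, `rho`, `p_value`, `flag`.
#' @export
correlation_panel <- function(data, x_vars, y_var, by = "sex") {
  stopifnot(all(c(x_vars, y_var) %in% names(data)))
  strata <- list(all = rep(TRUE, nrow(data)))
  if (!is.null(by)) {
    for (lev in sort(unique(stats::na.omit(data[[by]])))) {
      strata[[lev]] <- data[[by]] == lev
    }
  }
  rows <- list()
  for (s in names(strata)) {
    for (x in x_vars) {
      xv <- data[[x]][strata[[s]]]
      yv <- data[[y_var]][strata[[s]]]
      ok <- is.finite(xv) & is.finite(yv)
      xv <- xv[ok]; yv <- yv[ok]
      n <- length(xv)
      if (n < 3) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          x = x, y = y_var, stratum = s, n = n, rho = NA_real_,
          p_value = NA_real_, flag = "insufficient_n")
        next
      }
      if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          x = x, y = y_var, stratum = s, n = n, rho = NA_real_,
          p_value = NA_real_, flag = "constant")
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(xv, yv, method = "spearman", exact = n < 30))
      rows[[length(rows) + 1]] <- tibble::tibble(
        x = x, y = y_var, stratum = s, n = n,
        rho = unname(ct$estimate), p_value = ct$p.value, flag = NA_character_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Scan-length audit
#'
#' Compares the diagnostic scan range against the topogram length for each
#' examination. Change is `diagnostic - topogram` (negative = the operator
#' shortened the range). Reports the percent of examinations with reduced,
#' increased and unchanged range, mean +/- SD change (mm and percent of
#' topogram), per-sex breakdowns, and the sex comparison via
#' [compare_groups()].
#'
#' @param records Cohort tibble with `topogram_length_mm`,
#'   `scan_length_mm`, `sex`.
#' @param alpha Significance level for the sex comparison.
#' @return An object of class `scan_length_audit`: a list with elements
#'   `fractions` (percent reduced/increased/unchanged), `overall` and
#'   `by_sex` (mean/sd of the mm and percent change), and `sex_comparison`
#'   (`NULL` when a sex has fewer than 3 records).
#' @export
scan_length_audit <- function(records, alpha = 0.05) {
  change <- records$scan_length_mm - records$topogram_length_mm
  change_pct <- 100 * change / records$topogram_length_mm
  n <- length(change)
  fractions <- c(
    reduced = 100 * sum(change < 0) / n,
    increased = 100 * sum(change > 0) / n,
    unchanged = 100 * sum(change == 0) / n
  )
  summ <- function(x) c(n = length(x), mean = mean(x),
                        sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  by_sex <- lapply(split(seq_len(n), records$sex), function(i) {
    list(change_mm = summ(change[i]), change_pct = summ(change_pct[i]))
  })
  sexes <- names(by_sex)
  comparison <- NULL
  if (length(sexes) == 2 &&
      all(vapply(split(change, records$sex), length, 1L) >= 3)) {
    groups <- split(change, records$sex)
    comparison <- compare_groups(groups[[1]], groups[[2]], alpha = alpha)
    comparison$group_a <- sexes[1]
    comparison$group_b <- sexes[2]
  }
  structure(
    list(fractions = fractions,
         overall = list(change_mm = summ(change), change_pct = summ(change_pct)),
         by_sex = by_sex,
         sex_comparison = comparison),
    class = "scan_length_audit"
  )
}

#' @export
print.scan_length_audit <- function(x, ...) {
  cat(sprintf("Scan-length audit (n = %d)\n",
              as.integer(x$overall$change_mm["n"])))
  cat(sprintf("  reduced %.1f%%, increased %.1f%%, unchanged %.1f%%\n",
              x$fractions["reduced"], x$fractions["increased"],
              x$fractions["unchanged"]))
  cat(sprintf("  mean change %.2f mm (SD %.2f)\n",
              x$overall$change_mm["mean"], x$overall$change_mm["sd"]))
  invisible(x)
}

#' Effective-diameter census against the reference phantom
#'
#' Fraction of examinations whose effective diameter falls below the
#' reference phantom diameter (default 320 mm, the 32-cm body phantom).
#' A diameter exactly at the reference counts in the "not smaller" bin.
#' The mean deviation from the reference is reported under both
#' normalisation bases, since either appears in audit practice:
#' `vs_reference` = (reference - mean Deff)/reference and `vs_mean` =
#' (reference - mean Deff)/mean Deff.
#'
#' @param deff_mm Numeric vector of effective diameters (mm).
#' @param reference_mm Reference phantom diameter in mm.
#' @return An object of class `deff_census`: list with
#'   `fraction_below_pct`, `fraction_not_below_pct`, `reference_mm`, `n`,
#'   `mean_deff_mm`, and `mean_deviation_pct` (named `vs_reference`,
#'   `vs_mean`).
#' @export
deff_census <- function(deff_mm, reference_mm = 320) {
  .check_positive(deff_mm, "deff_mm")
  .check_positive(reference_mm, "reference_mm")
  n <- length(deff_mm)
  below <- sum(deff_mm < reference_mm)
  m <- mean(deff_mm)
  structure(
    list(
      fraction_below_pct = 100 * below / n,
      fraction_not_below_pct = 100 * (n - below) / n,
      reference_mm = reference_mm, n = n, mean_deff_mm = m,
      mean_deviation_pct = c(vs_reference = 100 * (reference_mm - m) / reference_mm,
                             vs_mean = 100 * (reference_mm - m) / m)
    ),
    class = "deff_census"
  )
}

#' @export
print.deff_census <- function(x, ...) {
  cat(sprintf("Deff census vs %g mm reference (n = %d)\n", x$reference_mm, x$n))
  cat(sprintf("  below: %.1f%%, at or above: %.1f%%\n",
              x$fraction_below_pct, x$fraction_not_below_pct))
  cat(sprintf("  mean Deff %.1f mm; deviation %.1f%% of reference, %.1f%% of mean\n",
              x$mean_deff_mm, x$mean_deviation_pct["vs_reference"],
              x$mean_deviation_pct["vs_mean"]))
  invisible(x)
}

#' Traditional versus size-specific dose comparison
#'
#' Per region (and overall/female/male strata): mean DLP vs DLPss and mean
#' ED vs EDss with the percent increase of the size-specific index over
#' the traditional one, plus the female-male comparison p-value for the
#' size-specific indices (Tables 5-6 layout).
#'
#' @param metrics Output of [compute_dose_metrics()] joined with
#'   `dlp_mGycm` (e.g. via [write_metrics()]'s join, or pass the metrics
#'   tibble plus records). Must hold `sex`, `region`, `dlp_mGycm`,
#'   `dlp_ss_mGycm`, `ed_mSv`, `ed_ss_mSv`.
#' @param regions Regions to tabulate; absent regions are skipped with a
#'   message.
#' @param alpha Significance level for the sex comparisons.
#' @return Tibble: `region`, `stratum`, `n`, `dlp_mean`, `dlpss_mean`,
#'   `dlp_increase_pct`, `ed_mean`, `edss_mean`, `ed_increase_pct`,
#'   `p_sex_dlpss`, `p_sex_edss` (p-values on the `"all"` rows only).
#' @export
size_specific_comparison <- function(metrics,
                                     regions = c("abdomen_pelvis", "chest"),
                                     alpha = 0.05) {
  needed <- c("sex", "region", "dlp_mGycm", "dlp_ss_mGycm", "ed_mSv", "ed_ss_mSv")
  stopifnot(all(needed %in% names(metrics)))
  out <- list()
  for (reg in regions) {
    sub <- metrics[metrics$region == reg, , drop = FALSE]
    if (nrow(sub) == 0) {
      message(sprintf("region '%s' absent from metrics; skipped", reg))
      next
    }
    strata <- c(list(all = rep(TRUE, nrow(sub))),
                lapply(split(seq_len(nrow(sub)), sub$sex),
                       function(i) seq_len(nrow(sub)) %in% i))
    p_dlpss <- p_edss <- NA_real_
    groups <- split(seq_len(nrow(sub)), sub$sex)
    if (length(groups) == 2 && all(vapply(groups, length, 1L) >= 3)) {
      p_dlpss <- compare_groups(sub$dlp_ss_mGycm[groups[[1]]],
                                sub$dlp_ss_mGycm[groups[[2]]], alpha)$p_value
      p_edss <- compare_groups(sub$ed_ss_mSv[groups[[1]]],
                               sub$ed_ss_mSv[groups[[2]]], alpha)$p_value
    }
    for (s in names(strata)) {
      x <- sub[strata[[s]], , drop = FALSE]
      out[[length(out) + 1]] <- tibble::tibble(
        region = reg, stratum = s, n = nrow(x),
        dlp_mean = mean(x$dlp_mGycm),
        dlpss_mean = mean(x$dlp_ss_mGycm),
        dlp_increase_pct = percent_increase(mean(x$dlp_ss_mGycm),
                                            mean(x$dlp_mGycm)),
        ed_mean = mean(x$ed_mSv),
        edss_mean = mean(x$ed_ss_mSv),
        ed_increase_pct = percent_increase(mean(x$ed_ss_mSv), mean(x$ed_mSv)),
        p_sex_dlpss = if (s == "all") p_dlpss else NA_real_,
        p_sex_edss = if (s == "all") p_edss else NA_real_
      )
    }
  }
  dplyr::bind_rows(out)
}
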