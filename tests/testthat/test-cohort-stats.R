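test_that("stratified summaries handle degenerate strata explicitly", {
  d <- tibble::tibble(sex = c("female", "female", "male"),
                      x = c(4, 4, 7))
  s <- summarize_cohort(d, "x")
  expect_equal(s$sd[s$stratum == "female"], 0)
  # single-record stratum: mean present, SD marked unavailable
  expect_equal(s$mean[s$stratum == "male"], 7)
  expect_true(is.na(s$sd[s$stratum == "male"]))
  expect_equal(s$n[s$stratum == "all"], 3)

  # empty stratum is an explicit NA row, never a zero
  s2 <- summarize_cohort(d[d$sex == "female", ], "x", by = "sex")
  expect_false("male" %in% s2$stratum)
  expect_equal(nrow(s2[s2$stratum == "female", ]), 1)
})

test_that("normality gate selects the t-test for normal data and ranks otherwise", {
  set.seed(11)
  a <- rnorm(200, 0, 1)
  b <- rnorm(200, 0.5, 1)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$test_used, "student_t")
  expect_lt(cmp$p_value, 0.05)

  heavy <- rcauchy(200)
  cmp2 <- compare_groups(a, heavy)
  expect_equal(cmp2$test_used, "mann_whitney_u")
  expect_true(cmp2$p_value >= 0 && cmp2$p_value <= 1)

  # identical groups: no difference
  cmp3 <- compare_groups(a, a)
  expect_equal(cmp3$p_value, 1, tolerance = 1e-8)

  # symmetry under group exchange
  cmp4 <- compare_groups(b, a)
  expect_equal(cmp4$p_value, cmp$p_value)
  expect_equal(cmp4$statistic, -cmp$statistic)

  expect_error(compare_groups(a, c(1, 2)), "at least 3")
})

test_that("Spearman panel is invariant under monotone transforms", {
  set.seed(21)
  d <- tibble::tibble(sex = rep(c("female", "male"), each = 25),
                      x = rnorm(50), z = rnorm(50))
  d$y <- exp(2 * d$x)          # strictly increasing transform of x
  d$neg <- -d$x^3              # strictly decreasing transform
  pan <- correlation_panel(d, c("y", "neg"), "x")
  expect_equal(pan$rho[pan$x == "y"], rep(1, 3))
  expect_equal(pan$rho[pan$x == "neg"], rep(-1, 3))

  # transform invariance for noisy pairs too
  r1 <- correlation_panel(d, "z", "x", by = NULL)$rho
  d$z2 <- qlogis(plogis(d$z))  # monotone, numerically identical ranks
  d$x2 <- d$x^3
  r2 <- correlation_panel(d, "z2", "x2", by = NULL)$rho
  expect_equal(r1, r2)

  d$const <- 5
  flagged <- correlation_panel(d, "const", "x", by = NULL)
  expect_true(is.na(flagged$rho))
  expect_equal(flagged$flag, "constant")
})

test_that("scan-length audit bins changes and fractions sum to 100", {
  rec <- make_records(12)
  rec$scan_length_mm <- rec$topogram_length_mm
  a <- scan_length_audit(rec)
  expect_equal(unname(a$fractions), c(0, 0, 100))
  expect_equal(a$overall$change_mm[["mean"]], 0)

  rec2 <- make_records(40)
  a2 <- scan_length_audit(rec2)
  expect_equal(sum(a2$fractions), 100, tolerance = 0.1)
  expect_equal(a2$overall$change_mm[["mean"]],
               mean(rec2$scan_length_mm - rec2$topogram_length_mm))
  expect_s3_class(a2$sex_comparison, "tbl_df")
  expect_output(print(a2), "Scan-length audit")
})

test_that("effective-diameter census counts ties as not-smaller", {
  c1 <- deff_census(rep(319, 10))
  expect_equal(c1$fraction_below_pct, 100)
  c2 <- deff_census(c(320, 320, 310, 330))
  expect_equal(c2$fraction_below_pct, 25)   # ties bin with "not smaller"
  expect_equal(c2$fraction_below_pct + c2$fraction_not_below_pct, 100)
  # deviation reported under both normalisation bases
  c3 <- deff_census(rep(290.44, 5))
  expect_equal(c3$mean_deviation_pct[["vs_reference"]],
               100 * (320 - 290.44) / 320)
  expect_equal(c3$mean_deviation_pct[["vs_mean"]],
               100 * (320 - 290.44) / 290.44)
})

test_that("size-specific comparison degenerates to zero at reference size", {
  ref <- make_reference_size_record()
  rec <- dplyr::bind_rows(lapply(1:8, function(i) {
    r <- ref
    r$exam_id <- sprintf("r-%02d", i)
    r$sex <- if (i %% 2) "female" else "male"
    r$dlp_mGycm <- 400 + 10 * i
    r
  }))
  met <- compute_dose_metrics(rec)
  joined <- dplyr::left_join(rec,
                             met[setdiff(names(met), c("sex", "region"))],
                             by = "exam_id")
  cmp <- size_specific_comparison(joined)
  expect_equal(cmp$dlp_increase_pct, rep(0, 3), tolerance = 1e-9)
  expect_equal(cmp$ed_increase_pct, rep(0, 3), tolerance = 1e-9)
  expect_message(size_specific_comparison(joined, regions = "chest"),
                 "absent")
})

test_that("summarised mean DLPss stays inside the per-record k envelope", {
  rec <- make_records(60)
  met <- compute_dose_metrics(rec)
  mean_dlp <- mean(rec$dlp_mGycm)
  mean_dlpss <- mean(met$dlp_ss_mGycm)
  expect_lte(mean_dlpss, mean_dlp * max(met$k))
  expect_gte(mean_dlpss, mean_dlp * min(met$k))
})

test_that("stratified table reports means, SDs and gated p-values per variable", {
  rec <- make_records(30)
  tab <- stratified_table(rec, c("weight_kg", "height_cm"))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$test_used %in% c("student_t", "mann_whitney_u")))
  expect_equal(tab$mean[1], mean(rec$weight_kg))
  # single-sex data: comparison columns unavailable, not fabricated
  tab2 <- stratified_table(rec[rec$sex == "female", ], "weight_kg")
  expect_true(is.na(tab2$p_value))
})
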