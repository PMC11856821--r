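test_that("BMI and effective diameter follow their defining formulas", {
  expect_equal(compute_bmi(100, 200), 25.0)
  # cohort-mean anthropometrics; note mean-of-BMI != BMI-of-means
  expect_equal(round(compute_bmi(74.88, 170.04), 2), 25.90)
  expect_equal(round(compute_bmi(69.19, 162.06), 2), 26.34)

  expect_equal(compute_deff(300, 300), 300)
  expect_equal(round(compute_deff(240.63, 350.30), 2), 290.33)
  expect_equal(round(compute_deff(150.91, 280.00), 2), 205.56)

  expect_error(compute_bmi(-1, 170), "weight_kg")
  expect_error(compute_bmi(70, 0), "height_cm")
  expect_error(compute_deff(0, 300), "ap_mm")
})

test_that("k factor: closed-form crossing, monotonicity and table agreement", {
  m <- conversion_model("body32")
  deff_star_mm <- 10 * log(m$coeff_a) / m$coeff_b
  expect_equal(k_factor(deff_star_mm, m), 1, tolerance = 1e-12)

  # strictly decreasing over the validity range
  grid <- seq(60, 550, by = 5)
  ks <- k_factor(grid, m)
  expect_true(all(diff(ks) < 0))

  # fit evaluation at named diameters
  expect_equal(k_factor(320, m), m$coeff_a * exp(-32 * m$coeff_b))
  expect_equal(k_factor(290.44, m), m$coeff_a * exp(-29.044 * m$coeff_b))

  # packaged table interpolation tracks the fit within 0.01 everywhere
  mt <- conversion_model("body32", mode = "table")
  probe <- seq(60, 550, by = 2.5)
  expect_lt(max(abs(k_factor(probe, mt) - k_factor(probe, m))), 0.01)

  for (ph in c("body32", "head16")) {
    tab <- aapm204_k_table(ph)
    fit <- conversion_model(ph)
    expect_lt(max(abs(tab$k - k_factor(tab$deff_cm * 10, fit))), 0.01)
  }
})

test_that("k factor range handling clamps with warning or errors in strict mode", {
  m <- conversion_model("body32")
  expect_warning(k_low <- k_factor(30, m), "clamped")
  expect_equal(k_low, k_factor(60, m))
  expect_error(k_factor(30, m, clamp = FALSE), "validity range")
  expect_silent(k_factor(300, m))
})

test_that("dose products are linear and the ED coefficients resolve by region", {
  expect_equal(compute_ssde(10, 1), 10)
  expect_equal(round(compute_ssde(11.37, 1.2234), 2), 13.91)
  expect_equal(compute_ssde(5.86, 1.5), 8.79)

  expect_equal(compute_ed(100, "abdomen_pelvis"), 1.5)
  expect_equal(compute_dlpss(500, 1), 500)
  expect_equal(round(compute_dlpss(514.88, 1.2194), 2), 627.84)
  expect_equal(round(compute_dlpss(165, 1.5856), 2), 261.62)
  expect_equal(compute_edss(1000, "abdomen_pelvis"), 15)

  # doubling DLP doubles every downstream quantity
  k <- 1.21
  expect_equal(compute_dlpss(2 * 400, k), 2 * compute_dlpss(400, k))
  expect_equal(compute_ed(2 * 400, "chest"), 2 * compute_ed(400, "chest"))

  expect_error(compute_ed(0, "abdomen_pelvis"), "dlp")
  expect_error(compute_ed(100, "pelvis_only"), "no f coefficient")
  expect_error(region_coefficients(chest = -1), "positive")
  # chest default is overridable
  co <- region_coefficients(chest = 0.017)
  expect_equal(compute_ed(100, "chest", co), 1.7)
})

test_that("percent increase and stochastic risk follow their conventions", {
  expect_equal(round(percent_increase(9.42, 7.72), 0), 22)
  expect_equal(percent_increase(5, 5), 0)
  expect_equal(round(percent_increase(627.83, 514.88), 2), 21.94)
  expect_error(percent_increase(5, 0), "old_value")

  expect_equal(stochastic_risk_increment(10), 0.05)
  expect_equal(stochastic_risk_increment(0), 0)
  expect_equal(stochastic_risk_increment(1000), 5)
  expect_error(stochastic_risk_increment(-1), "non-negative")
})

test_that("CTDIvol bias is zero at reference size and flips sign across it", {
  m <- conversion_model("body32")
  deff_star <- 10 * log(m$coeff_a) / m$coeff_b
  expect_equal(ctdi_bias(deff_star, m), 0, tolerance = 1e-12)
  # small patient: CTDIvol underestimates (positive bias)
  expect_equal(ctdi_bias(210.14, m), 1 - 1 / k_factor(210.14, m))
  expect_gt(ctdi_bias(210.14, m), 0)
  # large patient: overestimation
  expect_lt(ctdi_bias(410.12, m), 0)
})

test_that("per-record metric chain satisfies the size-correction identities", {
  rec <- make_records(40)
  met <- compute_dose_metrics(rec)
  expect_equal(met$dlp_ss_mGycm / rec$dlp_mGycm, met$k, tolerance = 1e-12)
  expect_equal(met$ssde_mGy / rec$ctdi_vol_mGy, met$k, tolerance = 1e-12)
  expect_equal(met$ed_ss_mSv / met$ed_mSv, met$k, tolerance = 1e-12)
  expect_equal(met$scan_length_change_mm,
               rec$scan_length_mm - rec$topogram_length_mm)

  # reference-size record: every size correction is the identity
  ref <- make_reference_size_record(dlp = 500)
  mref <- compute_dose_metrics(ref)
  expect_equal(mref$k, 1, tolerance = 1e-12)
  expect_equal(mref$dlp_ss_mGycm, 500, tolerance = 1e-9)
  expect_equal(mref$ed_ss_mSv, mref$ed_mSv, tolerance = 1e-12)

  ref$topogram_length_mm <- ref$scan_length_mm
  expect_equal(compute_dose_metrics(ref)$scan_length_change_mm, 0)

  bad <- rec
  bad$weight_kg[3] <- -1
  expect_error(compute_dose_metrics(bad), "weight_kg")
  expect_error(compute_dose_metrics(rec[, -4]), "missing column")
})
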