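test_that("packaged example cohort reads cleanly and round-trips", {
  path <- system.file("extdata", "example_cohort.csv", package = "ssdose")
  coh <- read_cohort(path)
  expect_equal(nrow(coh), 6)
  expect_equal(nrow(attr(coh, "row_errors")), 0)
  expect_identical(names(coh), cohort_columns())

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, tmp)
  again <- read_cohort(tmp)
  expect_equal(as.data.frame(again), as.data.frame(coh), tolerance = 1e-12)
})

test_that("malformed rows are reported with row numbers, not dropped silently", {
  rec <- make_records(6)
  rec$weight_kg[2] <- -5
  rec$ctdi_vol_mGy[5] <- NA
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(rec, tmp)
  coh <- read_cohort(tmp)
  errs <- attr(coh, "row_errors")
  expect_equal(nrow(coh), 4)
  expect_setequal(errs$row, c(2, 5))
  expect_true(any(errs$field == "weight_kg" & errs$row == 2))

  # unparseable numerics are row errors, and missing columns hard errors
  lines <- readLines(tmp)
  lines[4] <- sub("^t-003,female,[0-9]+", "t-003,female,sixty", lines[4])
  writeLines(lines, tmp)
  coh2 <- read_cohort(tmp)
  expect_true(any(grepl("unparseable", attr(coh2, "row_errors")$message)))

  rec2 <- make_records(3)
  rec2$ctdi_vol_mGy <- NULL
  write_cohort_csv(rec2, tmp)
  expect_error(read_cohort(tmp), "missing required column")
})

test_that("schema-level invariants: unique ids and phantom/region consistency", {
  rec <- make_records(4)
  rec$exam_id[2] <- rec$exam_id[1]
  rec$phantom[3] <- "head16"
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(rec, tmp)
  coh <- read_cohort(tmp)
  errs <- attr(coh, "row_errors")
  expect_true(all(c(1, 2) %in% errs$row[errs$field == "exam_id"]))
  expect_true(3 %in% errs$row[errs$field == "phantom"])
  expect_equal(nrow(coh), 1)
})

test_that("inclusion window is closed at both BMI bounds", {
  rec <- make_records(4)
  rec$height_cm <- 200
  rec$weight_kg <- c(17.9, 18.0, 35.0, 35.1) * 4  # BMI = weight / 4 at 2 m
  rec$age_years <- 50
  kept <- apply_inclusion(rec, inclusion_policy())
  expect_setequal(kept$exam_id, rec$exam_id[2:3])
  excl <- attr(kept, "exclusions")
  expect_equal(sum(excl$n), 2)
  expect_setequal(excl$reason, c("bmi_below_min", "bmi_above_max"))
})

test_that("flagged and underage records are excluded with reason codes", {
  rec <- make_records(5)
  rec$exclusion_flags[2] <- "ascites"
  rec$exclusion_flags[4] <- "motion_artifact;ascites"
  rec$age_years[5] <- 16
  kept <- apply_inclusion(rec)
  expect_setequal(kept$exam_id, rec$exam_id[c(1, 3)])
  excl <- attr(kept, "exclusions")
  expect_equal(excl$n[excl$reason == "ascites"], 1)
  expect_equal(excl$n[excl$reason == "motion_artifact"], 1)
  expect_equal(excl$n[excl$reason == "underage"], 1)
  # exclusion counts plus retained count conserve the input count
  expect_equal(sum(excl$n) + nrow(kept), nrow(rec))
})

test_that("inclusion filtering is idempotent and identity on a clean table", {
  rec <- make_records(8)
  strip <- function(x) {
    attributes(x)[c("exclusions", "row_errors")] <- NULL
    as.data.frame(x)
  }
  once <- apply_inclusion(rec)
  twice <- apply_inclusion(once)
  expect_equal(strip(twice), strip(once))
  expect_equal(nrow(attr(once, "exclusions")), 0)
  expect_equal(strip(once), strip(rec))
})

test_that("metrics round-trip through write_metrics at full precision", {
  rec <- make_records(3)
  met <- compute_dose_metrics(rec)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_metrics(rec, met, tmp)
  back <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_equal(nrow(back), 3)
  expect_true(all(c("ed_ss_mSv", "ed_ss_mSv_2dp") %in% names(back)))
  expect_equal(back$ed_ss_mSv, met$ed_ss_mSv, tolerance = 1e-9)
  expect_equal(back$k, met$k, tolerance = 1e-9)
  expect_identical(names(back)[seq_along(cohort_columns())], cohort_columns())

  # empty cohort: header-only file
  empty <- rec[0, ]
  write_metrics(empty, met[0, ], tmp)
  expect_equal(nrow(readr::read_csv(tmp, show_col_types = FALSE)), 0)
})
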