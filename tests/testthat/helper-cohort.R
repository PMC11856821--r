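# In-code fixtures shared across test files.

# A small deterministic cohort in the canonical schema.
make_records <- function(n = 6) {
  set.seed(99)
  sex <- rep(c("female", "male"), length.out = n)
  height <- ifelse(sex == "female", 162, 177) + rnorm(n, 0, 4)
  weight <- ifelse(sex == "female", 69, 80) + rnorm(n, 0, 6)
  deff <- 290 + rnorm(n, 0, 30)
  ratio <- 1.45
  topo <- 480 + rnorm(n, 0, 20)
  ctdi <- 11 + rnorm(n, 0, 2)
  scan <- topo + rnorm(n, -10, 25)
  tibble::tibble(
    exam_id = sprintf("t-%03d", seq_len(n)),
    sex = sex,
    age_years = round(60 + rnorm(n, 0, 8)),
    weight_kg = weight,
    height_cm = height,
    ap_mm = deff / sqrt(ratio),
    lat_mm = deff * sqrt(ratio),
    topogram_length_mm = topo,
    scan_length_mm = scan,
    ctdi_vol_mGy = ctdi,
    dlp_mGycm = ctdi * scan / 10,
    region = "abdomen_pelvis",
    phantom = "body32",
    exclusion_flags = ""
  )
}

# A record whose AP = LAT = the k = 1 crossing diameter of the default
# body-phantom model, so every size correction is the identity.
make_reference_size_record <- function(dlp = 500) {
  m <- conversion_model()
  deff_star <- 10 * log(m$coeff_a) / m$coeff_b
  rec <- make_records(1)
  rec$ap_mm <- deff_star
  rec$lat_mm <- deff_star
  rec$dlp_mGycm <- dlp
  rec
}

write_cohort_csv <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  path
}
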