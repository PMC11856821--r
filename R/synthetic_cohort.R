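# Synthetic abdominal-CT cohort generator. Emulates the statistical
# structure the audit pipeline assumes: sex-stratified anthropometrics,
# a BMI window, the linear BMI->effective-diameter relationship
# Deff_cm = 0.79*BMI + 9.4 with calibrated residual noise, tube-current
# modulation (CTDIvol growing exponentially with diameter), and topogram
# vs diagnostic scan-length behaviour.

#' Simulation configuration for a synthetic CT cohort
#'
#' All distribution parameters of [generate_cohort()], with defaults set to
#' the study conditions of a sex-stratified adult abdominal-pelvic CT
#' cohort. Per-sex anthropometric targets are the *post-inclusion* cohort
#' moments (age, weight, height mean/SD); because the BMI window truncates
#' the joint weight-height distribution, the parent (pre-window) weight
#' distribution is shifted/scaled by the `weight_parent_*` calibration
#' fields so the retained cohort reproduces the targets (see
#' [calibrate_parent_moments()]).
#'
#' @param n Number of examinations.
#' @param seed Integer seed; the generator is fully deterministic given
#'   `config` (same config, same cohort).
#' @param sex_fraction_female Probability a record is female (default
#'   113/247).
#' @param female,male Per-sex parameter lists with elements `age`,
#'   `weight`, `height`, `topogram` (each `c(mean, sd)`; heights cm,
#'   weights kg, lengths mm), `change_sd` (mm, scan-length change
#'   magnitude scale), and `weight_parent_shift` / `height_parent_shift`
#'   (kg and cm added to the parent means to undo the selection bias of
#'   the BMI window; see [calibrate_parent_moments()]). Post-window SDs
#'   run slightly below the parent SDs (truncation shrinkage) and are not
#'   force-matched.
#' @param weight_height_cor Parent weight-height correlation (default 0.5).
#' @param bmi_range Closed BMI inclusion window (default `c(18, 35)`).
#' @param deff_slope,deff_intercept Linear map from BMI to effective
#'   diameter in cm (defaults 0.79 and 9.4).
#' @param deff_residual_sd Residual SD (cm) around that line; the default
#'   is calibrated so a cohort of `n = 247` yields a BMI-Deff Spearman
#'   correlation near 0.78 (see [calibrate_residual_sd()]).
#' @param aspect_ratio_mean Mean LAT/AP aspect ratio of the abdominal
#'   cross-section (default 350.30/240.63).
#' @param aspect_log_sd SD of the log aspect ratio.
#' @param ctdi_base,ctdi_coef,ctdi_log_sd CTDIvol model
#'   `base * exp(coef * Deff_cm) * lognormal(0, log_sd)` in mGy; defaults
#'   tuned so the default cohort's mean CTDIvol is about 11.4 mGy with a
#'   CTDIvol-Deff rank correlation near 0.9.
#' @param change_probs Probabilities that the diagnostic range is reduced,
#'   increased or unchanged relative to the topogram (default
#'   `c(0.538, 0.457, 0.005)`).
#' @param region,phantom Constant columns for the generated records.
#' @return A `simulation_config` object (a validated list).
#' @export
simulation_config <- function(
    n = 247,
    seed = 1L,
    sex_fraction_female = 113 / 247,
    female = list(age = c(65.89, 12.91), weight = c(69.19, 13.24),
                  height = c(162.06, 6.33), topogram = c(476.98, 44.19),
                  change_sd = 57.4,
                  weight_parent_shift = -0.433, height_parent_shift = -0.124),
    male = list(age = c(63.15, 13.15), weight = c(79.67, 17.40),
                height = c(176.77, 6.77), topogram = c(493.10, 43.93),
                change_sd = 68.99,
                weight_parent_shift = -2.178, height_parent_shift = -0.321),
    weight_height_cor = 0.5,
    bmi_range = c(18, 35),
    deff_slope = 0.79,
    deff_intercept = 9.4,
    deff_residual_sd = 2.38,
    aspect_ratio_mean = 350.30 / 240.63,
    aspect_log_sd = 0.07,
    ctdi_base = 1.84,
    ctdi_coef = 0.06,
    ctdi_log_sd = 0.12,
    change_probs = c(reduced = 0.538, increased = 0.457, unchanged = 0.005),
    region = "abdomen_pelvis",
    phantom = "body32") {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              sex_fraction_female = sex_fraction_female,
              female = female, male = male,
              weight_height_cor = weight_height_cor,
              bmi_range = bmi_range,
              deff_slope = deff_slope, deff_intercept = deff_intercept,
              deff_residual_sd = deff_residual_sd,
              aspect_ratio_mean = aspect_ratio_mean,
              aspect_log_sd = aspect_log_sd,
              ctdi_base = ctdi_base, ctdi_coef = ctdi_coef,
              ctdi_log_sd = ctdi_log_sd,
              change_probs = change_probs,
              region = region, phantom = phantom)
  stopifnot(
    cfg$n >= 0,
    cfg$sex_fraction_female >= 0, cfg$sex_fraction_female <= 1,
    cfg$bmi_range[1] < cfg$bmi_range[2],
    cfg$deff_residual_sd >= 0,
    abs(cfg$weight_height_cor) < 1,
    cfg$ctdi_base > 0, cfg$ctdi_log_sd > 0, cfg$aspect_log_sd > 0,
    abs(sum(cfg$change_probs) - 1) < 1e-8
  )
  for (s in c("female", "male")) {
    p <- cfg[[s]]
    stopifnot(all(vapply(p[c("age", "weight", "height", "topogram")],
                         function(v) length(v) == 2 && v[2] > 0, TRUE)),
              p$change_sd > 0)
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> n=%d seed=%d female fraction=%.3f\n",
              x$n, x$seed, x$sex_fraction_female))
  cat(sprintf("  Deff_cm = %.2f*BMI + %.1f + N(0, %.2f); BMI window [%g, %g]\n",
              x$deff_slope, x$deff_intercept, x$deff_residual_sd,
              x$bmi_range[1], x$bmi_range[2]))
  invisible(x)
}

# Sample (height_cm, weight_kg) for one sex from the parent bivariate
# normal, rejecting pairs outside the BMI window or non-positive.
.sample_anthro <- function(n, pars, cor_wh, bmi_range) {
  if (n == 0) {
    return(list(height = numeric(0), weight = numeric(0)))
  }
  mu_w <- pars$weight[1] + pars$weight_parent_shift
  sd_w <- pars$weight[2]
  mu_h <- pars$height[1] + pars$height_parent_shift
  sd_h <- pars$height[2]
  height <- numeric(0); weight <- numeric(0)
  tries <- 0L
  while (length(height) < n) {
    m <- max(2L * (n - length(height)), 100L)
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    h <- mu_h + sd_h * z1
    w <- mu_w + sd_w * (cor_wh * z1 + sqrt(1 - cor_wh^2) * z2)
    keep <- h > 0 & w > 0
    bmi <- w[keep] / (h[keep] / 100)^2
    inside <- bmi >= bmi_range[1] & bmi <= bmi_range[2]
    height <- c(height, h[keep][inside])
    weight <- c(weight, w[keep][inside])
    tries <- tries + m
    if (tries >= 1000L && length(height) / tries < 0.01) {
      stop("BMI truncation acceptance below 1%; infeasible simulation config",
           call. = FALSE)
    }
  }
  list(height = height[seq_len(n)], weight = weight[seq_len(n)])
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` examination records in the [cohort_columns()] schema.
#' Per record: sex is Bernoulli; height and weight come from a truncated
#' bivariate normal (per-sex parent moments, BMI window enforced by
#' rejection); effective diameter follows the linear BMI relationship plus
#' Gaussian residual; AP and LAT are split from Deff via a log-normal
#' aspect ratio so that `sqrt(AP*LAT)` reproduces Deff exactly; CTDIvol
#' grows exponentially with diameter (tube-current modulation) with
#' log-normal noise; the diagnostic range is the topogram length plus a
#' signed half-normal change; DLP = CTDIvol x scan length (cm).
#'
#' @param config A [simulation_config()].
#' @return Cohort tibble (deterministic given `config`).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  if (n == 0) {
    out <- tibble::as_tibble(stats::setNames(
      lapply(cohort_columns(), function(x) character(0)), cohort_columns()))
    warning("generated an empty cohort (n = 0)", call. = FALSE)
    return(out)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  sex <- ifelse(stats::runif(n) < config$sex_fraction_female, "female", "male")
  height <- weight <- age <- topogram <- change_sd <- numeric(n)
  for (s in c("female", "male")) {
    idx <- which(sex == s)
    pars <- config[[s]]
    anth <- .sample_anthro(length(idx), pars, config$weight_height_cor,
                           config$bmi_range)
    height[idx] <- anth$height
    weight[idx] <- anth$weight
    age[idx] <- pmax(18, stats::rnorm(length(idx), pars$age[1], pars$age[2]))
    topogram[idx] <- pmax(300, stats::rnorm(length(idx), pars$topogram[1],
                                            pars$topogram[2]))
    change_sd[idx] <- pars$change_sd
  }
  bmi <- weight / (height / 100)^2
  deff_cm <- config$deff_slope * bmi + config$deff_intercept +
    stats::rnorm(n, 0, config$deff_residual_sd)
  deff_cm <- pmax(deff_cm, 10)
  deff_mm <- deff_cm * 10
  ratio <- exp(stats::rnorm(n, log(config$aspect_ratio_mean),
                            config$aspect_log_sd))
  ap <- deff_mm / sqrt(ratio)
  lat <- deff_mm * sqrt(ratio)
  ctdi <- config$ctdi_base * exp(config$ctdi_coef * deff_cm) *
    exp(stats::rnorm(n, 0, config$ctdi_log_sd))
  sign_draw <- stats::runif(n)
  p <- config$change_probs
  change_sign <- ifelse(sign_draw < p[["reduced"]], -1,
                        ifelse(sign_draw < p[["reduced"]] + p[["increased"]], 1, 0))
  change <- change_sign * abs(stats::rnorm(n, 0, change_sd))
  scan_len <- pmax(150, topogram + change)
  dlp <- ctdi * scan_len / 10

  tibble::tibble(
    exam_id = sprintf("sim-%05d", seq_len(n)),
    sex = sex,
    age_years = round(age, 1),
    weight_kg = weight,
    height_cm = height,
    ap_mm = ap,
    lat_mm = lat,
    topogram_length_mm = topogram,
    scan_length_mm = scan_len,
    ctdi_vol_mGy = ctdi,
    dlp_mGycm = dlp,
    region = config$region,
    phantom = config$phantom,
    exclusion_flags = ""
  )
}

#' Calibrate the effective-diameter residual SD to a target correlation
#'
#' Finds the residual SD (cm) around the BMI-diameter line such that the
#' expected sample Spearman correlation between BMI and Deff at the
#' config's cohort size matches `target_rho`. The sample correlation is
#' estimated by Monte Carlo (mean over `n_replicates` seeded cohorts) and
#' is strictly decreasing in the residual SD, so a bisection over
#' `[0, sd_max]` converges; common random seeds across evaluations keep
#' the search monotone.
#'
#' @param target_rho Target Spearman correlation in (0, 1).
#' @param config Base [simulation_config()]; its `deff_residual_sd` is
#'   ignored during the search.
#' @param n_replicates Cohorts per candidate SD (default 40).
#' @param tol Tolerance on the recovered mean correlation (default 0.02).
#' @param sd_max Upper search bound in cm (default 10).
#' @return The calibrated residual SD in cm.
#' @export
calibrate_residual_sd <- function(target_rho, config = simulation_config(),
                                  n_replicates = 40, tol = 0.02,
                                  sd_max = 10) {
  stopifnot(target_rho > 0, target_rho < 1)
  seeds <- config$seed + seq_len(n_replicates)
  mean_rho <- function(sd) {
    rhos <- vapply(seeds, function(s) {
      cfg <- config
      cfg$deff_residual_sd <- sd
      cfg$seed <- s
      coh <- generate_cohort(cfg)
      bmi <- compute_bmi(coh$weight_kg, coh$height_cm)
      deff <- compute_deff(coh$ap_mm, coh$lat_mm)
      stats::cor(bmi, deff, method = "spearman")
    }, numeric(1))
    mean(rhos)
  }
  lo <- 0; hi <- sd_max
  if (mean_rho(hi) > target_rho) {
    stop(sprintf("target rho %.2f not attainable with residual SD <= %g cm",
                 target_rho, sd_max), call. = FALSE)
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- mean_rho(mid)
    if (abs(r - target_rho) <= tol) return(mid)
    if (r > target_rho) lo <- mid else hi <- mid
  }
  stop("residual-SD calibration did not converge", call. = FALSE)
}

#' Calibrate parent weight moments to post-inclusion targets
#'
#' The BMI window biases the retained cohort's weight and height
#' distributions away from the parent's (high-BMI rejection removes heavy
#' and short records preferentially), so the parent means must be shifted
#' for the generated (post-window) cohort to reproduce the per-sex target
#' means. This fixed-point iteration generates large calibration cohorts
#' and adjusts `weight_parent_shift` and `height_parent_shift` until the
#' generated means match the targets. SDs are deliberately left alone:
#' truncation shrinkage of the spread is a property of the window itself.
#'
#' @param config A [simulation_config()].
#' @param n_cal Calibration cohort size per iteration (default 200000).
#' @param iterations Fixed-point iterations (default 4).
#' @return The config with updated `weight_parent_shift` and
#'   `height_parent_shift` for both sexes.
#' @export
calibrate_parent_moments <- function(config = simulation_config(),
                                     n_cal = 200000, iterations = 4) {
  cfg <- config
  for (it in seq_len(iterations)) {
    big <- cfg
    big$n <- as.integer(n_cal)
    big$seed <- cfg$seed + 1000L + it
    coh <- generate_cohort(big)
    for (s in c("female", "male")) {
      sel <- coh$sex == s
      cfg[[s]]$weight_parent_shift <- cfg[[s]]$weight_parent_shift +
        (config[[s]]$weight[1] - mean(coh$weight_kg[sel]))
      cfg[[s]]$height_parent_shift <- cfg[[s]]$height_parent_shift +
        (config[[s]]$height[1] - mean(coh$height_cm[sel]))
    }
  }
  cfg
}

#' End-to-end synthetic fixture
#'
#' Runs the full pipeline on one synthetic cohort - generate, inclusion
#' filter, per-record dose metrics, stratified summary and the
#' size-specific comparison - and asserts the per-record algebraic
#' identities before returning.
#'
#' @param config A [simulation_config()].
#' @param model,coeffs Passed to [compute_dose_metrics()].
#' @return List with elements `cohort`, `metrics` (records joined with
#'   derived columns), `summary`, `comparison`.
#' @export
end_to_end_fixture <- function(config = simulation_config(),
                               model = conversion_model(),
                               coeffs = region_coefficients()) {
  cohort <- generate_cohort(config)
  cohort <- apply_inclusion(cohort, inclusion_policy())
  metrics <- compute_dose_metrics(cohort, model, coeffs)
  ratios <- cbind(metrics$dlp_ss_mGycm / cohort$dlp_mGycm,
                  metrics$ssde_mGy / cohort$ctdi_vol_mGy,
                  metrics$ed_ss_mSv / metrics$ed_mSv)
  if (max(abs(ratios - metrics$k)) > 1e-12) {
    stop("internal error: size-correction identity violated", call. = FALSE)
  }
  joined <- dplyr::left_join(
    cohort, metrics[setdiff(names(metrics), c("sex", "region"))],
    by = "exam_id")
  list(
    cohort = cohort,
    metrics = joined,
    summary = summarize_cohort(joined,
                               c("age_years", "weight_kg", "height_cm", "bmi",
                                 "deff_mm", "ctdi_vol_mGy", "ssde_mGy",
                                 "dlp_mGycm", "dlp_ss_mGycm", "ed_mSv",
                                 "ed_ss_mSv")),
    comparison = size_specific_comparison(joined)
  )
}
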