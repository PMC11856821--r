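# AAPM Report 204 exponential fits of the size conversion factor k against
# effective diameter (cm). Normalisation phantom: 32 cm PMMA "body" or
# 16 cm "head". k = a * exp(-b * deff_cm).
.aapm204_fit <- list(
  body32 = c(a = 3.704369, b = 0.03671937),
  head16 = c(a = 1.874799, b = 0.03871313)
)

#' Phantom-specific conversion-factor model k(Deff)
#'
#' Builds the model that maps a patient's effective diameter to the AAPM
#' Report 204 conversion factor \eqn{k} used for size-specific dose
#' estimates. Two modes are available: `"fit"` evaluates the report's
#' exponential fit \eqn{k = a\,e^{-b\,D_{eff}}} (with \eqn{D_{eff}} in cm),
#' `"table"` linearly interpolates tabulated `(deff_cm, k)` pairs. The
#' packaged table (`system.file("extdata", "aapm204_k.csv", package =
#' "ssdose")`) is generated from the same fit at 1-cm spacing and rounded to
#' two decimals, so a site can audit or substitute the coefficients (e.g.
#' with water-equivalent-diameter tables) without touching code.
#'
#' @param phantom Reference phantom the scanner's CTDIvol is normalised to:
#'   `"body32"` (32 cm PMMA, body protocols) or `"head16"` (16 cm).
#' @param mode `"fit"` (default) or `"table"`.
#' @param table Optional data frame with columns `deff_cm` and `k`,
#'   strictly decreasing in `deff_cm`; defaults to the packaged AAPM-204
#'   table for `phantom` when `mode = "table"`.
#' @param valid_deff_range_cm Length-2 numeric, the effective-diameter range
#'   (cm) over which the model is considered valid. AAPM 204 covers roughly
#'   6-55 cm.
#'
#' @return An object of class `conversion_model`.
#' @seealso [k_factor()], [ctdi_bias()]
#' @export
#' @examples
#' m <- conversion_model("body32")
#' k_factor(290.44, m) # mean-sized abdominal patient, k > 1
conversion_model <- function(phantom = c("body32", "head16"),
                             mode = c("fit", "table"),
                             table = NULL,
                             valid_deff_range_cm = c(6, 55)) {
  phantom <- match.arg(phantom)
  mode <- match.arg(mode)
  stopifnot(length(valid_deff_range_cm) == 2,
            valid_deff_range_cm[1] < valid_deff_range_cm[2])
  fit <- .aapm204_fit[[phantom]]
  if (mode == "table") {
    if (is.null(table)) table <- aapm204_k_table(phantom)
    if (!all(c("deff_cm", "k") %in% names(table))) {
      stop("`table` must have columns `deff_cm` and `k`", call. = FALSE)
    }
    table <- table[order(table$deff_cm), , drop = FALSE]
    if (any(diff(table$k) >= 0)) {
      stop("table k values must be strictly decreasing in deff_cm",
           call. = FALSE)
    }
  }
  structure(
    list(phantom = phantom, mode = mode,
         coeff_a = unname(fit["a"]), coeff_b = unname(fit["b"]),
         table = table, valid_deff_range_cm = valid_deff_range_cm),
    class = "conversion_model"
  )
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf("<conversion_model> phantom=%s mode=%s k = %.6f * exp(-%.8f * Deff_cm)\n",
              x$phantom, x$mode, x$coeff_a, x$coeff_b))
  cat(sprintf("  valid Deff %g-%g cm; k = 1 at %.2f cm\n",
              x$valid_deff_range_cm[1], x$valid_deff_range_cm[2],
              log(x$coeff_a) / x$coeff_b))
  invisible(x)
}

#' Packaged AAPM-204 conversion-factor table
#'
#' Reads the packaged `(phantom, deff_cm, k)` table used by table-mode
#' [conversion_model()]s. Values are the report's exponential fit evaluated
#' at 1-cm spacing and rounded to two decimals, matching the report's
#' printing convention.
#'
#' @param phantom `"body32"` or `"head16"`.
#' @return A tibble with columns `deff_cm` and `k`.
#' @export
aapm204_k_table <- function(phantom = c("body32", "head16")) {
  phantom <- match.arg(phantom)
  path <- system.file("extdata", "aapm204_k.csv", package = "ssdose")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tab[tab$phantom == phantom, c("deff_cm", "k")])
}

#' Size conversion factor k for an effective diameter
#'
#' Evaluates a [conversion_model()] at one or more effective diameters.
#' Patients narrower than the reference phantom get `k > 1` (the scanner's
#' phantom-referenced CTDIvol understates their dose); wider patients get
#' `k < 1`. `k` is strictly decreasing in `deff_mm` and crosses 1 at
#' `log(a)/b` cm for fit-mode models.
#'
#' @param deff_mm Effective diameter(s) in mm (as measured on the axial
#'   image; converted to cm internally).
#' @param model A [conversion_model()]; default body phantom fit.
#' @param clamp If `TRUE` (default), diameters outside the model's validity
#'   range are clamped to the nearest bound with a warning; if `FALSE`, an
#'   error is raised.
#' @return Numeric vector of conversion factors.
#' @export
k_factor <- function(deff_mm, model = conversion_model(), clamp = TRUE) {
  .check_positive(deff_mm, "deff_mm")
  stopifnot(inherits(model, "conversion_model"))
  deff_cm <- deff_mm / 10
  rng <- model$valid_deff_range_cm
  out_of_range <- deff_cm < rng[1] | deff_cm > rng[2]
  if (any(out_of_range)) {
    if (!clamp) {
      stop(sprintf("effective diameter %.1f cm outside model validity range [%g, %g] cm",
                   deff_cm[which(out_of_range)[1]], rng[1], rng[2]),
           call. = FALSE)
    }
    warning(sprintf("%d effective diameter(s) outside [%g, %g] cm clamped to range",
                    sum(out_of_range), rng[1], rng[2]), call. = FALSE)
    deff_cm <- pmin(pmax(deff_cm, rng[1]), rng[2])
  }
  if (model$mode == "fit") {
    model$coeff_a * exp(-model$coeff_b * deff_cm)
  } else {
    tab <- model$table
    # rule = 2: flat beyond tabulated ends (ends coincide with the validity
    # range for the packaged table)
    stats::approx(tab$deff_cm, tab$k, xout = deff_cm, rule = 2)$y
  }
}

#' Fractional CTDIvol bias relative to the size-specific dose
#'
#' Returns `1 - 1/k`: the fraction by which the phantom-referenced CTDIvol
#' under-reports the size-specific dose estimate. Positive values mean
#' CTDIvol underestimates the dose (patient narrower than the reference
#' phantom, `k > 1`); negative values mean overestimation. The sign flips
#' exactly at the model's `k = 1` crossing.
#'
#' @inheritParams k_factor
#' @return Numeric vector of fractional biases (dimensionless; multiply by
#'   100 for percent).
#' @export
ctdi_bias <- function(deff_mm, model = conversion_model(), clamp = TRUE) {
  k <- k_factor(deff_mm, model, clamp = clamp)
  1 - 1 / k
}
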