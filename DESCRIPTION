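Package: ssdose
Title: Size-Specific CT Dose Estimation and Cohort Dose Audit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-examination size-specific dose estimation for computed
    tomography: effective diameter from anteroposterior and lateral
    cross-sections, AAPM Report 204 conversion factors, the size-specific
    dose estimate (SSDE), and the size-specific dose-length product and
    size-specific effective dose that correct whole-scan dose indices for
    patient size. Includes a cohort audit pipeline (scan-length
    discipline, effective-diameter census against the 32-cm reference
    phantom, normality-gated two-group comparisons, Spearman correlation
    panels, traditional-versus-size-specific comparison tables), CSV
    cohort input/output with inclusion filtering, and a calibrated
    synthetic-cohort generator so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
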