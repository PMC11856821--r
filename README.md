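# ssdose

Size-specific CT dose estimation and cohort dose auditing in R.

## The problem

The dose indices a CT scanner reports — CTDIvol and the dose–length
product DLP = CTDIvol × scan length — are defined against a fixed PMMA
reference phantom (32 cm diameter for body protocols). A patient whose
abdomen is narrower than that phantom absorbs *more* dose than CTDIvol
suggests; a wider patient absorbs less. In a typical abdominal cohort
roughly seven patients in ten sit below the reference diameter, so the
conventional effective dose `ED = DLP × f` systematically understates
individual exposure.

`ssdose` implements the size-specific correction chain used in dose
audits, for medical physicists and radiology quality teams:

- **BMI** = weight (kg) / height (m)²
- **Effective diameter** D<sub>eff</sub> = √(AP × LAT), the geometric mean
  of the anteroposterior and lateral dimensions of the scanned
  cross-section
- **Conversion factor** k(D<sub>eff</sub>) = a·exp(−b·D<sub>eff</sub>),
  the AAPM Report 204 fit (body phantom: a = 3.704369, b = 0.03671937 per
  cm), with an auditable table-interpolation mode
- **SSDE** = CTDIvol × k — the size-specific dose estimate
- **DLPss** = DLP × k — the size-specific dose–length product
- **EDss** = DLPss × f — the size-specific effective dose
  (f = 0.015 mSv/(mGy·cm) for abdomen/pelvis)

plus the cohort-level machinery of a dose audit: CSV ingestion with
row-level validation and BMI-window inclusion rules, sex-stratified
summary tables, normality-gated two-group comparisons (Shapiro–Wilk gate,
Welch t or Mann–Whitney U), Spearman correlation panels, a scan-length
discipline audit (topogram vs diagnostic range), a census of effective
diameters against the 320 mm reference, and traditional-vs-size-specific
comparison tables. A calibrated synthetic-cohort generator makes the whole
pipeline testable without patient data.

## Worked example

```r
library(ssdose)

path <- system.file("extdata", "example_cohort.csv", package = "ssdose")
cohort <- apply_inclusion(read_cohort(path))
metrics <- compute_dose_metrics(cohort)
dplyr::select(metrics, exam_id, bmi, deff_mm, k, ssde_mGy, ed_mSv, ed_ss_mSv)
#> # A tibble: 6 × 7
#>   exam_id   bmi deff_mm     k ssde_mGy ed_mSv ed_ss_mSv
#>   <chr>   <dbl>   <dbl> <dbl>    <dbl>  <dbl>     <dbl>
#> 1 ex-001   26.3    288.  1.29     14.9   7.92     10.2
#> 2 ex-002   25.5    292.  1.27     14.2   8.23     10.4
#> 3 ex-003   23.4    263.  1.41     13.8   6.47      9.11
#> 4 ex-004   28.9    340.  1.06     17.4  12.6      13.4
#> 5 ex-005   26.3    298.  1.24     15.0   8.53     10.6
#> 6 ex-006   26.5    310.  1.19     15.4   9.32     11.1
```

Every patient here except ex-004 is narrower than the 320 mm reference
phantom (k > 1), so their size-specific effective dose `ed_ss_mSv` exceeds
the conventional `ed_mSv` — by about 29% for the smallest patient
(ex-003) and 6% for the largest. The same chain on a full synthetic
cohort, end to end:

```r
fx <- end_to_end_fixture(simulation_config(n = 247, seed = 1))
fx$comparison[, c("stratum", "n", "ed_mean", "edss_mean", "ed_increase_pct")]
#>   stratum   n ed_mean edss_mean ed_increase_pct
#> 1     all 247    8.32      10.1            21.3
#> 2  female 113    8.36      10.1            20.4
#> 3    male 134    8.29      10.1            22.2

deff_census(fx$metrics$deff_mm)
#> Deff census vs 320 mm reference (n = 247)
#>   below: 71.3%, at or above: 28.7%
#>   mean Deff 299.3 mm; deviation 6.5% of reference, 6.9% of mean
```

The size-specific effective dose runs about a fifth higher than the
conventional one on a realistic abdominal cohort — the gap the
size-specific indices exist to close.

## Command-line tool

A thin wrapper over the same functions ships at
`system.file("cli", "ssdose", package = "ssdose")`:

```sh
ssdose simulate --output-dir sim --n 247 --seed 1
ssdose compute  --input sim/cohort.csv --output-dir metrics
ssdose audit    --input metrics/metrics.csv --output-dir report --report-format md
```

Each run writes a `manifest.json` (command, config hash, seed, package
version, outputs). Exit codes: 2 schema error, 3 empty post-filter
cohort, 4 infeasible simulation config.

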