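---
title: "Size-specific CT dose estimation: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-specific CT dose estimation: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdose)
```

## The dose model

A CT scanner reports its dose against a fixed-diameter PMMA phantom:
CTDIvol (mGy) for one rotation, and DLP = CTDIvol × irradiated length
(mGy·cm) for the whole scan. Body protocols reference a 32 cm phantom.
Because attenuation falls steeply with patient diameter, a patient
narrower than the phantom absorbs more dose than CTDIvol states and a
wider one less. The correction chain implemented here is:

$$\mathrm{BMI} = \frac{w\,[\mathrm{kg}]}{h^2\,[\mathrm{m}^2]}, \qquad
D_{\mathrm{eff}} = \sqrt{AP \times LAT}, \qquad
k(D_{\mathrm{eff}}) = a\,e^{-b\,D_{\mathrm{eff}}}$$

$$\mathrm{SSDE} = \mathrm{CTDIvol} \times k, \qquad
\mathrm{ED} = \mathrm{DLP} \times f, \qquad
\mathrm{DLP_{ss}} = \mathrm{DLP} \times k, \qquad
\mathrm{ED_{ss}} = \mathrm{DLP_{ss}} \times f$$

with $D_\mathrm{eff}$ in cm inside $k(\cdot)$ (records store mm, as
measurement tables do). The exponential coefficients are the AAPM
Report 204 fits: body phantom $a = 3.704369$, $b = 0.03671937$ cm$^{-1}$;
head phantom $a = 1.874799$, $b = 0.03871313$ cm$^{-1}$. The model's
assumptions are inherited from that report: the scanned volume is
approximated by a cylinder at the measured cross-section, and $k$ depends
on geometry only, not on tissue attenuation (the water-equivalent-diameter
refinement of AAPM Report 220 is out of scope; sites using it can load
their own table, see below).

Three consequences the test-suite checks as invariants:

- **Identity.** $\mathrm{DLP_{ss}}/\mathrm{DLP} =
  \mathrm{SSDE}/\mathrm{CTDIvol} = \mathrm{ED_{ss}}/\mathrm{ED} = k$
  exactly (to 1e-12), because $f$ cancels.
- **Monotone crossing.** $k$ is strictly decreasing and crosses 1 at
  $D_{\mathrm{eff}} = \ln(a)/b \approx 35.7$ cm for the body phantom — a
  little *above* the 32 cm phantom diameter, because PMMA and patient
  tissue differ. The CTDIvol bias $1 - 1/k$ flips sign exactly there.
- **Linearity.** Doubling DLP doubles ED, DLP$_{ss}$ and ED$_{ss}$.

### Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| $f$ abdomen/pelvis | 0.015 | mSv/(mGy·cm) | AAPM Report 96 convention |
| $f$ chest | 0.014 | mSv/(mGy·cm) | same convention; both overridable via `region_coefficients()` or the YAML config |
| k-model validity | 6–55 | cm $D_\mathrm{eff}$ | outside it, clamp-with-warning (default) or error (`clamp = FALSE`) |
| BMI window | [18, 35] | kg/m² | closed interval at both bounds |
| adult age | ≥ 18 | years | inclusion rule |
| risk slope | 5 | % per Sv | linear no-threshold stochastic-risk scaling |

The chest $f$ deserves a note: the abdominal coefficient is fixed by
convention at 0.015, but published chest coefficients vary (0.014–0.017
depending on ICRP weighting generation). We ship 0.014 as the default and
make it a plain configuration value, because back-computing a single
"correct" chest coefficient from published cohort summaries is not
possible either way.

### Fit mode vs table mode

`conversion_model(mode = "table")` interpolates a packaged
`(phantom, deff_cm, k)` file generated from the same exponential fits at
1-cm spacing, rounded to two decimals (the printing convention of the
source report). Fit and table agree within 0.01 everywhere, which the
suite asserts. The point of the file is auditability and substitution: a
site can drop in its own table (e.g. water-equivalent-diameter based)
without touching code.

### The CTDIvol bias convention

`ctdi_bias()` returns $1 - 1/k$: the fraction by which CTDIvol
under-reports SSDE. Positive for small patients, negative for large ones,
zero at the crossing. Other conventions in circulation ($k - 1$, or
normalising by SSDE) give different magnitudes for the same physics —
at $D_\mathrm{eff} = 210$ mm this convention gives ≈ +42%, while $k-1$
gives ≈ +71% — so the function documents its convention rather than
matching any particular published headline number.

## The synthetic cohort generator

No patient-level dataset accompanies the dose-audit summaries this
package is built around, so `generate_cohort()` produces cohorts with the
statistical structure the pipeline assumes. What it emulates:

- **Sex mix and anthropometrics.** Sex is Bernoulli (female fraction
  113/247). Height and weight are bivariate normal per sex (correlation
  0.5) with the BMI window enforced by rejection. The per-sex targets are
  the *post-window* cohort moments (female 69.19 ± 13.24 kg,
  162.06 ± 6.33 cm; male 79.67 ± 17.40 kg, 176.77 ± 6.77 cm), and since
  high-BMI rejection preferentially removes heavy and short records, the
  parent means carry small calibrated shifts (−0.43/−2.18 kg,
  −0.12/−0.32 cm) so the *generated* cohort reproduces the target means.
  `calibrate_parent_moments()` re-derives these shifts by fixed-point
  Monte Carlo for any other target set. Post-window SDs run 10–20% below
  the parent SDs — truncation shrinkage — and are deliberately not
  force-matched: a window of width 17 kg/m² caps the attainable BMI SD
  near 4.9 (the uniform limit), so matching a published SD of 5.3 inside
  it is not possible for any realistic shape.
- **Effective diameter.** $D_\mathrm{eff}\,[\mathrm{cm}] = 0.79\,
  \mathrm{BMI} + 9.4 + \varepsilon$, the published linear regression of
  diameter on BMI, with $\varepsilon \sim N(0, \sigma)$. The default
  $\sigma = 2.38$ cm is calibrated (`calibrate_residual_sd()`, monotone
  bisection over Monte-Carlo estimates with common random seeds) so that
  a cohort of n = 247 yields a BMI–$D_\mathrm{eff}$ Spearman correlation
  of 0.78. AP and LAT are split from $D_\mathrm{eff}$ by a log-normal
  aspect ratio (mean LAT/AP = 350.30/240.63 ≈ 1.456, log-SD 0.07), so
  $\sqrt{AP \times LAT}$ reproduces $D_\mathrm{eff}$ exactly.
- **Tube-current modulation.** CTDIvol $= 1.84 \cdot e^{0.06\,
  D_\mathrm{eff}[\mathrm{cm}]} \cdot e^{N(0,\,0.12)}$ mGy. Exponential
  dose growth with diameter is the standard behaviour of
  attenuation-based modulation; the base is calibrated so the default
  cohort's mean CTDIvol is ≈ 11.4 mGy and the coefficient/noise pair puts
  the CTDIvol–$D_\mathrm{eff}$ rank correlation near 0.9.
- **Scan lengths.** Topogram length is normal per sex; the diagnostic
  range differs by a signed half-normal change, with sign probabilities
  0.538 (reduced) / 0.457 (increased) / 0.005 (unchanged) and per-sex
  magnitude scales of 57.4/68.99 mm. This reproduces the three-bin audit
  fractions; it does *not* attempt to reproduce the per-sex mean change
  asymmetry, which would need asymmetric magnitude distributions the
  summaries do not pin down. DLP = CTDIvol × scan length (cm).
- **Age** is generated for summary tables only; no age–dose mechanism is
  modelled beyond what CTDIvol inherits from size.

Under these defaults the generated cohorts land where an abdominal audit
cohort should: mean $D_\mathrm{eff}$ ≈ 298 mm with ≈ 70% of examinations
below the 320 mm reference, mean SSDE ≈ 13.8 mGy against mean CTDIvol
≈ 11.4 mGy, and ED$_{ss}$ exceeding ED by ≈ 21% — against which note
that the BMI→diameter regression slope/intercept come from an external
cohort, so the generator's mean diameter sits ≈ 1 cm above the 290 mm a
direct measurement census reports; the below-reference fraction is
correspondingly 2–4 points lower than that census's 73%.

What the generator does **not** emulate: within-patient diameter
variation along z (the single-slice convention below), scanner- and
protocol-level dose heterogeneity, missing data, and any real left/right
or AP asymmetry structure. Passing parameter-recovery tests therefore
demonstrates that the *pipeline* recovers known structure, not that real
cohorts obey these distributions.

## Statistical protocol

The audit statistics mirror standard dose-survey practice:

- Normality is gated per variable *per group* (Shapiro–Wilk at the same
  $\alpha$ as the comparison, default 0.05); Student's t is used only if
  both groups pass, otherwise Mann–Whitney U. The t-test is the Welch
  form — the equal-variance assumption buys nothing here and costs
  robustness. Zero-variance groups route to the rank test (normality is
  untestable), and two identical constant groups compare with p = 1.
- Correlations are Spearman throughout (most dose variables are
  right-skewed); exact p-values below n = 30, asymptotic above.
- The effective-diameter census bins a diameter exactly at the reference
  as "not smaller", and the scan-length audit keeps a third bin for
  exactly-unchanged ranges, since the reduced/increased fractions of a
  real audit do not sum to 100%.
- The mean deviation of diameters from the reference is reported under
  *both* normalisation bases (fraction of the reference; fraction of the
  cohort mean) because audit reports are ambiguous about the base and the
  two differ visibly (6.5% vs 6.9% in the example below).
- No multiple-testing correction is applied — each table tests few,
  pre-specified contrasts at its own $\alpha$ — and the rendered report
  says so in `NOTES.txt`.

## Numerical and degenerate-input choices

- All internal computation is double precision; only report columns are
  rounded (2 decimals for mGy/mSv, whole percents for ratio tables).
- Validation is fail-loud: non-positive dose or geometry fields name the
  offending field; malformed CSV rows are collected with row numbers and
  never silently dropped; a missing column is a hard error.
- Out-of-range diameters (outside 6–55 cm) clamp to the range bound with
  a warning by default because audit cohorts exclude cachexia and extreme
  obesity anyway; `--strict-range`/`clamp = FALSE` turns them into errors.
- The BMI inclusion window is closed at both ends ("18 to 35" read
  inclusively), which the boundary tests pin down.
- `generate_cohort()` restores the caller's RNG state, so simulation is a
  pure function of its config.
- Rejection sampling aborts if the BMI window accepts under 1% of parent
  draws (infeasible configuration, exit code 4 in the CLI).

## Problem sizes

The shipped tests run cohorts of 247 (the audit-scale size), with
parameter-recovery checks over 200 replicates at n = 247, moment-recovery
at n = 5000 (three pooled cohorts, judged against the single-cohort
standard error), and 50-replicate census checks; the whole suite runs in
a few seconds. Calibrations use larger one-off cohorts (2 × 10⁵) via the
exported `calibrate_*` helpers.

## Worked numbers

```{r example}
fx <- end_to_end_fixture(simulation_config(n = 247, seed = 1))
fx$comparison[, c("stratum", "n", "ed_mean", "edss_mean", "ed_increase_pct")]
deff_census(fx$metrics$deff_mm)
```

## Known limitations

- The single-slice convention (diameter measured at the largest
  cross-section) overestimates whole-scan dose relative to per-slice
  averaging; the engine accepts any caller-supplied AP/LAT, so per-slice
  means can be fed in, but no averaging is performed internally.
- $k$ is geometric; attenuation-based (water-equivalent) corrections
  require substituting the conversion table.
- The ED coefficients $f$ are protocol-level constants; organ-dose
  modelling is out of scope.
- The generator's dose model is a one-parameter exponential; real
  modulation curves are scanner-specific.
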