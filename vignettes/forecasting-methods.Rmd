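---
title: "Forecasting beef-cattle meat productivity from birth-time markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting beef-cattle meat productivity from birth-time markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdcast)
```

## The prognosis workflow

`herdcast` implements the staged protocol zootechnicians use to
forecast post-slaughter productivity from early-life records:

1. **Descriptive biometry.** For each trait and age: mean, error of
   the mean $m = \sigma/\sqrt{n}$ and standard deviation $\sigma$
   (denominator $n-1$). `describe()`.
2. **Correlation analysis.** Pearson correlations of live weight
   between the seven ontogenesis ages (birth, 3, 6, 9, 12, 15, 18
   months) and between body measurements within each age, per
   pedigree group and pooled. Each $r$ carries the classical
   zootechnical error $m_r = (1-r^2)/\sqrt{n-2}$ and is flagged
   *reliable* when $|r/m_r|$ meets the two-sided Student critical
   value at level $\alpha$. `correlate()`, `correlation_table()`.
3. **Marker screening.** A candidate trait is kept as a forecast
   marker when its correlation with *every* target index clears a
   threshold and is reliable. The canonical candidates are dam live
   weight, calf live weight at birth and calf withers height at
   birth. `screen_markers()`.
4. **Regression coefficients.** $b = r\,\sigma_y/\sigma_x$: the
   expected change of the slaughter index per unit of the marker.
   `regression_coefficient()`.
5. **Forecast tables.** A grid of marker values centred on the
   rounded marker mean; each cell is the affine rule
   $\hat y(x) = \bar y + b\,(x - \bar x)$. `build_forecast_table()`.
6. **Combined forecast and approbation.** The prediction for a calf
   is the unweighted arithmetic mean of the per-marker table
   readings; the method is validated by forecasting a test herd and
   comparing the mean forecast with the mean realized value per
   target, accuracy being $100\,(1 - |F-A|/F)$ percent.
   `forecast_animal()`, `approbate()`.
7. **Selection planning.** Heritability as doubled dam–offspring
   correlation $h^2 = 2r$ (clipped to $[0,1]$), response to
   selection $\Delta G = S\,h^2$, and propagation to each slaughter
   index through its regression coefficient on live weight,
   $\Delta y = b\,\Delta G$. `estimate_heritability()`,
   `selection_effect()`, `propagate_effect()`.

`herdcast()` packages stages 1–5 into a single fitting call returning
a classed model object with the usual accessors; `run_pipeline()`
executes all stages end to end with delimited-file artefacts and a
JSON manifest.

### Assumptions

The forecast model is deliberately univariate-then-averaged: each
marker predicts each target through its own simple regression, and the
three forecasts are averaged with equal weights. This mirrors
established barn practice (a keeper reads three printed tables and
averages), is robust to the strong collinearity between birth weight
and birth withers height, and makes every table usable on its own. It
is *not* the least-squares-optimal multivariate predictor; a
correlation-weighted combination is available behind
`combine_forecasts()`-level code but deliberately not the default.
Linearity of every marker–target relationship and approximate
normality of traits are assumed throughout, as in the source
methodology.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 0.05 | — | Conventional reliability level for $r$. |
| `screen$threshold` | 0.3 | r | Admits moderately correlated ancestral traits (dam live weight sits near $r = 0.4$ with the targets) while rejecting noise-level signal. A threshold of 0.6 would keep only the calf's own birth traits. |
| `half_width`, `step` | 6, 1 | marker units | The conventional span of printed forecast tables: mean ± 6 in unit steps. Linear evaluation makes the grid resolution irrelevant to predictions. |
| `interpolation` | `"linear"` | — | `"linear"` evaluates the regression line exactly; `"nearest"` reads the nearest printed cell, as a barn user would, warning and falling back to the line outside the grid. |
| `top_fraction` | 0.2 | — | Typical intensity for retaining breeding stock; the expected differential for a Gaussian trait is then about $1.40\,\sigma$. |
| `digits` (rendering) | 1 | decimal | Table cells and herd files are rendered to one decimal, accuracies to whole percent — always with half-up ("commercial") rounding, full precision kept internally. |

## The synthetic-herd generator

No raw farm records ship with the package; `generate_herd()` produces
herds with the statistical structure the analysis assumes, so every
stage is testable.

**What it emulates.** Longitudinal traits (live weight plus nine body
measurements at seven ages, and dam live weight) are drawn from a
joint Gaussian on the raw measurement scale, truncated at three
standard deviations below the mean to keep masses positive. The
default configuration (`default_herd_config()`) anchors the moments
the forecast machinery quotes: dam live weight 512 kg, birth weight
26 kg, birth withers height 70 cm, and target means 425.7 / 237.3 /
175.2 kg for pre-slaughter, slaughter and pulp weight. Slaughter
indices are linear in the three markers plus an independent Gaussian
residual, with the multivariate coefficients solved so that the
implied *univariate* slopes equal the canonical regression
coefficients (11.3, 5.1 and 1.3 kg of pre-slaughter weight per unit
of birth weight, withers height and dam weight, and correspondingly
for the other targets). The remaining carcass components are fixed
fractions with small multiplicative noise, and chilled carcass mass
is computed as pulp + bone + tendon, so the composition bound holds
by construction.

**The correlation structure** is implied by a proper factor model — a
shared size factor (variance share 0.70), an age factor whose
correlation decays geometrically (0.75 per age step), a trait factor
(0.0875) and independent noise — and is therefore positive definite
by construction. Every implied value lies inside the canonical
published ranges: live-weight age pairs between 0.73 and 0.90 with
adjacent ages at 0.90 exactly, same-age measurement pairs at 0.85,
and dam live weight at 0.40 with every offspring trait. We chose a
model-implied matrix rather than transcribing published per-cell
values because the printed pattern (a dip to $\approx 0.5$ for the
6–9-month pairs coexisting with uniformly high measurement
cross-correlations) is not jointly realizable as a correlation
matrix: embedding it verbatim produces eigenvalues far below zero.
User-specified matrices that are only slightly indefinite are
repaired by eigenvalue clipping and re-normalization
(`repair_correlation()`, tolerance $10^{-6}$); anything worse is
rejected, naming the offending eigenvalue.

**Dispersions** are back-derived from the canonical coefficients:
with $\sigma$(birth weight) = 5 kg and $\sigma$(pre-slaughter) =
62.8 kg (so that $0.9 \cdot 62.8/5 = 11.3$), the printed $b$ = 5.1
and 1.3 force $\sigma$(withers at birth) $\approx$ 9.85 cm and
$\sigma$(dam) $\approx$ 19.3 kg. The withers dispersion is larger
than typical field values — it is what the coefficient set jointly
implies, and we kept the coefficients authoritative. Intermediate-age
means follow a saturating growth curve between the birth and 18-month
anchors; they are realistic placeholders, not published values.

**What it does not emulate** — and hence what passing tests do not
show about real data: measurement error of any recording system,
non-Gaussian trait distributions and growth-curve mechanics
(no Gompertz-type model), genuine pedigree structure beyond the
dam–offspring link (no sires, no half-sib families), seasonal and
management effects, and missing-data patterns (generated records are
complete). Group labels default to equal thirds with no mean
contrast; a `mean_scale` hook creates heavier/lighter lines when a
scenario needs them.

`generate_parent_offspring()` is a separate, minimal generator for
heritability work: dam–offspring pairs with correlation exactly
$h^2_{\text{true}}/2$, used for parameter-recovery testing of
`estimate_heritability()`.

## Numerical choices

- **Rounding** is half-away-from-zero (`round_half_up()`), applied
  only at rendering; all internal arithmetic is full precision.
  Printed-table reproduction is exact under this rule.
- **Strict replication.** Published tables sometimes print $b$ to one
  decimal while their cells imply more precision. `herdcast` computes
  cells from full-precision $b$; `printed_coefficient()` lets a user
  drive a table from a published coefficient instead when
  reproducing a printed artefact is the goal.
- **Degenerate inputs.** A zero-variance marker is a hard error for
  regression; zero-variance inputs to correlation are an
  undefined-correlation error; $|r| = 1$ gives $m_r = 0$ and is
  reliable by convention. Fewer than 2 values for description or 4
  pairs for correlation are errors. Zero trait sds in the generator
  are allowed and produce exactly-at-mean values (the degenerate
  limit used in tests).
- **Selection edge cases.** Selecting every animal is a valid
  "no selection" giving differential 0; an empty selection is an
  error. Raw $2r$ outside $[0,1]$ is clipped with a warning —
  phenotypic resemblance can exceed the additive bound through
  common environment or sampling noise.
- **Reliability is two-sided** ($|t|$ against the critical value), so
  a strongly negative correlation is also flagged; the classical
  one-sided reading would silently never flag them.
- **Determinism.** All generation is seeded; `run_pipeline()` reruns
  byte-identically under the same config and seed.

## Problem sizes

Parameter-recovery checks (correlation targets, implied slopes,
heritability across $h^2 \in \{0.2, 0.4, 0.8\}$, truncation-selection
differential) use $n = 5000$ animals, where three Monte-Carlo
standard deviations give tight, honest tolerances; structural and
workflow tests use herds of 60–800. The full suite and the
reference-results script each run in seconds on one core.

## Known limitations

- Heritability from doubled dam–offspring correlation is upward-biased
  by shared environment and ignores paternal information; no animal
  model / REML machinery is provided or intended.
- The accuracy statistic normalizes by the forecast, so it is not
  symmetric in forecast and actual, and farm-level accuracy on means
  can flatter offsetting per-animal errors — which is why the
  per-animal mean accuracy is reported alongside.
- Forecasts carry no uncertainty intervals; the source methodology
  provides none, and honest intervals would require the multivariate
  model this package deliberately does not fit.
- One generation means one application of the breeder's equation; no
  overlapping-generation demography.
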