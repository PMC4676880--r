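---
title: "Characterizing SRM/MRM assays: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing SRM/MRM assays: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmqc)
```

## The problem

Selected/multiple reaction monitoring (SRM/MRM) quantifies proteins through
the chromatographic peak areas of a few precursor-to-fragment transitions
per proteotypic peptide. Before such an assay can be trusted, its analytical
behaviour must be characterized: how little analyte it can detect (limit of
detection, LOD), over what range it quantifies with acceptable precision
and accuracy (LLOQ to ULOQ, the linear range), how reproducible it is
within and across days (intra-, inter- and total assay CV), whether
high-concentration injections contaminate subsequent blanks (carry-over),
and whether each transition's signal really comes from the targeted peptide
(specificity, judged by the stability of relative transition intensities).
These are the "Tier 2" measures recommended by the CPTAC Assay Development
Working Group for non-clinical quantitative assays.

`mrmqc` computes all of them from three tab-delimited inputs — a
Skyline-style transition-level peak-area export, a run-metadata table, and
a serial-dilution map — at two levels per peptide: each individual
transition, and the per-run sum of all its transitions ("summed"), which
emulates quantification on the aggregate signal.

## The experiments and their statistics

### Response curve

The response-curve experiment is a multipoint serial dilution (by default
seven calibration points, each in triplicate, bracketed by blank runs).
Per transition the package computes:

* **Calibration regression.** Ordinary least squares of peak area on
  theoretical concentration, every replicate entered individually so the
  slope standard error reflects replicate scatter. We regress in linear
  space (no log-log transform): the quantity validated is the linear
  response itself, and averaging replicates first would hide their
  contribution to `SE(slope)`. `Curve.SlopeStdErr(%)` is
  `100 * SE(slope) / |slope|`; `Curve.Rsquared` is the ordinary coefficient
  of determination. Bioanalytical `1/x` and `1/x^2` weighting are available
  (`mrm_control(weighting =)`); the reported R² is always computed
  unweighted on the raw scale so that weighted and unweighted fits remain
  comparable.

* **Linear range (ULOQ).** All contiguous windows of at least three
  calibration points are searched. A window passes when every member point
  has replicate CV at or below `lloq_cv_threshold` (default 20 %), at least
  two detectable replicates, and back-calculated accuracy — the window's
  own fitted curve inverted at the point's mean area — within
  `accuracy_tolerance` (default 20 %, boundary inclusive) of nominal. The
  widest passing window wins; ties prefer the higher top point, then the
  lower bottom point, making the search deterministic and auditable.
  `ULOQ.CaliPoint` is the top of that window. The reported calibration
  regression is the fit over the same window; if no window passes, the
  curve is fitted over all points and LLOQ/ULOQ are reported not estimable
  (`NA`).

* **LLOQ.** The lowest calibration point, at or below the ULOQ, at which
  all replicates are detectable (non-missing and positive) and the
  replicate CV is within threshold, with every higher point up to the ULOQ
  also compliant. Not estimable is a legal, reportable outcome.

* **LOD.** The classical 3-sigma rule. When at least two blank runs show
  detectable signal, the LOD signal is `mean(blank) + 3 * sd(blank)`,
  converted to concentration through the inverse of the fitted curve.
  Sensitive instruments usually report no blank signal at all; the package
  then falls back to the spiked-in estimate
  `3 * sd(lowest detectable calibration point) / slope` and flags the row
  with `LOD.usedSpiked = TRUE`. The multiplier is configurable
  (`mrm_control(lod_multiplier =)`). Negative blank-route LODs are clamped
  to zero. When low-end dropout leaves the first calibration point without
  measurements, the lowest point retaining at least two detectable
  replicates supplies the fallback.

* **Carry-over.** Runs are assumed listed in acquisition order in the
  metadata file (the usual convention for instrument run lists). Blank
  runs ordered after the last highest-calibration-point run are carry-over
  blanks; `Carryover.percent` is their mean signal as a percent of the mean
  high-point signal, and `Carryover.flag` is raised when that mean exceeds
  20 % of the LLOQ-point signal. Both views are reported because
  laboratories differ in which they act on. With no post-high blanks the
  measure is not applicable (`NA`).

### Mini-validation of repeatability

The repeatability experiment measures QC samples at three concentration
levels (low/medium/high), in triplicate, repeated across days (default
five). Per transition and level, replicate areas grouped by day enter a
one-way random-effects decomposition in its closed-form method-of-moments
form: the within-day variance is the pooled within-day mean square, the
between-day variance is `max(0, (MS_between - MS_within) / n0)` with
`n0 = (N - sum(n_d^2)/N) / (D - 1)` handling unbalanced days, and the
intra-, inter- and total CV are the component square roots over the grand
mean. Clamping the occasional negative between-day moment estimate to zero
is standard for this estimator; the event is recorded on the result. Days
retaining fewer than two detectable replicates are dropped with a warning
rather than failing the decomposition — real acquisition batches lose runs.

The **validated LLOQ level** is the lowest level (low < medium < high)
whose total CV is within `validation_cv_threshold` (default 20 %) and
whose replicates are all detectable on all days. Its companion
`totalCV.Me` is a median-based summary: the CV of the per-day medians of
the replicate measurements at that level. With one median per day this
series has no within-day component, so `totalCV.Me` is simply
`100 * sd(day medians) / mean(day medians)`; the conventional mean-based
total CV per level is reported alongside, so neither reading is lost.

The **partial validation of specificity** checks that relative transition
intensities are stable. In every QC sample at or above the validated LLOQ
level (determined on the summed-transition series; if no level validates,
all samples enter with a warning), each transition's ratio is its area over
the summed area of all the peptide's transitions in that sample — so
ratios are relative fractions summing to one. A ratio-to-most-intense
denominator is available via `mrm_control(ratio_denominator =
"max_transition")`. Per transition the maximum percent deviation of any
sample's ratio from that transition's mean ratio is reported, with the
annotations (day, level) of the maximizing sample, and the transition is
deemed specific when that maximum is at most `specificity_threshold`
(default 30 %). Because the mean includes every qualifying sample, a given
interference dilutes with the number of samples: a 1.4-fold inflation of a
0.1-fraction transition in one of 45 samples deviates about 34 % from the
mean, but the same inflation in one of 6 samples only about 27 %.
PVSpec fields are transition-specific by construction, so summed-transition
rows always carry `NA` for them.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lod_multiplier` | 3 | sigma multiplier in the LOD rules |
| `lloq_cv_threshold` | 20 % | replicate CV bound (LLOQ, linear-range) |
| `accuracy_tolerance` | 20 % | back-calculated accuracy bound (ULOQ) |
| `validation_cv_threshold` | 20 % | total-CV bound validating an LLOQ level |
| `specificity_threshold` | 30 % | maximum tolerated transition-ratio deviation |
| `ratio_denominator` | `"sum"` | transition-ratio denominator |
| `weighting` | `"none"` | calibration regression weighting |

All thresholds are inclusive at the boundary. They can also be set in a
flat `key = value` configuration file (`read_engine_config()`); explicit
arguments win on conflict.

## What the synthetic generator emulates — and what it does not

`simulation_config()` defaults encode the canonical study design: 15
peptides, 3 transitions each, a seven-point dilution spanning 0.01–100
concentration units in triplicate with three pre-curve and one post-high
blank, and a 3-level × 5-day × 3-replicate repeatability panel. Peak areas
follow `area = slope * conc * exp(eps)` with log-normal noise; the
log-scale sigma is `sqrt(log(1 + (CV/100)^2))`, the exact moment relation,
so the generated CV equals the configured CV by construction (default
within-replicate CV 5 %, between-day CV 10 % — typical mid-range values for
scheduled MRM peak areas). Day effects are shared across a peptide's
transitions, as instrument drift is, which also keeps transition ratios
exactly stable under day-to-day variation. Transition slopes default to
relative intensities 0.1/0.3/0.6 and are scaled geometrically across
peptides (two decades) so LODs span magnitudes. Blanks default to exactly
zero signal, reproducing the common situation in which every LOD must come
from the spiked-in fallback. Dropout (`dropout_below`), carry-over
(`carryover_fraction`) and a single-sample ratio interference
(`interference`) manufacture the corresponding engine paths with known
ground truth, which is emitted as a JSON sidecar so tests never re-derive
expectations from the generator's internals.

The generator starts where the engine's input starts — integrated peak
areas. It does not simulate chromatography (peak shape, co-elution,
integration error), matrix effects that bend the low end of real curves,
heteroscedasticity beyond the proportional-CV model, or missingness that
correlates with anything but concentration. Tests passing on synthetic data
therefore validate the estimators and the bookkeeping, not the behaviour of
any particular instrument or matrix.

## Numerical choices and degenerate inputs

* Detectability is `area > 0` and non-missing; missing and non-numeric
  area cells (`""`, `"#N/A"`, `"NA"`, `"NaN"`) are missing, never zero —
  zero-filling would bias the low end of the curve where dropout
  concentrates. Summed transitions likewise sum only non-missing areas and
  go missing only when every transition is missing in a run.
* Replicate CVs with fewer than two detectable values, grand means at or
  below zero, single-day designs, and sub-three-point windows all yield
  not-estimable (`NA`) results rather than errors; hard errors are reserved
  for malformed inputs (unknown runs, duplicate metadata, non-monotone
  dilutions).
* Reports print CVs and percentages with 4 decimal places and other reals
  with 6 significant figures; missing cells are the literal `NA`. Reading a
  report back (`read_report()`) restores types and missingness, so the
  tables round-trip to their printed precision.
* Test problem sizes: oracle-equivalence checks run on 50 random
  unbalanced CV instances and 20 random regressions; the
  variance-component recovery study uses 500 Monte-Carlo repeats of the
  5-day × 3-replicate design, enough for the mean estimated CVs to sit well
  inside their sampling bands while the whole suite stays fast.

## Known limitations

* Acquisition order is taken from metadata row order; if a run list is
  reordered, carry-over attribution follows the file, not the instrument
  log.
* The engine is agnostic to whether the area column is light, heavy, or a
  ratio; heavy/light internal-standard arithmetic is out of scope.
* No detection-probability (ROC/logistic) LOD modelling and no bootstrap
  intervals on LOD/LLOQ; the point estimators above are what the reports
  contain.
* Skyline's native `.sky`/`.skyd`/mzML formats are not read — only the
  tabular export.
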