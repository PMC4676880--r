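# mrmqc

Assay characterization and quality control for SRM/MRM targeted
proteomics.

Targeted proteomics quantifies proteins through the chromatographic peak
areas of a few precursor→fragment transitions per proteotypic peptide.
Before an assay is used, its analytical performance must be established.
`mrmqc` computes the CPTAC ADWG "Tier 2" performance measures from
Skyline-style transition-level peak-area exports, for assay developers
running the two canonical characterization experiments:

* **Response curve** (multipoint serial dilution): limit of detection
  (LOD, classical `mean_blank + 3·sd_blank` with a spiked-in fallback
  `3·sd(lowest point)/slope` when blanks are silent), LLOQ and ULOQ
  calibration points from a contiguous linear-range search (replicate
  CV ≤ 20 %, back-calculated accuracy ± 20 %), the calibration regression
  (slope, intercept, R², `100·SE(slope)/|slope|`), and carry-over in
  post-high blank runs.
* **Mini-validation of repeatability** (3 concentration levels × 5 days ×
  3 replicates): intra-, inter- and total assay CV per level from the
  one-way random-effects decomposition
  `σ²_between = max(0, (MS_between − MS_within)/n0)`,
  `CV = 100·σ/grand mean`; the validated LLOQ concentration level
  (total CV ≤ 20 % with full detectability) and its median-based
  `totalCV.Me`; and partial validation of specificity — a transition is
  specific when no above-LLOQ sample's transition ratio (area over the
  peptide's summed transition areas) deviates > 30 % from its mean ratio.

Every measure is reported at two levels: each individual transition
(labelled `"{precursor charge}.{fragment ion}.{product charge}"`, e.g.
`2.y4.1`) and the per-run sum of the peptide's transitions (`summed`).
A seeded synthetic-data generator reproduces both experiment designs with
known ground truth.

## Worked example

```r
library(mrmqc)

cfg   <- simulation_config(seed = 42, n_peptides = 2)
sim   <- simulate_response_curve(cfg, dir = "example")
assay <- mrm_assay(sim$paths$export, sim$paths$metadata, sim$paths$dilution)
assay
#> MRM assay data: 2 peptide(s), 6 transition(s), 25 annotated run(s)
#>   runs by sample type: blank=4, calibration=21
#>   dilution map: 7 calibration points spanning 0.01 - 100

rc <- response_curve(assay)
summary(rc)
#> Response-curve summary
#>   peptides: 2, report rows: 8
#>   LOD range: 0.000308298 - 0.0020771
#>   R^2 range: 0.993162 - 0.999923
#>   SlopeStdErr(%) range: 0.2433 - 2.3014
#>   LLOQ estimable for 8 rows, not estimable for 0
```

The report table (`as.data.frame(rc)`, written to disk with
`write_report()`) holds one row per transition plus a summed row per
peptide; for the first peptide:

```
  Transition LOD.value LLOQ.CaliPoint ULOQ.CaliPoint Curve.Slope Curve.Rsquared
1     2.y4.1 0.0004134              1              7       49.42         0.9974
2     2.y5.1 0.0012182              1              6      152.46         0.9954
3     2.y6.1 0.0003289              1              6      315.29         0.9965
4     summed 0.0003083              1              6      519.85         0.9977
```

LOD is in the dilution file's concentration units (here the curve spans
0.01–100): with silent blanks each row used the spiked-in fallback, and
`2.y5.1`'s noisier top point trimmed its linear range to calibration
point 6. The repeatability side works the same way:

```r
simr <- simulate_repeatability(cfg)
rp   <- repeatability(mrm_assay(simr$export, simr$metadata))
summary(rp)
#> Repeatability summary
#>   peptides: 2, report rows: 8
#>   total CV range: 8.5118 - 13.5042 %
#>   lowest totalCV.Me at a validated LLOQ: 7.7090 %
#>   validated LLOQ levels:
#>    low medium   high
#>      8      0      0
#>   transitions specific: 6, non-specific: 0
```

`mrm_run()` wires parsing, both analyses, report writing and (optionally)
per-peptide figures plus an eight-panel global overview into one call;
`inst/scripts/mrmqc.R` exposes the same pipeline on the command line
(`--demo --seed 7 --out demo` runs it end to end on synthetic inputs).

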