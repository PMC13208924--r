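# putatex — synthetic putamen ROI cohorts and histogram texture analysis

Histogram-based (first-order) texture analysis compares the intensity
distribution inside a region of interest (ROI) between clinical groups.
`putatex` implements the full analysis chain for a putamen case–control
setting on T2-weighted MRI:

1. **Synthetic cohort generator** — seeded two-group cohorts (bipolar
   disorder vs controls) of putamen-like 2D ROIs. Per-subject central
   intensities are normal, within-ROI pixels are skew-normal
   (location/scale/shape solved from a target mean, SD and skewness),
   masks are perturbed ellipses with exact pixel counts. The default
   configuration is calibrated to published group-level summaries
   (33 subjects per group, left/right putamen), with the within-ROI
   spread derived *only* from the 10th/90th-percentile gap:
   `sigma_within = (p90 − p10) / (2·Φ⁻¹(0.9))`, leaving quartiles and the
   RMS level as out-of-sample predictions.
2. **Feature extraction** — the 14 first-order parameters per masked ROI:
   pixel count, mean, median, min, max, mode (ties → smallest), skewness
   (uncorrected g₁ = m₃/m₂^{3/2}), RMS level √(Σx²/n),
   root-sum-of-squares level √(Σx²) = RMS·√n, percentiles 10/25/75/90
   (linear interpolation at rank 1 + (q/100)(n−1)), and the Katz fractal
   dimension D = log₁₀m / (log₁₀m + log₁₀(d/L)) of the z-scored
   raster-order waveform.
3. **Distribution-gated comparison** — per feature × side, Shapiro–Wilk
   in both groups gates Student's pooled t vs Mann–Whitney U (two-sided);
   gender via chi-square/Fisher; 28 feature rows + age + gender rows,
   α = 0.05, no multiplicity correction by default (BH optional).
4. **Derived profiles** — pooled z-score texture signature
   (n₁z₁ + n₂z₂ = 0 by construction) and the percentile-shift series at
   levels 10/25/50/75/90.

It also ships a reader for uncompressed single-frame DICOM slices
(rescale slope/intercept applied) and lossless TIFF/CSV round trips for
images, masks, manifests and feature tables.

## Worked example

```r
library(putatex)

config <- default_generator_config()      # calibrated reference settings
cohort <- generate_cohort(config, seed = 1)
features <- cohort_feature_table(cohort)  # 132 rows: 66 subjects x 2 sides

parameter_recovery_summary(features)[, c("feature", "side", "group",
                                         "reference", "recovered")]
#>    feature  side   group reference recovered
#>  1 mean     left  bipolar    511.19   504.71
#>  2 mean     left  control    440.68   439.28
#>  3 median   left  bipolar    511.92   505.58
#>  4 p25      left  bipolar    477.92   472.65
#>  5 p75      left  bipolar    545.70   537.83
#>  6 rms_level left bipolar    513.58   507.15
#>  7 skewness left  bipolar     -0.11    -0.108
#>  8 skewness left  control      0.11     0.112
#>  9 mean     right bipolar    476.33   490.85
#> 10 mean     right control    417.19   422.54
```

All ten across-subject feature means land within the ±3·SD/√33 sampling
tolerance of their reference values — rows 4–6 without ever being fitted
(the calibration never sees the quartiles or the RMS level). The gated
results table and the derived profiles follow:

```r
results <- build_results_table(features)  # 30 rows: 28 features + age + gender
shift <- percentile_shift_series(features)
shift[shift$side == "left", c("level", "difference")]
#>   level difference
#> 1    10       61.7
#> 2    25       65.8
#> 3    50       66.8
#> 4    75       67.2
#> 5    90       66.0
```

The uniformly positive differences are the "global upward intensity
shift" pattern: the bipolar group sits higher across the whole left-side
intensity distribution, not just at the centre.

The numbered drivers under `analysis/` run the same steps as a workflow
(`01_simulate.R` → `04_signature_report.R`), writing tables under
`results/` and bulky rasters under `scratch/`.

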