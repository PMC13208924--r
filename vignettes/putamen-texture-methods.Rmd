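---
title: "Simulating and analysing putamen texture cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing putamen texture cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(putatex)
```

## The problem

First-order (histogram-based) texture analysis summarizes the intensity
distribution inside a manually delineated region of interest (ROI) — here
the putamen on axial T2-weighted MRI — with statistics such as the mean,
median, percentiles, skewness, root-mean-square level and the Katz fractal
dimension of the intensity sequence. Case–control studies compare these
per-subject features between groups (bipolar-disorder patients vs matched
controls) with distribution-gated two-sample tests.

Raw clinical images for such studies are controlled-access. `putatex`
therefore provides a calibrated generative stand-in: a seeded simulator of
two-group cohorts of putamen-like 2D ROIs whose *per-subject feature
summaries* match published group-level statistics, together with the
feature extractor, the gated statistical pipeline and the derived
signature/percentile-shift reports. The simulator makes the whole analysis
chain testable end to end, and the calibration makes several features
(quartiles, RMS level) genuine out-of-sample predictions rather than
curve fits.

## The generative model

For each group $g$ (bipolar, control) and side $s$ (left, right):

* **Subject level.** Subject $i$ receives a central intensity
  $m_i \sim \mathcal N(\mu_{gs}, \sigma^{subj}_{gs})$ and an ROI pixel
  count $N_i \sim \mathrm{round}\,\mathcal N(\nu_{gs}, \tau_{gs})$,
  floored at 16 pixels.
* **Pixel level.** The $N_i$ masked intensities are i.i.d. skew-normal
  with population mean $m_i$, SD $\sigma^{within}_{gs}$ and skewness
  $\gamma_{gs}$, then rounded to integers and clipped to the 12-bit range
  $[0, 4095]$ (typical stored MRI pixel depth; T2-FSE signal units are
  arbitrary, so the absolute scale carries no meaning).
* **Mask.** An ellipse with axis ratio 2.2 (putamen-like elongation) whose
  boundary radius is perturbed by low-frequency harmonics (orders 2–3,
  relative amplitude ≤ 0.08 by default, random phases). Rasterization
  keeps exactly the $N_i$ grid cells with the smallest perturbed elliptic
  radius — a threshold on a star-shaped field, so the mask is a single
  connected component and the realized count is exact.

The skew-normal family is used because the reference summaries print
small but nonzero within-ROI skewness (−0.11 / +0.11) that a plain normal
cannot encode. Its shape parameter is obtained from the target skewness
$\gamma$ by inverting the skew-normal skewness formula in closed form
(with $k = (2|\gamma|/(4-\pi))^{1/3}$, $\mu_z^2 = k^2/(1+k^2)$ and
$\delta = \mathrm{sign}(\gamma)\,\mu_z\sqrt{\pi/2}$), valid for
$|\gamma| < 0.99527$, the family's attainable range; the location and
scale then follow from the requested mean and SD. Sampling uses the
standard convolution representation
$Z = \delta|U_0| + \sqrt{1-\delta^2}\,U_1$.

### Calibration

`calibrate_config_from_table()` maps one row of group-level summaries per
group × side to the model:

* $\mu_{gs}$ = the printed across-subject mean of the mean feature;
* $\sigma^{subj}_{gs}$ = the printed between-subject SD. (The sampling
  contribution $\sigma^{within\,2}/N \approx 48^2/948 \approx 2.5$ is
  negligible against $\sigma^{subj\,2} \approx 107^2$, so no deconvolution
  is attempted.)
* $\sigma^{within}_{gs} = (p_{90} - p_{10}) / (2 z_{0.9})$ with
  $z_{0.9} = \Phi^{-1}(0.9) = 1.2816$: the spread implied by the
  normal-quantile distance between the mean 10th and 90th percentile
  features. Only this pair enters the calibration, so the 25th/75th
  percentiles and the RMS level ($\approx \sqrt{\mu^2 + \sigma^{within\,2}}$)
  are out-of-sample predictions used as recovery targets.
* $\gamma_{gs}$ = the printed mean within-ROI skewness; pixel counts from
  the printed mean ± SD.

Demographics (sex counts exact, ages normal clipped to the study's 18–65
inclusion band) are cosmetic: they drive only the demographic rows of the
results table.

### What the simulator does **not** emulate

Pixels are spatially independent by default: no cortical neighbourhood
correlation, no bias fields, partial-volume effects or scanner physics.
Consequently any feature that depends on spatial arrangement — here only
the Katz fractal dimension — takes values characteristic of white noise
(≈ 1.07 at ~950 pixels), not the published ≈ 1.23–1.27, and no numeric
fractal-dimension target is claimed. An optional per-cell
`smooth_window` knob applies a moving average along the raster waveform
(restandardized to the target mean/SD), which injects correlation and
lowers the fractal dimension; it is off by default and exercised only by
direction tests. Passing recovery tests therefore validates the
distributional model of the features, not the spatial realism of the
images.

## Feature definitions and conventions

All 14 features are computed on the masked intensities in row-major
raster order:

* **Percentiles** use linear interpolation at fractional rank
  $1 + (q/100)(n-1)$ (`stats::quantile` type 7). Stated explicitly
  because conventions differ across ecosystems.
* **Skewness** is the uncorrected Fisher–Pearson $g_1 = m_3/m_2^{3/2}$
  (population moments, no $n$-adjustment; the difference is negligible at
  $n \approx 950$), with $g_1 \equiv 0$ for zero-variance samples.
* **Most frequent value** requires integer-quantized intensities
  (guaranteed by the image model); ties resolve to the smallest value.
* **RMS level** $= \sqrt{\sum x^2 / n}$; **root-sum-of-squares level**
  $= \sqrt{\sum x^2}$, the Euclidean norm, so RSS = RMS·$\sqrt n$
  identically. The Euclidean-norm reading is forced by the printed
  magnitudes (≈ 513.6 × √948 ≈ 15.6k, matching the printed ≈ 15,624; a
  literal sum of squares would be ~2.5 × 10⁸).
* **Katz fractal dimension**: the raster-order waveform is z-scored
  (population SD; constant waveforms return 1), vertices sit at unit
  abscissa spacing, and $D = \log_{10} m / (\log_{10} m + \log_{10}(d/L))$
  with $L$ the polyline length, $m$ the segment count and $d$ the maximal
  distance from the first vertex. The z-normalization makes $D$ shift- and
  scale-invariant; straight lines give exactly 1. The published analysis
  does not state its waveform construction (raster scan, boundary contour
  or histogram curve are all possible), which is the single largest
  implementation freedom here — a further reason no numeric
  fractal-dimension target is set.

## Statistical pipeline

Per feature × side, each group's per-subject values are assessed with
skewness, excess kurtosis and the Shapiro–Wilk test; the *gate* is
Shapiro–Wilk alone (both groups p > 0.05 → Student's pooled-variance t;
otherwise Mann–Whitney U with normal approximation and tie correction,
two-sided). Skewness/kurtosis are reported, not gated, since no combining
rule is published. Student's rather than Welch's t is the default reading
of "independent samples t-test"; a `welch` flag is exposed. Gender uses
chi-square without continuity correction when every expected count
exceeds 5 (the boundary case goes to Fisher's exact test, matching the
worked selection examples), Fisher otherwise. α = 0.05 two-sided, no
multiplicity correction by default (matching the reference analysis,
which applied none); `correction = "bh"` adds Benjamini–Hochberg adjusted
p-values over the 28 feature rows.

The results table carries 28 feature rows (14 features × 2 sides) plus
the gender and age rows, in the reference layout.

## Derived profiles

* `zscore_signature()` standardizes each group's feature mean against the
  pooled-cohort mean and SD; $n_1 z_1 + n_2 z_2 = 0$ holds by
  construction (the balance is exact at equal n). Control-referenced
  standardization is available via `reference = "control"` since the
  published figure does not specify its reference.
* `percentile_shift_series()` reports each group's across-subject mean
  percentile feature at levels 10/25/50/75/90 (the median standing at the
  50th) and the bipolar − control difference per level; an upward
  intensity shift shows as positive differences at every level. These
  outputs are validated by direction and invariants only — the published
  figures print no numeric axes.

## Numerical and design choices

* Exact-count mask rasterization (Nth-order-statistic threshold) instead
  of a tolerance search; radius ties are resolved deterministically.
* Seeding: every generator entry point accepts a seed and restores the
  caller's RNG state; a cohort is reproduced pixel-for-pixel from
  (configuration, seed).
* Degenerate inputs: empty masks, constant samples, inverted percentile
  pairs, unattainable skewness and malformed configurations all fail with
  named errors before any output is written.
* Rasters are uncompressed 16-bit grayscale TIFF (masks 8-bit {0,255}),
  so writers are byte-deterministic; tables are CSV with doubles at 17
  significant digits for exact round trips.
* The optional clinical-slice reader handles uncompressed little-endian
  single-frame DICOM with rescale slope/intercept; multi-frame and
  compressed syntaxes are rejected explicitly. It is read-only and the
  pipeline never requires it.

## Problem sizes

The reference-scale cohort (33 per group, ~800–1100 pixels per ROI)
generates and extracts in a few seconds. The calibration studies run at
reduced but statistically adequate sizes chosen once: type-I error on 200
replicate null cohorts of 20 subjects per group (~300-pixel ROIs), and
power for the left-mean contrast on 500 replicate 33-per-group cohorts —
the pooled-t power at the calibrated standardized difference (≈ 0.67) is
≈ 0.77, comfortably inside the published-compatible [0.60, 0.90] band.

## Known limitations

* Spatial structure is not modelled (see above); fractal-dimension
  magnitudes are implementation-relative.
* The published gender p-value (0.500) is not reproduced by any standard
  two-sided test on the printed 2×2 counts (chi-square ≈ 0.80, Fisher
  ≈ 1.0); the original categorical test variant is unknown, so the
  pipeline reports its own chi-square/Fisher result and no categorical-p
  target is claimed.
* Whether the published percentile summaries are per-subject features
  averaged across subjects (assumed here, consistent with their ± SD
  columns) or pooled-pixel percentiles is not stated.
* Single-cohort p-values are sampling-noisy by nature; recovery targets
  are means with ±3·SD/√n tolerances, not p-values.
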