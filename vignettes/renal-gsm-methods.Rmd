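---
title: "Gray-scale analysis of renal ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-scale analysis of renal ultrasound: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalGSM)
```

## The problem

B-mode ultrasound encodes tissue echogenicity as up to 256 shades of gray,
far more than the few dozen the human eye can separate, and the displayed
gray level depends heavily on operator-chosen settings (gain, time gain
control, dynamic range) and on the device. Quantitative gray-scale analysis
of the renal parenchyma therefore needs two ingredients before images from
different operators or devices can be compared:

1. **Region statistics.** The kidney is segmented manually (the accepted
   gold standard for renal ultrasound) and summarized by its *gray-scale
   median* (GSM) — the gray level that splits the region's pixels into a
   brighter and a darker half — together with the proportional distribution
   of the region's pixels over 14 pre-established brightness ranges, each
   associated with a probable tissue type ("virtual histology"), and a
   pseudocolor rendering that makes the band structure visible.
2. **Normalization.** All pixel intensities are linearly rescaled so that a
   bright reference structure — the posterior renal fascia — attains a fixed
   anchor GSM of 200. This is a one-point variant of the two-point
   (adventitia 200 / lumen 0) standardization used for carotid plaque.

`renalGSM` implements this pipeline, a synthetic phantom study generator,
and the nonparametric protocol used to test whether operators remain
distinguishable in each image category.

## The normalization model

Let `medF0` be the GSM of the manually segmented fascia. The normalization
factor is

```
Fn = |medF0 - 200| / medF0
```

and the transfer function applied to **every** pixel `r` of the image is
`r (1 + Fn)` when `medF0 <= 200` and `r (1 - Fn)` when `medF0 > 200`. Both
branches are the single linear map `r -> r * 200 / medF0`; the package
computes that unified slope directly under the default `exact_factor`
policy, so the two printed branch forms and the implementation agree to
within one floating-point ulp (and exactly on every integer output,
verified exhaustively over `medF0` in 1..255).

Three numerical conventions deserve note:

* **Sign of the factor.** Read literally, `(medF0 - 200)/medF0` is negative
  whenever the fascia is darker than the anchor, and the `medF0 <= 200`
  branch would then *darken* the image — the opposite of its purpose. The
  package therefore uses the absolute value, which reproduces the worked
  example (`medF0 = 220` gives `Fn = 0.09` at two decimals, and pixel 50
  maps to `50 * 0.91 = 45.5 -> 46`). The literal signed form is retained
  behind `literalSign = TRUE` purely for auditing.
* **Pixel rounding** is round-half-away-from-zero — the only rule consistent
  with `45.5 -> 46` — followed by clipping to `[0, 255]`. The number of
  clipped pixels is recorded in the output metadata.
* **Rounding policy.** `exact_factor` (default) uses the full-precision
  slope; `paper_compat` first rounds `Fn` to two decimals, reproducing the
  published example and nothing else. Because the transfer is monotone
  non-decreasing, pixel rank order inside any region is preserved, and for
  a fascia region with an odd pixel count the recomputed fascia GSM after
  `exact_factor` normalization is *exactly* 200 (the median pixel `medF0`
  maps to `round(medF0 * 200 / medF0) = 200`). For even counts the GSM is
  the mean of two mapped order statistics and can differ from 200 by at
  most one gray level; the same rounding argument bounds a second
  normalization's residual factor by `1/200` and its per-pixel effect by
  one gray level.

## GSM and the brightness ranges

The GSM is the sample median: the middle order statistic for odd *n*, the
mean of the two middle order statistics for even *n*. Half-integer values
are propagated unrounded into the statistics. Zero-level pixels are **not**
excluded from region statistics; no exclusion rule is part of the method.

The 14 brightness ranges are closed integer intervals that must tile
`[0, 255]` exactly — a configuration that fails to tile is refused outright.
The published boundaries exist only in a figure that is not machine-readable
in the source available to this package, so the shipped default is the
documented fallback: thirteen bands of width 18 and a final band 234–255,
labeled along the usual echogenicity gradient (anechoic fluid, blood-like,
hypoechoic/medullary, lipid-, muscle-, parenchyma-, fibrous-, fascia- and
calcification-like). Every object computed from the default carries the
provenance flag `fallback_uniform` through to the results table, so analyses
run with transcribed boundaries (via `readBrightnessConfig()`) are
distinguishable from analyses run with the fallback. The choice of
boundaries shifts individual band percentages but does not affect the GSM,
the normalization, or the partition property (counts sum to *n*,
percentages to 100 within 1e-9).

## ROI rasterization

Segmentation contracts are "vertices in, mask out": a polygon is rasterized
by testing each pixel center (integer coordinates, 0-based, origin top-left)
against the even–odd rule, with centers lying exactly on an edge included.
This convention is deterministic, translation-equivariant, and makes an
axis-aligned rectangle with corners `(x0,y0)`–`(x1,y1)` contain exactly
`(x1-x0+1)(y1-y0+1)` pixels. A polygon that captures no pixel center is an
error rather than an empty region.

## What the phantom emulates — and what it does not

The synthetic phantom stands in for patient images, which are not
distributable. It models:

* **Geometry**: an elliptical kidney with a brighter inner sinus over a dark
  background, and a bright posterior fascia band that never intersects the
  kidney. The fascia ROI is an odd-width by odd-height rectangle so its
  pixel count is odd and the re-anchoring identity above holds exactly.
* **First-order texture**: multiplicative speckle `1 + s (R - 1)` with `R`
  unit-mean Rayleigh — the standard first-order envelope model — attenuated
  by the contrast `s`. The default `s = 0.25` reflects that displayed
  B-mode images are log-compressed and scan-converted, which strongly
  reduces envelope contrast; with full Rayleigh contrast (`s = 1`) the
  region median would sit ~6% below the region mean, which does not match
  how display-stage gray levels behave. With `s = 0.25` the fascia GSM
  stays within 5 gray levels of its configured mean of 220.
* **Region means** (defaults: background 40, cortex 90, sinus 150, fascia
  220 gray levels) follow the usual echogenicity ordering of renal B-mode
  images.
* **Operator and device variability** as a linear gain and offset applied to
  the displayed gray levels: the simplest mechanism that produces
  between-operator separation under free ("random") acquisition. Under the
  "standardized" method the operator's gain/offset are replaced by a fixed
  study-wide preset, identical for every physician — the in-silico analogue
  of locking gain, TGC and dynamic range.
* **Patient heterogeneity** as a normal perturbation (sd 5 gray levels) of
  the region means per patient and side, giving the Kruskal–Wallis groups
  realistic within-group variance.
* **Reproducibility**: substreams are derived hierarchically from the study
  seed per (patient, side, physician), so the random and standardized
  acquisitions of one physician share the same underlying tissue image, and
  adding a physician never changes another physician's images.

It deliberately does **not** model beamforming, depth-dependent attenuation,
TGC curves, shadowing, or anatomical variability. Consequently, passing
tests demonstrate that the *pipeline and statistics* behave correctly under
a controlled data-generating process with known operator effects — not that
the method is clinically validated on real kidneys, where fascia visibility,
segmentation quality and non-linear device processing all intervene.

## The comparability protocol

For each image category — random, standardized, random-normalized,
standardized-normalized (normalized rows are derived in-pipeline from the
raw image plus its fascia ROI, not stored as separate acquisitions) — the
15 analysis variables are the kidney GSM and the 14 band percentages,
treated as continuous. Per variable the protocol runs a Kruskal–Wallis test
(mid-ranks, tie-corrected H, chi-square reference on k−1 df; H defined as 0
with p = 1 when all observations are identical) across operators, and a
two-sided Wilcoxon–Mann–Whitney test for every operator pair (exact null
distribution when both groups have n ≤ 25 and the pooled data are tie-free,
otherwise the normal approximation with tie and continuity corrections).
Anderson–Darling (case 3, estimated mean and variance) checks normality of
the variables beforehand. α = 0.05 throughout; pairwise tests run regardless
of the omnibus outcome, and **no multiple-testing correction** is applied —
that is the protocol being reproduced — but every report carries the total
number of tests performed. Repeated images of the same patients by
different physicians are treated as independent samples because that is the
protocol under study; the package follows it without endorsing it (a
mixed-effects treatment of patient as a random effect is out of scope).

The qualitative pattern the package is expected to reproduce, and which its
acceptance tests check over 50 seeded study replicates (24 patients × 2
sides, physicians with gains 0.9/1.0/1.1 on one device): the GSM
Kruskal–Wallis across physicians is significant for raw random images and
non-significant for standardized-normalized images in at least 90% of
replicates. Normalization alone cannot fix free acquisition — an offset, or
any non-multiplicative operator effect, survives a purely multiplicative
correction — which is why the random-normalized category is exposed
separately.

## Problem sizes and runtime choices

Single-phantom examples and the re-anchoring checks use the full 800 × 600
raster (fascia region ≈ 2.8 × 10⁴ pixels). Replicated study simulations use
256 × 192 rasters: the GSM and the rank tests depend on region medians, which
are stable for regions above ~10³ pixels, so the reduced raster changes
nothing statistically while keeping 50 replicates of a 288-image study
tractable. Null-calibration checks use 2000 simulations per test at group
size 15. Masks for a study's shared ROIs are computed once and memoized.

## Known limitations

* The fallback band boundaries are a uniform tiling, not the published ones;
  supply a transcribed configuration for comparisons against published band
  percentages.
* One-point normalization corrects only multiplicative distortions exactly;
  additive offsets are reduced, not removed.
* The wrapper statistics assume independent rows, as the protocol does;
  repeated measures on the same patient are not modeled.
* BMP support covers uncompressed 8-bit palette and 24-bit files — the
  variants ultrasound systems export — not RLE or bitfield variants.
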