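---
title: "Quantifying fly eye pigmentation: models, conventions and design notes"
author: "eyeQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fly eye pigmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyeQuant)
```

# The measurement model

`eyeQuant` treats an adult fly eye as an elliptical region of a macro
photograph and its pigmentation as the distribution of per-pixel *pigment
values*: each RGB pixel is color-inverted and collapsed to weighted 8-bit
grayscale, so that 0 is pure white, 255 pure black, and darker (more
pigmented) red eyes score higher. The weights are the ITU-R 601 luminance
weights (0.299, 0.587, 0.114), the convention behind ImageJ's "weighted"
RGB-to-gray conversion with which this package interoperates.

Two conventions in that arithmetic deserve explicit statement because they
propagate through everything else:

* **Order of operations.** Inversion happens *before* the grayscale
  conversion: `pigment(c) = gray(255 − c)`. Because the weights sum to 1,
  this agrees with `255 − gray(c)` to within one unit of rounding, and the
  test suite enforces that ±1 equivalence for random triples.
* **Rounding.** The weighted sum is rounded half-up (`floor(x + 0.5)`).
  Under this rule pure red maps to gray 76 (0.299·255 = 76.245) and to
  pigment 179 (0.587·255 + 0.114·255 = 178.755). The synthetic generator's
  inverse color ramp is solved under the same rule, which is what makes the
  render-and-extract round trip exact.

## ROI geometry and the extraction scan

A segmented eye is an axis-aligned ellipse stored by its bounding box in
0-based pixel coordinates (origin top-left). A pixel (x, y) belongs to the
eye iff its center satisfies

$$\left(\frac{x + 0.5 - c_x}{a}\right)^2 +
  \left(\frac{y + 0.5 - c_y}{b}\right)^2 \le 1,$$

with the center and semi-axes derived from the bounding box. Extraction
enumerates the bounding box row-major (y outer, x inner) and emits one row
`(ROI name, pigment value)` per contained pixel, ROIs in set order — so a
pixel table is fully reproducible from an image plus an ordered ROI set,
and tables written by ImageJ's equivalent macro loop concatenate cleanly
with ours. The pixel-center rule is this package's documented containment
convention; ImageJ's own oval hit-test is not published to the bit, so we
assert parity against a brute-force evaluation of the inequality, not
against ImageJ binaries. Bounding boxes may overhang the image; extraction
clips, and a fully off-image ROI yields zero rows with a warning.

ROI names carry the experimental design in delimited fields, by default
`sex:genotype:replicate:user`. Parsing is positional: surplus tokens are
retained as extras, missing trailing fields become `NA` rather than being
dropped, and formatting is the exact inverse for delimiter-free fields.
Duplicate ROI names are an error (they would make CSV rows ambiguous), and
the delimiter is configurable but fixed per run.

# Estimation statistics

One eye contributes one number: the mean of its pixel values. Group
comparisons are reported as the difference of group means of per-eye means
with a 95% bootstrap confidence interval (`meanDifference()`), in the
estimation-statistics style — effect sizes with uncertainty, no
null-hypothesis tests. Design choices that the underlying workflow leaves
open, decided and fixed here:

* **Resampling unit: the eye.** Eyes, not pixels (pixel resampling would
  shrink intervals absurdly because thousands of correlated pixels share an
  eye) and not flies (left/right eyes are treated as independent samples;
  if that assumption bothers you, feed per-fly means instead).
* **Interval type: BCa by default.** Pigment scales are bounded and
  variegating genotypes are strongly skewed, so the bias-corrected
  accelerated interval (bias correction from the bootstrap distribution,
  acceleration from a leave-one-eye-out jackknife) is the default;
  `method = "percentile"` is the simpler fallback. With a degenerate
  bootstrap distribution (e.g. zero-variance groups) the BCa correction is
  undefined and the code falls back to percentile quantiles. The interval
  is additionally clamped to contain the point estimate, an invariant the
  `EffectSize` class enforces.
* **Resamples and seeds.** `nBoot = 5000` by default; every resampling run
  is seeded and records `(seed, nBoot, method, group sizes)` in the
  returned object, so an effect size is reproducible from its provenance.
  Our BCa and percentile intervals are cross-checked in the test suite
  against the independent implementation in the `boot` package on a fixed
  fixture.
* **Unweighted eyes.** A group mean weights each eye equally regardless of
  ROI area; sample standard deviations use the n − 1 denominator
  throughout.

Inter-operator reproducibility (`interoperatorCv()`) is defined as the
percent coefficient of variation of per-user genotype means,
`100 · sd / mean`. The workflow's empirical bound for trained student
operators is a CV of at most about 4%, rising to about 6% for the
lightest-eyed stocks — not because segmentation degrades, but because the
same absolute spread is a larger fraction of a small mean; the CV is
scale-equivariant, which the tests assert. A CV over a zero mean
(an idealized fully white eye) is undefined and raised as an error.

The two plot annotations `referenceLines()` returns — white ≈ 35 and
wild-type ≈ 140 — are published calibration landmarks of this imaging
configuration, used as visual anchors (beige and red horizontal lines) on
every figure; they are configuration defaults, not constants of nature.

# The synthetic generator: what it emulates, and what it does not

`renderPlate()` produces the package's test bench: a grid of elliptical
eyes on a uniform tray background, each filled from one of four pigment
patterns:

| pattern | emulates | parameters (units) |
|---|---|---|
| `distConstant(v)` | idealized uniform eye | target intensity v |
| `distNormal(mu, sigma)` | biological scatter | pigment units |
| `distMixture(v1, v2, p, patchScale)` | PEV mosaic (clonal silencing) | two intensities, silenced fraction, patch correlation length (px) |
| `distGradient(vTop, vBottom)` | dorsoventrally patterned eyes | intensities at eye top/bottom |

Colors come from a white→red→dark-brown ramp solved so that
`pigmentValue(intensityToRgb(v)) == v` for every integer v — an exhaustive
256-case test — which gives the generator its defining property: a
constant-v eye extracts back to mean exactly v with zero variance, and the
white (35) and wild-type (140) presets reproduce the calibration landmarks
exactly. Mosaic patches are thresholded smoothed Gaussian noise; the patch
geometry of real variegation is not quantitatively characterized, so
`patchScale` is a free generator parameter, not a biological claim.

The seven presets (`genotypePresets()`) span the realistic phenotype range:
`yw` constant 35 and `wt1` constant 140 anchored to the calibration
landmarks; `mini-white` normal(60, 8), `strongPEV` mixture(35, 110, 0.6),
`dorsal-eye` gradient(150, 45), `wm4` mixture(50, 140, 0.5), `wt2`
normal(140, 7) as plausible intermediates. Default geometry: eye semi-axes
(34, 26) px in 96 × 110 px cells, tray background intensity 12 (a light
3D-printed tray), an optional neutral 6-patch strip standing in for the
color checker. Rendering is bit-deterministic given the plate seed.

Operator variability (`jitterRois()`) perturbs each ground-truth ellipse
per simulated operator: center shifted by N(0, centerSd²) per axis and
semi-axes scaled by 1 + N(0, axisRelSd²), defaults 2 px and 0.05 — the
scale of placement disagreement expected from careful humans re-drawing the
same ellipse. Jitter that would collapse an axis is resampled with a
warning. Defocus stacks (`renderStack()`) blur each pixel with a Gaussian
of width `blurScale · |depth − focal plane|`; sigmas are quantized to
0.25 px so a slice costs only a handful of convolutions, and an in-focus
plane is copied through exactly.

What the generator does **not** emulate: ommatidial lattice texture,
bristles and specular glints, illumination gradients, chromatic variation
between stocks beyond the one ramp, camera noise and demosaicing, and
non-elliptical eye outlines. Passing tests therefore demonstrate the
*arithmetic and statistical* correctness of the pipeline — exact macro
equivalence, calibration, estimator behaviour, reproducibility bounds —
on images that are geometrically and photometrically idealized; they do
not certify segmentation quality or color fidelity on real photographs.

# Focus stacking

`planAcquisition()` is the rail arithmetic: covering a depth range D at
step s takes `ceil(D/s)` steps and `ceil(D/s) + 1` images (the canonical
configuration — 2750 μm at 50 μm — gives 55 steps and a 56-image stack
exactly; ceiling is chosen so a non-divisible range never under-travels).
The compositing algorithms used by commercial stackers are proprietary, so
`focusStack()` implements the standard open alternative: per-slice
sharpness as the local variance of the Laplacian of the grayscale image
(window 9 px), Gaussian smoothing of the per-slice sharpness maps
(radius 4 px by default, which regularises the decision map into coherent
regions), then a per-pixel argmax over slices. Ties break toward the
earlier (shallower) slice, making the composite deterministic and the
operation idempotent. No parity with any commercial stacker's output is
claimed; the contract, enforced on synthetic stacks with known sharp truth,
is that the composite's RMSE to the truth never exceeds the best single
slice's.

Numerical details: convolution borders are replicated; tiny negative local
variances from floating-point cancellation are clamped to zero; kernels are
capped at the image size so small test images remain valid inputs.

# Files and formats

* **ImageJ ROIs**: binary `.roi` (oval subtype only; anything else is
  rejected naming the offending entry) and `RoiSet.zip` archives, readable
  and writable; archives are written with stored (uncompressed) entries,
  which every unzip implementation including ImageJ's accepts. A plain-text
  dialect (`name,x0,y0,width,height` CSV) covers scripted use.
* **Pixel CSVs**: `,ROI,pixel` with a leading 1-based index column,
  imitating the ImageJ Results export; reading concatenates multiple files
  preserving file-then-row order and splits names into factor columns.
* **Images**: 8-bit RGB TIFF/PNG/JPEG. Alpha is dropped with a warning;
  16-bit input is rejected — the workflow is 8-bit end to end.
* **Config**: `runConfig()` serializes to YAML and round-trips exactly;
  `runPipeline()` logs seed and input/config checksums with every run.

# Problem sizes and limitations

The test and verification suites run entirely on generated data, sized for
tight feedback: rendering tests use 14 × 11 px eye semi-axes on 40 × 44 px
cells; the effect-size recovery checks use two groups of 30 eyes
(between-eye SD 10) with 5000 bootstrap resamples, plus a 200-replicate
coverage simulation at 600 resamples each; the inter-operator simulation
uses the full seven-preset plate (6 eyes per genotype, default geometry)
with five operators; the stacking check uses a 56-slice stack over a
64 × 140 px tilted-plane scene.

Known limitations: no automated eye segmentation (ROIs are drawn by humans
or generated synthetically); no color-checker-based white balance (the
checker is a visual control only); no RAW processing; exact bit-parity with
ImageJ's oval containment is asserted against this package's documented
rule, not against ImageJ; and the estimator treats eyes as exchangeable
within groups, ignoring fly- and vial-level structure.
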