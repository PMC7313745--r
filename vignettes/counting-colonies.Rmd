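---
title: "Counting colonies by prominence of brightness minima"
author: "colonycount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting colonies by prominence of brightness minima}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonycount)
```

## The counting model

Colony-forming units (CFU) on a backlit agar plate appear as dark,
roughly circular spots on a bright background. `colonycount` implements a
counting method built on two deliberate simplifications:

1. **Only the number of objects matters, not their outlines.** No
   thresholding or segmentation is attempted; colony size and shape are
   ignored.
2. **Every colony has exactly one darkest spot, at its center.** Counting
   colonies is therefore counting regional brightness minima.

These assumptions turn a hard segmentation problem (low contrast,
confluent colonies) into a robust peak-counting problem: two colonies
that have visibly merged are still counted as two so long as each keeps
its own dark core.

The pipeline applies five operators in a fixed order (`runPipeline()`):

| stage | operator | default | purpose |
|---|---|---|---|
| 1 | `subtractBackground()` | ball radius 50 px | remove broth-layer brightness gradients; background to white |
| 2 | `autoContrast()` | 0.35 % per tail, ROI statistics | spread gray values over the full range; equalize plates |
| 3 | `medianFilter()` | disc radius 6 px | suppress sensor noise; drop sub-0.25 mm specks |
| 4 | `liftBrightness()` | +135, saturating | push residual background above white |
| 5 | `findLocalMinima()` | prominence 10 | one point per sufficiently deep regional minimum |

All parameters live in a `PipelineParams` object whose defaults reproduce
the reference configuration for *E. coli* DH5alpha colonies of 0.5--4 mm
imaged at 40 um/pixel; every image operator returns an image of identical
dimensions with intensities in [0, 255], and identical inputs give
bit-identical outputs.

### Rolling-ball background subtraction

The background surface is estimated by grayscale **closing with a flat
disc structuring element** of the ball radius (for dark objects on a
light background; opening for the inverse polarity), then the image is
rewritten as `img - background + 255`. Structure wider than the ball
(twice the radius) is absorbed into the background; darker objects up to
that size survive with their local depth intact. The 50 px default
corresponds to a 4 mm maximum object diameter at 40 um/pixel — chosen
above the largest expected colony so that growth-rate variation does not
clip real colonies.

Two numerical choices matter here:

* **Flat disc, not a paraboloid.** The classical implementation in
  desktop tools approximates the ball by a downsampled paraboloid. The
  exact morphological definition is simpler, deterministic, and testable
  against a brute-force max/min oracle; only the contract (scales larger
  than the ball removed, smaller dark objects preserved) is promised, not
  bit-equivalence with any particular tool.
* **Edge replication on the input, composed exactly.** The two
  morphological passes are computed on an extended domain (input padded
  by twice the radius) so the erosion sees the true extended dilation.
  Composing independently clipped passes instead leaves brightness ramps
  un-flattened within one ball radius of the border — a visible artifact
  that the extended composition removes exactly.

### Automatic contrast expansion

Percentile stretch: the intensities at the saturation fraction's lower
and upper percentile (default 0.35 % per tail) map linearly to 0 and 255,
computed **over the region of interest only**. Restricting the statistics
to the ROI is essential because ink marks or labels outside the countable
area would otherwise anchor the stretch.

A region whose percentile range does not exceed `minRange` (default 32
gray levels, one eighth of the dynamic range) is returned unchanged.
Contrast expansion presumes the gray values represent either background
or objects; on an object-free region the range is pure sensor noise
(about +-2 sigma around the subtracted background) and stretching it
~16x would promote smoothed noise into structures deep enough to be
counted. The floor sits far above the noise spread of a flat region
(about 16 gray at sigma = 3) and far below the depth of any real colony
(well over 100 gray after background subtraction), so it only ever
affects empty regions.

### Median filtering and the brightness lift

The disc median (radius 6 px ~ 0.25 mm) suppresses noise while
preserving edges, and intentionally erases features smaller than its
working area — the same minimum size a human counter would apply.
Borders are handled by edge replication so the filter cannot create an
artificial dark rim that the minima detector would count. The saturating
lift (+135) then clamps everything within 120 gray of white to exactly
255: what remains below white is colony interior.

### Prominence-thresholded regional minima

A regional minimum is an 8-connected plateau of equal intensity strictly
darker than all neighbors (within the ROI). Its **prominence** is the
depth below the lowest saddle connecting it to a *dominating* minimum —
deeper, or equally deep with lexicographically smaller representative —
and for a basin that never meets a dominating one, the depth below the
lifted white level (255). Minima with prominence below the noise
tolerance (default 10 gray levels) are absorbed into their neighbors.
Implementation: union-find flooding over intensity levels (the classical
watershed order), which resolves ties deterministically:

* plateau minima report exactly one point, the plateau pixel nearest the
  plateau centroid, ties broken toward the smallest row then column;
* equal-depth basins meeting at a saddle: the one with the
  lexicographically smaller representative absorbs the other;
* pixels at exactly 255 are lifted background and never count.

Counts are invariant under 90-degree rotations and flips (the
tie-breaking choices can swap which of two equal basins is "parent", but
never how many basins are counted), and non-increasing in the prominence
threshold. Both properties are asserted in the test suite, along with
exact agreement with an independent brute-force prominence oracle on
random images.

## Plate geometry

`PlateLayout` describes a dish of known center and radius; the countable
region is the disc inset 3 mm from the rim (default) — rim colony
clusters and the thicker broth layer near the wall stay outside — either
whole (`makeFullPlateRoi()`) or split into six wedges of 60 degrees minus
a 4-degree gap (`makeSegmentRois()`), matching dilution plates inoculated
in six sectors behind drawn border lines. The exact inset and strip
width are parameters because practice varies ("a few millimeters");
wedges are half-open in angle so they stay disjoint even at zero gap.
Segment counts are multiplied by 6 (`scaleSegmentCount()`) to compare
with whole-plate enumerations.

## The synthetic plate generator

Real plate images are not distributable with the package, so every
end-to-end claim is tested against `generatePlate()`, which renders the
imaging conditions the pipeline was designed for at 40 um/pixel:

* background `230` plus a low-order polynomial field (+-15 gray,
  emulating variable broth-layer thickness) plus Gaussian sensor noise
  (sigma = 3);
* colonies of 0.5--2 mm diameter (24 h growth) with center darkness
  drawn from 120--200 gray below local background — under transmissive
  illumination colonies are near-opaque, and depths much below ~100 are
  structurally invisible to the +135 lift after typical contrast gain,
  so shallower defaults would contradict the one-darkest-spot premise;
* radial profile `darkness * (1 - rho^6)`: a near-flat opaque core with
  a steep smooth rim. The exponent balances two opposing requirements,
  measured during design: the radius-6 median filter must retain the
  core of a 0.5 mm colony (favors a flat profile), while two colonies
  overlapping by 30 % of their diameter must keep a saddle at least one
  noise tolerance shallower than their cores (favors a peaked profile);
* overlapping colonies combine by per-pixel **maximum** of their depth
  profiles — colonies are opaque domes side by side, not stacked ink —
  which preserves one darkest spot per colony under confluence;
* placement by uniform rejection sampling with a minimum center
  separation (default twice the largest diameter: "well-separated"
  suites), each colony fully inside its ROI as the drawn border lines
  enforce on real dishes; infeasible packings raise an error rather than
  silently placing fewer colonies.

Generation is a pure function of the spec (including its seed).
`generateConfluentPair()` renders exactly two colonies at a prescribed
overlap fraction for characterizing the confluence limit; it uses the
spec's largest diameter and mean darkness for both, since confluence is
a grown-colony phenomenon and the small-diameter end of the range (cores
nine pixels apart, inside a single median disc) cannot carry two
resolvable cores at any profile.

What the generator does **not** emulate: bubbles and foreign particles
in the agar (avoided by plate preparation, and explicitly out of scope),
the dark ring of the dish wall, colony shape irregularity, and spatial
correlation of sensor noise. Passing the recovery suite therefore shows
the pipeline is correct *for clean, well-prepared plates of a
circular-colony organism*; it does not certify performance on damaged or
contaminated plates.

Suite sizes were chosen for a desk-scale run: the recovery acceptance
uses 50 plates of 1200x1200 px with 10--33 well-separated colonies each
(random sequential placement jams near ~45 colonies at the default
4 mm separation on this dish size), and oracle-equivalence checks use
100 random 32x32 images.

## Method-comparison statistics

The validation module reproduces the comparison of three enumeration
methods over 25 plate samples (three enumerations each): on-screen
point-and-click reference counting ("gold standard"), manual pen
marking, and the automatic pipeline. From the packaged table,
`validationReport()` recomputes:

* mean variation coefficients of repeated counts (reference 1 %, manual
  5 %), `meanVariationCoefficient()`;
* mean counting rates (reference 1.1/s, manual 1.9/s), `meanRate()`;
* the **error-weighted regression through the origin**,
  `originRegression()`: with zero colonies all methods must agree, so
  the model is `y = b x`, and because individual repeat SDs are often
  zero, each point carries assigned *relative* errors instead (1 % on
  the reference; 0.1 % on automatic counts, which are deterministic;
  5 % on manual counts). The slope minimizes the effective-variance
  chi-square `sum((y - b x)^2 / ((b cvX x)^2 + (cvY y)^2))`.

Numerical choices, and two findings a user of these statistics should
know:

* Only one parameter survives the origin constraint, so the minimum is
  located by Brent search (tolerance 1e-10), checked against a dense
  grid search; a Levenberg-Marquardt iteration would find the same
  minimum. The *full* minimization of the chi-square is essential: the
  fixed-point variant that freezes the weights at each iteration
  converges to a visibly different slope (0.973 vs 0.976 on the packaged
  table) and does not reproduce the published analysis.
* The 95 % CI comes from the chi-square curvature at the minimum
  (slope +- 1.96 standard errors). The original analysis does not state
  its CI construction, so the curvature intervals are reported alongside
  the published ones without being enforced.
* `correctionFactor()` is `1/slope` computed at the slope's reported
  3-decimal precision, matching how the published factors (1.025, 1.095)
  were derived from the printed slopes.
* **Known estimator property:** because the observed `y` enters the
  weight denominators, downward-fluctuating points get slightly more
  weight, biasing the slope low by roughly `2 cvY^2` relative — about
  0.5 % (half a standard error at n = 25) at a 5 % y-error, negligible
  at 0.1 %. Simulated 2-SE coverage is accordingly ~95 % at the
  automatic error assignment but only ~93 % at the manual one. The
  estimator-recovery test therefore runs at the automatic assignment;
  the bias is a property of the effective-variance weighting itself.

The packaged table stores counts exactly as published and recomputes the
two ratio columns from them (round half-up to two decimals): in the
published table one row's printed ratios are inconsistent with its
printed counts, and the regression slopes confirm the counts are what
the published analysis used.

## Degenerate inputs and conventions

* All linear intensity rescaling rounds half-up to integers; products
  are formed before quotients so exact halves are hit deterministically.
* Coordinates are 1-based `(row, col)` pixel indices, R's matrix
  convention, used consistently in detections, ground truth CSVs and
  annotations.
* Constant images: background subtraction returns all-white (nothing
  below the ball's scale), contrast and median return the input, minima
  detection returns nothing (a plateau with no brighter neighbor is not
  a minimum).
* Empty ROIs yield empty center lists; an inset that swallows the dish,
  a wedge gap of 60 degrees or more, an image/layout size mismatch, and
  non-8-bit color inputs are errors, not warnings.

## Limitations

* Parameters are calibrated for dark circular colonies at ~40 um/pixel;
  other organisms or optics require re-deriving the ball radius, median
  radius and lift from the physical sizes involved, and a fresh
  comparison against reference counts.
* Touching colonies are resolved only while each keeps a darkest core;
  beyond roughly 50 % center overlap (at the default profile) pairs
  merge into one count, and no cluster-splitting heuristic is attempted.
* Blank-plate behavior depends on the contrast floor described above;
  plates whose true colonies are shallower than the floor after
  background subtraction would be reported empty.
* The rim area inside the inset is deliberately never counted.
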