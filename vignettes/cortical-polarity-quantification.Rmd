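---
title: "Quantifying cortical protein polarity with CortexQuant"
author: "CortexQuant maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical protein polarity with CortexQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CortexQuant)
```

## The measurement problem

In yolky embryonic cells (e.g. *Xenopus* gastrula chordamesoderm), any
soluble fluorescent marker looks "enriched" wherever the cytoplasm is free
of yolk platelets — most conspicuously in the large protrusions at the cell
poles. An apparent polarised accumulation of a protein such as Dishevelled
(Dvl) can therefore be pure volume artefact. The remedy is ratiometric:
express the protein's distribution *relative to* a cytoplasm-filling,
biologically inert reference (rhodamine–dextran) that shares exactly the
same yolk-excluded support. CortexQuant implements that measurement as a
reusable, testable pipeline:

1. **Outline** a single labelled cell with a parametric active contour
   (snake), or take the outline from ground truth / manual input.
2. **Partition** the cell into four domains — NSB-directed (toward the
   notochord–somite boundary), anti-NSB, anterior, posterior — by the two
   diagonals of the bounding rectangle oriented along the cell's NSB axis.
3. **Measure**, per domain and channel, summed intensity over the whole
   cell or over a 5 µm cortical band, always excluding the nucleus, and
   convert to *fractional fluorescence*
   \(f_{d,c} = S_{d,c} / \sum_{d'} S_{d',c}\).
4. **Ratio**: the per-domain statistic is the ratio of fractions
   \(R_d = f_{d,\mathrm{sig}} / f_{d,\mathrm{ref}}\), which is invariant to
   the expression level of either marker and equals 1 everywhere when the
   protein merely fills cytoplasm.
5. **Test** for a within-cell domain effect with a one-way repeated-measures
   ANOVA across the four domains, Greenhouse–Geisser (GG) corrected, with
   Bonferroni-adjusted paired post hoc comparisons (factor 6).
6. **Puncta**: detect discrete bright spots (multiscale Laplacian of
   Gaussian), keep those whose centroid lies in the cortical band, and
   normalise per-domain counts by the domain's contour arc length.

Because no imaging data are distributed with the package, every stage is
validated against a synthetic-image generator with complete ground truth.

## The synthetic cell model

`generateCellGeometry()` draws a star-shaped (hence simple) polygon: an
ellipse of length 40 µm and width 20 µm carrying smooth cosine protrusion
bumps (relative amplitude 0.35, angular half-width 0.7 rad) at the cell
ends dictated by the polarity class — both ends for bipolar cells, one for
monopolar cells, none for unpolarised or boundary-captured cells — plus
low-order random radial roughness (5 %). A nuclear ellipse (5 × 4 µm
semi-axes) is placed near the centre, and 12 yolk platelets (radius 1–2.2
µm) are packed by rejection sampling inside the outline, clear of the
nucleus and the boundary. These dimensions are typical of mid-gastrula
chordamesoderm cells in a single optical section; packing failure raises an
explicit error after a bounded number of attempts.

`renderCell()` rasterises the geometry at 0.25 µm/px (a typical 63×
confocal sampling; pixel centres at integer 0-based coordinates, row =
image y) and builds per-pixel intensity expectations:

* both channels share the base cytoplasm level (60 / 80 photons per pixel
  for signal / reference), are zero on yolk (hard exclusion), and carry
  per-channel nuclear factors (0.7 / 1.3 — the dextran-marked nucleus; the
  nuclear level of the reference is not a measured constant, so it is an
  exposed parameter rather than a fixed value);
* the **signal channel only** is multiplied by a per-domain cortical
  enrichment inside the 5 µm band (all 1 by default — the null), and may
  receive Gaussian puncta (amplitude 150 photons, σ 0.5 µm) planted in the
  band at per-domain Poisson rates; a cortex-uniform null is available as a
  rate per µm of contour (per-domain means proportional to arc length),
  since equal per-domain *counts* would themselves be a planted bias once
  densities are normalised by unequal domain lengths;
* the signal channel is modulated by a spatially correlated log-normal
  **texture field** (CV 0.15, correlation scale 3 µm, unit mean). This
  models protein-pool inhomogeneity that the volume marker does not share —
  without it, the only per-cell variance in the domain ratios would be shot
  noise on sums over thousands of pixels, giving per-domain ratio SDs far
  below anything seen in real cells. With it, per-cell domain ratios have a
  CV of roughly 5–8 %, a realistic scale that makes group tests behave like
  the emulated experiments (clear significance at 1.5×, weaker at 1.2×,
  none at 1.0×);
* noise is applied last: Poisson shot noise, then Gaussian read noise
  (σ = 2), then a constant camera offset (4), clipped at zero. With all
  noise off and offset 0 the background is exactly zero, matching the
  zeroed-background acquisition contract, and the per-pixel signal/reference
  ratio is exactly constant on cytoplasm.

What the generator deliberately does **not** emulate: a point-spread
function (intensities are piecewise-constant expectations, not
optics-blurred), 3-D structure (a single 2-D section only), photobleaching,
time-lapse dynamics, and abutting labelled neighbours (cells are isolated,
as in mosaic expression). Passing tests on these images therefore validate
the measurement geometry and statistics, not robustness to optical blur or
segmentation of confluent tissue.

`generateField()` places cells in non-overlapping tiles with centroids at
controlled distances (in mean-cell-diameter units, diameter =
(length + width)/2 = 30 µm) from a vertical NSB line, axes pointing toward
the line with ±0.15 rad jitter, and emits one annotation row per cell.

## Geometry conventions and numerical choices

* **Quadrants.** The bounding rectangle is aligned to the cell's NSB axis
  (not the image axes), so "NSB-directed" is well defined for oblique
  cells. Each cell pixel is classified by the sign pattern of the two
  rectangle diagonals in normalised rectangle coordinates. Ties (points
  exactly on a diagonal) go to the sector counter-clockwise of the
  diagonal; the centre belongs to NSB. "Anterior" is the flank 90°
  counter-clockwise (in the mathematical x/y sense) from the NSB direction
  — a labelling convention only, since the statistics treat the two flanks
  symmetrically.
* **Arc lengths.** The contour polyline is split exactly at its
  intersections with the diagonals and each piece accrues to the domain of
  its midpoint, so domain lengths sum to the perimeter to machine
  precision; a contour may cross a diagonal any number of times
  (protrusions).
* **Cortical band.** A cell pixel is cortical iff its centre lies within
  the band width of the contour *polygon* (sub-pixel distance, not a
  rasterised distance transform); width defaults to 5 µm. A width beyond
  the inradius yields the whole cell with a warning.
* **Rasterisation.** A pixel belongs to a mask iff its centre is inside
  the polygon (even-odd rule); rasterised area tracks the shoelace area to
  < 2 % for cells of realistic size.
* **Ratios** are formed from domain sums, never pixelwise, so
  zero-reference pixels (yolk) cannot destabilise them. Nucleus exclusion
  is applied at measurement time in both whole-cell and cortical regions
  (the nucleus rarely touches the band, so the cortical effect is nil) and
  never changes arc lengths.

## The snake

The active contour uses the classical internal energies (elasticity
0.15, stiffness 0.05), an edge-attraction force — the gradient of the
squared gradient magnitude of the Gaussian-smoothed image (σ 2 px), whose
stable zero lies on the intensity edge — and an inflation (balloon) force
(0.6) along the outward normal that carries a small initial circle placed
inside the cell out to the edge's capture range. Integration is explicit
Euler (step 0.3) with per-vertex displacement capped at 1 px per
iteration, arc-length resampling to 2 px spacing every 10 iterations,
convergence when the mean displacement drops below 0.02 px (cap 1500
iterations, returning the best contour with a warning flag), and a
self-intersection check resolved by coarser resampling or failure. Dark
intracellular holes (yolk) are filled by grayscale morphological closing
(disc radius 9 px) before force computation so the snake settles on the
outer boundary. With balloon and image forces at zero the contour shrinks
under pure elasticity — a property used in the tests. On noise-free
fixtures the snake reaches IoU ≥ 0.99 and mean boundary error < 0.4 px
against ground truth; a ground-truth bypass (`segmentFromTruth()`) lets
downstream modules be validated independently of snake quality. Nucleus
outlines are treated as *input* (manually outlined in the emulated
workflow), not auto-segmented.

## Statistics

`ggEpsilon()` implements Box's epsilon from the double-centred sample
covariance of the four repeated measures, clipped to [1/3, 1]; constant
data return ε = 1 with a degeneracy flag. `rmAnovaGG()` computes the
one-way within-cell F and evaluates it at (3ε, 3(n−1)ε) degrees of
freedom. "ANOVA" is read as repeated-measures across domains of the same
cells — comparisons are within-cell and a sphericity correction is cited
in the emulated analysis, which only makes sense for repeated measures.
Post hocs are paired t-tests on the 6 domain pairs with Bonferroni factor
6; stars follow the 0.05 / 0.01 / 0.001 convention. The GG correction is
conservative where it matters: for F in the rejection region the corrected
p is never smaller than the uncorrected one (for F < 1 the inequality can
reverse — irrelevant to error control). The analysed statistic defaults to
the untransformed per-cell ratio (a log option would be natural for
strongly skewed ratios, but at the CVs produced here skew is mild and the
untransformed scale matches the emulated plots). Distance strata default
to ≤2, 3–4 and ≥5 cell diameters (edges configurable). Ratio and fraction
summaries report mean ± 2×SD; puncta densities report mean ± 2×SEM.

## Validation suite and problem sizes

The acceptance tests regenerate everything from scratch: 100 replicate
83-cell null datasets (whole-cell ratios must be non-significant in ≥ 90 %),
500 replicate 30-cell null groups for the empirical type-I error
(within [0.03, 0.08] at α = 0.05), 50 replicates of three 30-cell class
groups for planted-enrichment recovery (1.5× planted in toward-facing
classes must be starred there and not in the away class, with the measured
cortical elevation within 10 % of 1.5), 50 replicates of a 30-cell
distance-gradient field (1.5 / 1.2 / 1.0 across bins must give
monotonically decreasing significance), 50 random polygons compared against
brute-force line-side, midpoint-split and exact-distance oracles, 5
noise-free snake fixtures, an SNR-5 detector fixture and 40 replicate
uniform-puncta fields. `scripts/acceptance.R` recomputes the same
quantities at reduced replicate counts (30 / 120 / 20 / 20) so a complete
run takes a few minutes on one CPU; both sizes give the binomial rates
quoted above comfortable Monte-Carlo precision.

## Known limitations

* Yolk platelets inside the cortical band are not separately segmented at
  measurement time (they exist only in ground truth); because both
  channels are excluded identically, the ratio statistic is unaffected,
  but per-channel cortical sums underestimate yolk-free cortical density.
* The detector is validated against synthetic truth only; whether the
  emulated counts were manual or automated is unknown.
* Single 2-D optical sections; no z-reconstruction.
* The node-binning alternative to exact diagonal splitting of arc lengths
  (sensitivity option) shares the same oracle only in the limit of dense
  vertices.
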