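---
title: "Methods: pore morphometrics and front kinetics in lyomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore morphometrics and front kinetics in lyomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyomorph)
```

## Scope and conventions

`lyomorph` analyzes two kinds of freeze-drying-microscope data: single
micrographs of the dried porous structure, and time-lapse sequences of the
same field of view while the sublimation front traverses it. Throughout the
package an image is a numeric matrix `m[row, col]` with row 1 at the top;
x is the column index, y points up (i.e. `-row`), and angles are measured
counter-clockwise from the +x axis. Pixel centers sit at integer 1-based
coordinates, and physical positions in micrometres count pixel widths from
the image border. One global seed fans out to fixed per-stage seeds
(`derive_seed()`), so each stage is independently reproducible and a full
pipeline rerun is byte-identical.

## Segmentation

The pore phase is isolated in four steps:

1. **Binarization.** Default is Otsu's threshold on the gray-level
   histogram; it is parameter-free and deterministic. FDM practice often
   uses a manually tuned threshold, which is supported
   (`threshold_method = "manual"`), as is a local adaptive threshold
   (window half-width and offset in config) for uneven illumination.
   Polarity is explicit: walls bright and pores dark by default,
   switchable. A constant image has no Otsu threshold and is rejected.
2. **Border clearing.** Connected pore components touching any image (or
   ROI-crop) edge are deleted: cut pores have truncated areas and would
   bias the size distribution downward. The operation is idempotent and is
   verified against a brute-force flood fill from the border in the tests.
3. **Marker extraction.** The Euclidean distance transform of the pore
   phase is smoothed (Gaussian, `marker_smoothing_sigma`, default 1 px).
   Marker plateaus are pixels within `marker_tolerance` (default 1 px, in
   distance-map units) of the local maximum over a disc of radius
   `marker_min_separation` (default 5 px); plateau components closer than
   the separation are merged, highest peak first. The tolerance is what
   keeps a long lamellar pore as a single marker: its distance-map ridge is
   nearly flat, and boundary raster noise puts bumps of up to about one
   pixel on it, so a tolerance of 1 px bridges the ridge while the much
   deeper waist between two genuinely fused pores (for example two discs of
   radius 10 px whose centers are 18 px apart have a waist about 1.6 px
   below the adjacent maxima) still separates markers.
4. **Watershed.** A seeded priority flood on the smoothed distance map,
   restricted to the pore phase (compiled in `src/flood.cpp`): pixels are
   claimed in order of decreasing distance value starting from the marker
   pixels, with insertion-order tie-breaking, so the result is
   deterministic. Regions smaller than `min_pore_area` (default 4 px²,
   suppressing noise specks) are discarded and labels are canonicalized by
   raster order of each region's first pixel. The tests compare the flood
   against an independent brute-force nearest-marker growth on the distance
   map and require at least 95 % pixel agreement on random masks.

Connectivity (4 or 8, default 8) applies uniformly to components, border
contact and flooding.

## Pore morphometrics

* **Equivalent diameter.** `d_eq = 2 * sqrt(area / pi) * pixel_scale`, the
  diameter of the circle with the pore's area.
* **Shape.** The moment-equivalent ellipse in the regionprops convention:
  normalized second central moments of the pixel coordinates with the 1/12
  variance of a unit pixel added to the diagonal, axis lengths
  `2*sqrt(2)*sqrt(eigenvalues)`. The aspect ratio (shape factor) is
  major/minor and is 1 for discs. We chose the moment ellipse over a
  maximal inscribed ellipse because it is deterministic, standard, and
  matches the regionprops-style tooling used in FDM practice; the choice is
  recorded in the output metadata. A useful side effect of the 1/12 term is
  that even a single-pixel or collinear region has a finite minor axis
  (4·√(1/12) ≈ 1.15 px), so ratios never blow up; a `degenerate` flag is
  kept for defensive handling. The closed-form fit is verified against a
  brute-force projection search over a 0.25° angle grid.
* **Orientation.** θ is the angle between the pore's major axis and the
  front line (the line perpendicular to the travel direction), folded to
  [0°, 90°]: 0° means parallel to the front, 90° perpendicular. Only
  absolute values are used, which makes the axis's 180° ambiguity
  irrelevant. The front line is the global line perpendicular to the travel
  direction, not the local fissured tangent - the reference used when
  orientations are quoted per field of view. Near-circular pores
  (aspect ratio < 1.1) have noise-dominated axis directions; they are
  flagged `low_ar` and included by default, with an option to exclude them
  from orientation means.
* **Summaries.** Arithmetic means with Student-t confidence intervals
  (default level 0.95; half-widths undefined at n = 1). The t interval was
  chosen as the standard small-sample construction; its 95 % coverage is
  verified by simulation (10,000 replications of n = 50 normal samples) in
  the acceptance suite.
* **Size distributions** use user-supplied bin edges; records outside the
  range are counted in open-ended outer bins and flagged rather than
  silently dropped.

## Front kinetics

The sublimation front is the boundary between the dried porous region and
the still-frozen region. For each coordinate perpendicular to the travel
direction, the front position is defined as the farthest dried/frozen
boundary from the entry border.

The detector reduces the frame to a feature image and thresholds it. The
default feature is the absolute deviation of the gray level from the frozen
reference level (`feature = "contrast"`): the frozen phase is smooth and
sits at one gray level, while both dried phases (bright walls, dark pores)
differ from it, and since the dried/frozen boundary in a composited frame
is sharp this feature localizes the front to one pixel. The feature is
box-averaged across the perpendicular coordinate (`perp_window`, default
15 px) so pore interiors - locally smooth and potentially near the frozen
gray level - borrow wall signal from neighbouring columns without smearing
the front along the travel axis. A rolling local-standard-deviation feature
(`feature = "texture"`) is available for data whose frozen phase overlaps
the dried gray levels.

The frozen reference (median and MAD of the far-border strip of the first
frame, the strip the front reaches last) gives the decision threshold
(level + 5 spreads; the spread is floored at 10^-3 gray levels so noiseless
data still thresholds). Per column, the position is the majority change
point of the thresholded profile - the split maximizing above-threshold
pixels behind it and below-threshold pixels ahead - which is robust to
isolated misclassified pixels on both sides. Frames with fewer than 0.5 %
or more than 99.5 % dried-like pixels are classified as fully frozen
(positions 0) or fully dried (positions = extent) rather than measured.
Without a reference the frozen level is self-estimated from the frame's own
far strip and the frame must be detectably bimodal (Otsu split with classes
at least 5 pooled within-class standard deviations apart, a gate sitting
well between uniform noise at about 2.6 and genuine fronts at 16+ on
synthetic data); a uniform frame without a reference is an error ("front
not found").

Velocities are per-interval displacements of the column-mean position in
µm/min, restricted to the ROI's perpendicular extent. Only frames with a
*measured* boundary enter the velocity fit: classified positions of uniform
frames (0 or the full extent) are not detector measurements and would bias
the first and last interval; frames after the front exits the ROI are
dropped entirely, avoiding zero-displacement bias. The mean velocity is the
arithmetic mean of interval velocities with a Student-t interval,
consistent with the pore summaries. Because the detector's (sub)pixel
offset is constant across frames, it cancels in the differences; on
noiseless synthetic data the recovery is exact.

Primary drying ends when the slowest column (the minimum front position)
has traversed the extent; if the trace does not cover the traversal the
time is extrapolated as extent / mean velocity and flagged.

## Reporting

`roi_compare()` joins per-ROI structure means with per-ROI velocities.
ROIs from different fields of view are never mixed: the mass-transfer path
length differs between FOVs, so only structures inside one image are
comparable; the join enforces a single image identifier. Spiderweb (radar)
data min-max normalizes each metric across the compared ROIs; a metric
constant across ROIs carries no contrast and maps to 0.5 with a flag. This
normalization is idempotent. Condition-level tables aggregate replicate
runs as unweighted means of run-level summaries with t intervals over run
means (undefined for a single run).

## The synthetic-data generator

FDM micrographs of this kind are not publicly archived, so the package
ships a generator that emulates their statistical structure with exact
ground truth:

* **Microstructure.** Elliptical pores with configurable equivalent
  diameter distribution (default lognormal with mean 7 µm, within the
  3-11 µm range typical of sucrose/maltodextrin freeze-dried structures),
  aspect ratio (cellular preset: uniform 1.2-2; dendritic preset: uniform
  2.5-4) and axis-angle distribution (cellular: uniform; dendritic: normal
  wrapped onto the 180° axis circle, emulating directional ice growth).
  Packing is rejection sampling with a wall-thickness exclusion zone
  (default 3 px): a candidate is tested by growing both semi-axes by the
  wall thickness, a superset of the true Minkowski dilation, so accepted
  pores are conservatively separated and watershed-separable by
  construction. Placement is fully interior by default so the ground truth
  is unaffected by border clearing; cut pores can be enabled. An attempt
  budget converts infeasible packings (porosity beyond what sequential
  placement can reach, roughly 40-50 % for these shapes) into an explicit
  error naming the constraint.
* **Rendering.** Two gray levels (walls 0.75, pores 0.25 by default,
  polarity switchable), Gaussian optical blur (0.8 px), then additive
  Gaussian noise (0.03 gray levels) - the simplest model that reproduces
  the soft-edged, mildly noisy appearance of optical micrographs. The
  rasterizer uses exact trigonometry at multiples of 90° so rotated copies
  of one ellipse are pixel-for-pixel symmetric, and every stored truth row
  carries the analytic semi-axes, angle and the realized pixel area.
* **Time-lapses.** Frame k composites the dried field behind the true front
  and a smooth frozen texture (gray 0.45) ahead of it at 60 s cadence, with
  optional per-frame noise. Per-column true positions are
  `base_velocity * multiplier * t`. Multipliers come either from an
  explicit per-column vector or from the fissure model: columns whose pores
  are oriented perpendicular to the front ((θ - 45°)/45° > 0) are boosted
  and parallel ones slowed, smoothed along the perpendicular coordinate
  (Gaussian kernel, 10 px bandwidth) and scaled so the position spread at
  the final frame approximates `fissure_amplitude` (µm). This reproduces
  the *phenomenon* of a fissured front shaped by local microstructure as a
  generator behaviour, not as a physical claim. When all pores share one
  orientation the normalized modulation shifts all columns equally rather
  than fissuring - by design, since the modulation is relative to the
  field's own orientation contrast.

What the generator does **not** emulate: true dendrite branching (elongated
ellipses stand in for lamellae; sufficient to exercise every metric, but
real dendritic structures are connected networks), uneven illumination or
vignetting (available in tests via an added gradient), partially
transparent frozen phases, front curvature within a column, collapse or
shrinkage during drying, and any heat- or mass-transfer physics. Passing
recovery tests therefore demonstrates that the measurement chain is
unbiased on well-posed two-phase images with known truth - not that
segmentation of low-contrast experimental micrographs is solved; on real
data the manual/adaptive threshold and the texture front feature are the
knobs to reach for.

## Problem sizes and numerical choices

The test and acceptance suites use 420×420 px fields of 200 pores at
0.5 µm/px (ten seeded fields: five cellular, five dendritic with minor
semi-axes of at least 4 px and 3 px walls), 256-384 px time-lapses of 9-12
frames, 20 random ≤ 64×64 masks for the watershed/oracle comparison, and
10,000 replications for the confidence-interval coverage - sizes chosen so
the whole suite runs in well under a minute while keeping sampling noise
far below the tolerances being asserted (5 % on mean equivalent diameter,
10 % on mean aspect ratio and pore count, 3° on mean orientation, 5 % on
noisy velocity, ±1 % on CI coverage).

Deterministic tie-breaks are fixed everywhere: insertion order in the
flood, first-index maxima in the change point, raster-order canonical
labels, and highest-peak-first marker merging. Degenerate inputs have
defined behaviour rather than warnings: empty masks yield zero-pore label
maps, empty record sets refuse to summarize, constant images refuse Otsu,
uniform frames classify against the frozen reference or error without one,
and a stationary front refuses drying-time extrapolation.

## Known limitations

* The watershed marker parameters trade split/merge errors: separations
  below ~5 px oversegment elongated pores, tolerances above ~1.5 px merge
  genuinely fused round pores. The defaults fit pore minor radii ≥ 4 px;
  structures at 1-2 px resolution need a finer pixel scale, as in practice.
* Orientation means over near-isotropic (cellular) fields are
  noise-dominated per pore; they stabilize as means over hundreds of pores
  but should not be over-interpreted, which is why `low_ar` flags and the
  exclusion option exist.
* The contrast front feature assumes the frozen phase's gray level is
  distinguishable from the dried average; the texture feature covers the
  opposite case at the cost of ~half a texture window of positional bias.
* Velocities assume a constant frame interval (enforced within 1 %) and a
  monotone front; retreating fronts (for example collapse) are out of
  scope.
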