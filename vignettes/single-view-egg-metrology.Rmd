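---
title: "Single-view egg metrology: model, geometry and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-view egg metrology: model, geometry and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovometry)
```

# The measurement problem

A single perspective image cannot give metric lengths, but it preserves the
cross ratio of collinear points. If a reference segment of known world
length `R` lies parallel to the measured segment, and the vanishing line of
a world plane parallel to both is known, the measured length `Z` follows
from image measurements alone. `ovometry` applies this to eggs: a V-groove
carrier fixes the egg pose so that its major axis is horizontal and its
frontal outline is the true outline; two cards printed with crossed parallel
lines, standing in the same frontal plane, supply the vanishing geometry and
the reference lengths.

## The carrier

The groove's two walls make an angle `alpha` with the vertical bisector
plane. The egg's maximal cross-section circle (radius `b_e`, the semi-minor
axis) is tangent to both walls, so the egg axis floats at
`h = b_e / sin(alpha)` above the apex line ([resting_height()]) regardless
of egg size, with the major axis parallel to the frontal plane. At
`alpha = pi/2` the expression degenerates gracefully to a flat floor
(`h = b_e`). Outside `(0, pi/2]` the geometry is meaningless and the
function refuses. The packaged carrier is 75 x 64 x 34 mm with
`alpha = pi/3` and a 5 mm apex height: a 42 mm-minor-axis egg then rests
with its centre about 29 mm up, standing proud of the carrier as in a
typical acquisition.

## The length transfer

With image endpoints `a, b` (egg axis), `c, d` (reference, world-parallel
to the egg axis) and the vanishing line `l`:

* `e = (b v d) ^ l` — the vanishing point of the world direction `BD`;
* `f = (e v c) ^ (a v b)` — world lines `FC` and `BD` share the ideal point
  `E`, so `FCDB` is a parallelogram and the world distance `BF` equals `R`;
* `g = (a v b) ^ l` — the vanishing point of the measured direction;
* `Z = R * [d(b,a) * d(g,f)] / [d(b,f) * d(g,a)]`, signed distances along
  `a v b`, the `g`-factor computed by a limit-aware ratio that is exactly 1
  when `g` is ideal (measured direction parallel to the image plane).

This is implemented in `transfer_projection_point()` / `measure_axis()` and
is projectively exact: for any nondegenerate configuration with exact
projections and the true vanishing line the recovered length equals the
world length to floating-point precision (the test suite checks 500 random
poses at 1e-9 relative).

### Sign conventions fixed by the camera oracle

The interplanar forms are typeset ambiguously in most sources, so every
grouping and sign here is pinned to a pinhole-camera oracle rather than to
typography. With signed distances along the common image line, and `v` the
vanishing point of the reference direction:

* `interplanar_Zcr`: `Zr / Zcr = 1 - [d(r1,v) d(r2,cr)] / [d(r2,v) d(r1,cr)]`,
  where `r1` lies on the base plane, `r2` a known `Zr` toward the camera,
  and `cr` on the vanishing line. The world point imaged at `cr` sits at the
  camera's distance, which is what makes the bracket a ratio of plane
  distances. Physically `Zr/Zcr` lies in `(0, 1]`; brackets outside that
  range (beyond tolerance 1e-9 low, 1e-6 high) raise an
  inconsistent-configuration error.
* `interplanar_Zc`: `Zc = Zcr * [d(s2,cs) d(s1,v)] / [d(s1,cs) d(s2,v)]`
  with `s1` on the reference plane and `s2` on the measured plane; the
  grouping is the one that satisfies `CR(s2, s1; cs, v) = Zc / Zcr` on the
  oracle. Coincident planes return `Zcr` exactly.
* `interplanar_Z`: `rho = [d(x,c) d(x',v)] / [d(x',c) d(x,v)]` equals
  `Zc / (Zc - Z)`, giving the signed separation `Z = Zc (1 - 1/rho)`
  (positive toward the camera; coincident points return 0; `|rho| < 1e-9`
  is rejected as unbounded). Callers take the absolute value when a length
  is wanted; the sign is retained so configurations on either side of the
  base plane stay consistent.

A vanishing point at infinity is handled throughout by the exact limit: the
two distance factors containing it cancel to 1, which reduces every formula
to its affine (similar-triangles) counterpart.

# Homogeneous-geometry conventions

Points and lines are homogeneous triples; `join`/`meet` are the cross
product (one computation, by duality). After every join/meet the result is
rescaled so its largest-magnitude coordinate is 1, keeping long constructive
chains away from overflow. Equality is proportionality, tested through the
cross-product norm at 1e-9. A point is ideal when `|h3|` is below 1e-12 of
the largest coordinate. Collinearity for cross-ratio inputs is accepted at
an incidence residual of 1e-6 after normalization (callers may loosen it for
points far from the origin, where normalized residuals grow). Signed
distances along a line take the orientation induced by the first two finite
points passed. Image coordinates are 0-based, x right, y down, at pixel
centres; the clockwise 90-degree frame rotation is
`(x, y) -> (H - 1 - y, x)` with ideal points rotated as directions and lines
mapped contravariantly.

# Vanishing-point estimation

`estimate_vanishing_point()` is a deliberately small, fully seeded
MLESAC-style estimator: hypotheses are meets of two sampled support lines;
each segment is scored by the RMS perpendicular distance of its endpoints to
the line joining the hypothesis and the segment midpoint, truncated at
`(3 * noise_scale)^2`; the best hypothesis is polished by Nelder–Mead on the
robust cost (500 iterations by default). A pencil of mutually parallel
support lines (within 1e-9 on the direction cross product) short-circuits to
the common ideal point. With noiseless concurrent segments the sampled meet
is already exact, and refinement is skipped below numerical noise, so
recovery is exact for any seed.

Accuracy under noise depends strongly on where the vanishing point lies:
each segment of length `L` with endpoint noise `sigma` constrains the
vanishing point laterally to about `sigma * sqrt(2) * D / L` at distance
`D`. The recovery experiments therefore use pencils whose vanishing point is
near the frame (x about 700 at 640x480, segments about 150 px), where the
3 px target is information-theoretically attainable; the default scene's
card vanishing points lie several thousand pixels out, where no estimator
could localize them to pixels — and where, equally, the measurement needs
them only as directions.

The right card is processed in the 90-degree-rotated frame
(`rotate_frame_90()`), mirroring the acquisition practice of rotating the
image so the second card's pencil becomes horizontal, and the estimate is
mapped back before the two vanishing points are joined into the vanishing
line.

# Mask-based endpoints

Three extractors are provided, trading simplicity for stability:

* `region_extreme_points()` — the two support pixels along a direction, ties
  broken by smaller row then smaller column. Simple and contract-exact, but
  on the flat tip of an egg silhouette the extreme *pixel* can sit several
  pixels off the true tangency point laterally, which the far vanishing-line
  intersections then amplify.
* `region_support_centroid()` — centroid of all region pixels within a 1 px
  slab of the extreme projection; subpixel and nearly unbiased on smooth
  convex outlines.
* `region_moment_ellipse_points()` — support points of the area-moment
  ellipse (`M = 4 * cov` plus the 1/12 pixel-variance correction); uses
  every region pixel and is the default inside the raster pipeline, where
  the silhouette is elliptical by construction.

Because the carrier fixes the egg axes parallel to the card stroke
families, the egg-axis and reference image lines are known to pass through
the corresponding vanishing points. `snap_endpoints_to_vp()` projects noisy
endpoints onto the least-squares line through the vanishing point before the
transfer; this removes exactly the lateral noise component the construction
amplifies most, passes exact data through unchanged, and is applied by
default when building measurement scenes from simulator truth.
`average_reference_endpoints()` implements the complementary multi-image
rule: the cards are static across acquisitions, so averaging their noisy
image coordinates over a batch suppresses reference noise before
measurement (`measure_batch(average_reference = TRUE)`).

The reference used by the raster pipeline is a full printed stroke (every
stroke of a family has the same known world length), measured against the
better-offset half of the family and averaged — strokes whose support line
passes near the egg-axis line give an ill-conditioned transfer and are
excluded by construction, not by outcome.

# The synthetic scene generator

`make_scene()` builds a pinhole camera (640x480, 720 px focal — a short
machine-vision lens — placed at (40, -225, 75) mm looking at the nominal
egg position, a fixed rig that does not re-aim per egg), a prolate-spheroid
egg resting in the carrier, and two 60x60 mm cards in the frontal plane with
4 strokes per direction at 10 mm spacing, stroke length 50 mm (the second
stroke of each family is the designated reference, `ref_length_mm = 50`).
The pose gives mild perspective: finite vanishing points, egg spanning
roughly a quarter of the frame width, as in a close-up bench acquisition.

Ground truth is exact: projected axis endpoints, the silhouette conic by
dual-quadric projection (`C* = P Q* P^T`, inverted and sign-normalized so
the interior is negative), silhouette extreme points in closed form
(tangent lines with normal parallel to the direction, via the dual conic),
stroke segments, vanishing points and vanishing line.
`render_scene()` classifies pixels exactly (conic interior; plane
homography for the cards), paints flat-ended rectangular strokes, and emits
a near-palette RGB image for the classical segmenter.

`generate_batch()` draws egg sizes from independent normals — major
`N(54, 1.9)` mm, minor `N(42, 0.8)` mm, matching a retail sample of
medium eggs — with a shared carrier/camera/cards, optional Gaussian endpoint
noise (`noise_px`), and silhouette endpoints by default (what a mask-based
pipeline actually sees). Everything is reproducible from one integer seed.

What the generator deliberately does **not** emulate: lighting, shadows and
the dark egg–carrier contact band (a known segmentation hazard in real
images), lens distortion, non-ellipsoidal egg shape (the pointed pole of a
real egg breaks the prolate-spheroid symmetry; an asymmetric profile is
left as future work), card misalignment out of the frontal plane, and any
texture or colour variability. Passing tests on synthetic batches therefore
demonstrate the geometry and the pipeline mechanics, not robustness to real
segmentation failure modes — the known dominant error source on
photographs.

# Known biases and limitations

* **Silhouette bias.** The extremal chord of a perspective silhouette is
  slightly longer than the projected maximal cross-section, so mask-based
  endpoints overestimate both axes by an amount that grows with proximity
  (about (size/distance)^2 relative). The bias is measured by the simulator
  (the test suite asserts the chord is never shorter and shrinks
  monotonically with camera distance) and is *reported, not corrected*,
  matching the mask-based measurement procedure itself.
* **Conditioning.** The length transfer intersects nearly parallel lines
  when the camera is near-frontal; endpoint regularization (vanishing-point
  snapping, moment-ellipse endpoints, multi-stroke averaging) is essential
  and documented above. A strongly oblique camera would condition the
  vanishing geometry better but destroys the very outline fidelity the
  carrier exists to provide; the near-frontal pose is the right trade.
* **Regression direction.** Agreement statistics regress measured on
  actual. R² (the squared correlation) and hence adj.R² and the simple-OLS
  F are direction-invariant; only the reported slope/intercept depend on
  the choice.
* **F statistics.** `ols_report()` returns the simple-regression
  `F = R^2 (n-2)/(1-R^2)` consistent with its own R²; published F values
  derived from an unstated model are displayed by callers, never asserted.
* **Segmentation.** `segment_classical()` is a controlled-scene fallback
  (colour thresholds, morphological opening/closing, connected components),
  not a general segmenter; on real photographs a learned segmenter would
  take its place, feeding the same mask interface.

# Problem sizes used by the checks

The property suites use 500 random poses for projective exactness, 1000
random projective maps for cross-ratio invariance, 40 poses for the
interplanar chain, 50 seeds for noisy vanishing-point recovery, 100 random
carrier configurations for the tangency oracle, a 100-scene noisy batch for
the end-to-end error scale, and a 6-scene rendered batch for the full
raster pipeline — sizes chosen so the whole suite exercises every claim at
desk scale while each stochastic bound retains a comfortable margin.
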