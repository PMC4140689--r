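---
title: "Detecting bilateral symmetry from keypoint constellations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bilateral symmetry from keypoint constellations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symaxis)
```

## The model

`symaxis` treats bilateral symmetry detection as a voting problem on a
sparse point set. A single-object image is reduced to keypoints with
scale-invariant locations and local gradient statistics; if the object has
a mirror axis, the keypoint constellation is (approximately) invariant
under reflection across that line, and so is the field of local gradients.
The detector therefore needs three ingredients:

* a **centroid** so the constellation can be expressed in polar
  coordinates `(r, θ)` and reflection becomes the one-line rule
  `θ ↦ 2α − θ` for an axis at angle `α`;
* a **pair test** deciding whether two keypoints are mirror images of each
  other, combining geometry (`|r₁ − r₂| ≤ θr`,
  `|wrap(θ₁ + θ₂ − 2α)| ≤ θθ`) with gradient consistency
  (magnitudes within a ±5 band after normalising the constellation maximum
  to 100; orientation within ±2 histogram bins of the reflected partner
  orientation `2α − Q`);
* a **sweep** over candidate angles `α = 0, Δα, …, 180° − Δα` in which
  every accepted pair casts one vote, the arg-max wins, and a minimum vote
  count separates *symmetric* from *asymmetric*.

Axes are undirected, so 180° of sweep covers every line. Pairs are
assigned one-to-one (greedy, ordered by combined residual
`|Δr|/θr + |Δθ|/θθ` with a lexicographic tie-break) so a dense cluster
cannot inflate one candidate's count; points within 1 px of the centroid
are excluded because they lie on every axis.

### Assumptions

One object, one straight axis, keypoints dense enough on both halves. The
approach inherits the feature detector's failure modes: too few keypoints
(weak texture) gives an *undetermined* verdict, and abundant off-object
structure biases the centroid (this is the documented failure mode of the
underlying method — and the motivation for the refinement below).

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `delta_alpha` | 1 | degrees | sweep increment; 180 candidates |
| `theta_r` | 2% of radial range | px | radial mirror tolerance |
| `theta_theta` | `delta_alpha` | degrees | angular mirror tolerance |
| `grad_mag_tol` | 5 | 0–100 scale | magnitude band |
| `grad_ori_tol` | 2 | histogram bins | orientation band |
| `window` | 16 | px | gradient histogram window |
| `n_bins` | 36 | — | orientation bins (10° each) |
| `sigma_factor` | 1.5 | × scale | Gaussian weighting width |
| `orientation_floor` | 5% | of histogram mass | unoriented cut |
| `vote_fraction` | 0.2 | — | verdict floor `max(3, ⌈0.2·N/2⌉)` |
| `contrast_thresh` | 0.015 | intensity | DoG acceptance |
| `centroid` | `"geometric"` | — | centroid estimator |

The histogram window, Gaussian width, bin layout and assignment floor
follow the standard conventions of the detector family; the magnitude band
is applied on a normalised 0–100 scale because an absolute band is
meaningless across exposure levels. `min_votes` is a declared surrogate:
the method needs *some* asymmetry criterion to produce true negatives, and
a floor relative to the pairing capacity `N/2` scales across keypoint
densities. All of these are config-exposed (`symaxis_config()`), and a
JSON config file round-trips through `write_config()`/`read_config()`
(JSON rather than YAML: the offline toolchain has no YAML parser).

## Design choices that were genuinely open

**Centroid estimator.** The natural robust choice, a component-wise median,
is not rotation-equivariant: for an exactly mirrored constellation it can
sit several pixels off the axis whenever the axis is oblique (in
simulation: median offset 1.7 px, 95th percentile 6.3 px over random
oblique axes). An off-axis origin breaks the polar mirror rule — a
perpendicular offset `δ` inflates the angular residual by roughly
`2δ·cosθ/r`, which dwarfs a 1° tolerance. The **geometric (spatial)
median** is equivariant under rotations and reflections, lies exactly on
the axis for an exactly mirrored set, and keeps the robustness to outlying
clutter keypoints; it is the default. (Implementation note: the Weiszfeld
iteration uses the Vardi–Zhang step, because the textbook update stalls
permanently when an iterate lands on a data point — which happens in
practice, since the iteration starts at the component median.) The
component-wise median and the arithmetic mean remain available via
`centroid = "median"` / `"mean"` for sensitivity analysis.

**Centroid refinement.** Real detectors are imperfect mirrors of
themselves: a few percent of keypoints appear on one side only, and each
such straggler drags the geometric median off-axis by roughly
`r̄/N` pixels. Detection therefore refines the centroid using the
structure it is looking for: a sweep under loosened geometric bands
(annealed, by default 20° / 20% of the radial range, then 8° / 8%)
collects candidate mirror pairs, and the centroid is re-anchored at the
midpoints of those pairs — the midpoint of a true mirror pair lies on the
axis *no matter where the centroid was*. The anchor takes scalar medians
of the midpoints' along-axis and cross-axis components (the frame angle is
first re-estimated from the median of the pairs' own axis-angle
estimates), which is robust to the occasional mispaired midpoint, unlike a
component-wise median of near-collinear points. Finally the refinement is
kept only if it increases the winning vote count under the tight
tolerances ("propose and verify"), so a spurious coarse-pass constellation
can never make the result worse than no refinement. This stage is the
package's own addition; it operationalises the observation that the
method stands or falls with the centroid, and it reuses only objects the
pipeline already defines (pairs and their midpoints).

**Gradient attributes.** `M` and `Q` are read off the peak of the
orientation histogram after (a) sampling the window at subpixel positions
centred exactly on the keypoint and (b) two passes of circular box
smoothing. Both choices exist for the same reason: two keypoints that
mirror each other almost never share a pixel-grid alignment, and without
them the peak bin — and with it `M` — flips essentially at random for
narrow orientation ridges straddling a bin boundary, defeating the ±5
magnitude band. Smoothing conserves total histogram mass, so the
mass-conservation property of the histogram is untouched.

**Angle conventions.** Raster y points down; the polar conversion flips it
so θ is counter-clockwise-positive, in `(−180°, 180]` with the boundary
mapped to `+180`. All tolerance comparisons are inclusive, ties in the
vote table break toward the smallest α, and the greedy pair order is fully
deterministic, so two runs on the same input produce identical reports.
The `α = 0` reduction of the pair rule is stated circularly
(`|wrap(θ₁ + θ₂)| ≤ θθ`); a non-circular `|θ₁ + θ₂|` misclassifies
genuinely mirrored pairs right at the ±180° branch cut.

## What the synthetic data does and does not establish

`make_mirrored_image()` composes an elongated body Gaussian with paired
anisotropic blobs, all evaluated as analytic functions of the axis-frame
coordinates `(|u|, v)` — the continuous intensity field is exactly
mirror-symmetric for any axis angle, and for axis-aligned angles the
sampled image satisfies `I(p) = I(reflect(p))` pixel-exactly. Blobs are
anisotropic on purpose: an isotropic blob has a near-uniform orientation
histogram, i.e. a keypoint whose orientation is undefined, which no
gradient-consistency test can survive; real-world local structure is
oriented. `make_cluttered_image()` adds off-object blobs (default 5 per
10⁴ px², roughly a dozen on the default 160 px canvas) that generate
background keypoints and perturb the centroid; `make_point_constellation()`
produces mirrored or uniform-random keypoint tables directly, with
bounded-uniform jitter in `(r, θ)`.

A green test on these fixtures establishes that the geometry, pairing,
voting, refinement and evaluation machinery do what they claim under
controlled violations (jitter, clutter, rotation with resampling). It does
**not** establish performance on photographs: the generator has no
perspective, no occlusion, no illumination gradients, no textured objects,
and its clutter is spatially unstructured. The original study's headline
figures were measured on an undeposited collection of internet images and
are therefore not reproduction targets; the package's acceptance suite is
property-based instead.

## Numerical notes and limitations

* The DoG detector thresholds raw |DoG| at 0.015 (image scaled to [0, 1]),
  applies the standard edge-response test (curvature ratio 10) and clamps
  the subpixel offset to ±0.6 px; detection is deterministic, and keypoint
  tables are sorted by `(x, y, scale)`.
* `rotate_image()` uses Catmull–Rom bicubic interpolation; bilinear
  resampling blurs anisotropically and shifts blob extrema enough to cost
  several degrees of axis accuracy after rotation.
* Degenerate inputs: a constant image yields zero keypoints and an
  `undetermined` verdict (never an error); windows running over the image
  border are clamped and counted in the report log; a keypoint exactly at
  the centroid gets `θ = 0` and is excluded from pairing.
* One object, one straight axis only. Curved or multiple axes, glide
  symmetry and skew correction are out of scope.
* Verdicts depend on the invented `min_votes` floor; with very sparse
  constellations (N < 10) the floor of 3 votes dominates and specificity
  claims should be re-checked at the target keypoint density.
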