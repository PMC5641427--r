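---
title: "Elliptic Fourier morphometrics of sperm head contours: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elliptic Fourier morphometrics of sperm head contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science and the engineering decisions inside
`spermshape`: the descriptor model and its estimation, the normalization
conventions (including how every discrete ambiguity is resolved), the PCA
layer and the abnormality filter, the statistics, and the synthetic
generator that stands in for real micrographs — what it emulates, what it
deliberately does not, and therefore what a passing test suite does and
does not demonstrate about real data.

## 1. The descriptor model

A closed head outline is a polygon traversed counter-clockwise in a y-up
frame (image row `r`, column `c` maps to `x = c - 1`, `y = -(r - 1)`).
With `t` the cumulative arc length and `T` the perimeter, the outline is
expanded in elliptic Fourier descriptors

$$X(t) = \sum_{n=1}^{N} a_n \cos\tfrac{2n\pi t}{T} + b_n \sin\tfrac{2n\pi t}{T},
\qquad
Y(t) = \sum_{n=1}^{N} c_n \cos\tfrac{2n\pi t}{T} + d_n \sin\tfrac{2n\pi t}{T}.$$

Coefficients are estimated with the classical closed-form line integrals
over the polygon segments (exact for piecewise-linear contours, hence for
chain-coded boundaries); the centroid terms are the arc-length averages of
the coordinates. The estimator is verified in the test suite against an
independent dense quadrature of the same integrals to 1e-6.

**Choice of parameter.** `t` is arc length. A consequence worth stating
plainly, because intuition often goes the other way: *the first harmonic
of a geometric ellipse is not that ellipse.* Arc-length traversal spends
more time near the flat ends of an elongated ellipse, which mixes energy
into odd higher harmonics and biases the first-harmonic axis ratio upward
(a 2:1 ellipse measures ≈ 0.587, not 0.5; only the circle is exact). The
package treats the measured first-harmonic aspect ratio `d1` as *the*
quantity of interest — it is what the normalization produces and what the
downstream statistics consume — and the synthetic generator plants effects
directly on that scale (section 5), so no stage ever relies on the false
identity between `d1` and a geometric axis ratio.

**Y-equation convention.** The series above uses cosine-then-sine in both
coordinates. Under the alternative ordering sometimes printed
(`Y = c sin + d cos`), fixing `c1 = 0` would collapse the first harmonic
to a line and `d1` could not be an aspect ratio; the convention here is
the one under which the normalized first harmonic is `(cos t, d1 sin t)`
and `d1` is minor/major.

## 2. Normalization and its ambiguities

`efd_normalize()` removes, in order: the starting-point phase of the first
harmonic, the spatial orientation of its semi-major axis, and its
magnitude (recorded as `scale_px` for absolute measurements). The result
fixes `a1 = 1, b1 = 0, c1 = 0` and leaves `4N - 3` free parameters —
`d1`, then `a_n, b_n, c_n, d_n` for `n ≥ 2` — 77 at the default `N = 20`.

The phase equation determines the removal angles only up to a π/2 grid,
leaving two discrete ambiguities:

* **Axis swap** (candidates with the semi-minor axis along x): rejected by
  requiring `|d1| ≤ 1`.
* **180° rotation**: both remaining candidates put the major axis along
  +x; they differ by rotating the shape half a turn (every even harmonic
  changes sign). The package picks the candidate with
  `a2 + c2 > 0`, which places the head's tapered anterior end at +x with
  its dorsal bend opening downward. Exact ties (centrally symmetric
  shapes such as pure ellipses, where the two candidates coincide anyway)
  fall back to the smallest phase.

The orientation functional deserves a note, because the obvious
alternatives fail quietly. Any "which end is farther/pointier" rule
measured relative to the path centroid — maximum reach, x-skewness, the
area centroid — cancels at first order, because the centroid itself
shifts toward the asymmetry; empirically such rules flip on a large
fraction of jittered shapes and bimodalize every even harmonic across a
population. The even-harmonic asymmetry `a2 + c2` has no such
cancellation, is intrinsic (so normalized vectors are invariant to
rotation, scale, translation and start vertex of the input, verified to
1e-9 in the tests), and is anchored far from zero for falciform heads by
their dorsal curvature (`c2`) and apical taper.

Clockwise contours are corrected upstream (`ensure_ccw()`); if one slips
through, the normalization mirror-corrects with a warning rather than
emitting a negative `d1`. Degenerate inputs (zero perimeter, collinear
vertices, vanishing first harmonic) are errors, not NaNs.

## 3. PCA, loadings, reconstruction, abnormality

PCA is run on the covariance (not correlation) matrix of the shape
vectors, divisor `n - 1`: after normalization all coefficients share one
dimensionless scale, and rescaling them would inflate the noise
harmonics. Contribution rates are eigenvalue fractions. Scores are the
centered data projected on the eigenvectors; their covariance is diagonal
with the eigenvalues (a test invariant).

Eigenvector signs are conventions, but the abnormality threshold makes
them load-bearing, so they are fixed: **PC1 is oriented so its `d1` entry
is non-negative** — higher PC1 = rounder first harmonic — which places
hook-lacking, round-headed abnormal specimens at high positive PC1; every
other component is oriented so its largest-magnitude entry is positive.

`factor_loadings()` reports correlations between each coefficient and
each score (equivalently `e_jk √λ_k / s_j`), with biplot arrow length
`√(l₁² + l₂²)` and a 0.1 display cutoff. `reconstruct_along_pc()` builds
`mean + k √λ e` (`|k| ≤ 3`), restores the fixed first-harmonic terms and
evaluates the series — the mean ± 2 SD outline panels.

`filter_abnormal()` is deliberately two-pass: pass 1 fits the PCA to
*everything* (the threshold is only meaningful on scores computed with the
outliers included), excludes specimens with PC1 score above the threshold
(default 0.55), and refits on the remainder. Both models are returned.
The qualitative "lacks the hook" criterion is not a second computational
gate — the numeric threshold alone decides — but pass-1 scores are
returned so the verdicts can be audited against morphology.

## 4. Measurements and statistics

Per head: `d1`; absolute axes `major = 2·scale_px`,
`minor = 2·scale_px·d1` (pixel units; physical calibration is a
user-supplied factor, since magnification alone does not determine
µm/px); the antero-posterior axis as the maximum vertex-pair distance
(computed on the convex hull, tested against the exhaustive O(V²) scan);
θ as the acute angle between that chord and the first-harmonic major
axis, in [0°, 90°); the shoelace area (self-intersecting outlines are
rejected — their shoelace value is not an area); and the percent
coefficient of variation (SD/mean, divisor `n - 1`).

Group statistics wrap the standard R implementations (pooled-variance t
by default — the workflow pairs t-tests with F-tests for
homoscedasticity — with Welch as a flag; asymptotic two-sample KS;
Shapiro–Wilk), attach the significance convention (n.s. / * / ** / ***
at 0.05 / 0.01 / 0.001), and report percent differences as
`100·(ref − test)/ref` against an explicitly named reference group (no
silent alphabetical default: the sign of "thinner" depends on it).

The Steel–Dwass all-pairs test is implemented from scratch: for each pair,
joint mid-ranks with tie correction give a standardized rank-sum `z`, and
the familywise p-value is `P(Q_{k,∞} ≥ √2·|z|)` from the studentized-range
distribution. The asymptotic convention was chosen over exact enumeration;
the tests check it two ways — against a Monte-Carlo permutation null of
the familywise max-|z| statistic on small groups (agreement within 0.02),
and by simulating the global null (familywise type-I error ≤ 0.07 at
α = 0.05, k = 4, n = 20).

## 5. The synthetic generator

`sample_population()` emulates exactly the statistical structure the
analysis assumes, nothing more:

* **Shape family.** A base ellipse carrying a fixed apical taper
  (radial `1 + 0.08 cos t`) and dorsal bend (`y += 0.09 cos 2t`) — the
  tapered, falciform silhouette — plus an asymmetric apical hook bump
  (amplitude `hook_strength`, mean 0.15, specimen-jittered 15 %) whose
  constant and first-harmonic content is removed analytically, plus small
  additive jitter on synthesis harmonics 2–8 of both coordinates
  (`coef_noise_sd`, default 0.018). High-harmonic jitter
  folds thin outlines long before it adds useful variance, so harmonics
  5–8 get 0.6× amplitude, and any non-simple draw is redrawn (checked at
  a stricter tolerance than downstream, so a borderline verdict cannot
  flip after a rigid transform).
* **Calibration.** The aspect-ratio parameter is the *measured* `d1`: for
  each specimen the geometric axis ratio is solved by root-finding
  (tolerance 1e-12, monotone in the axis ratio up to 1) so that the
  emitted polygon's normalized first-harmonic aspect ratio equals the
  drawn target exactly, hook and jitter included. Ground truth is
  therefore exact on the `d1` scale, and planted percent differences are
  recovered without calibration bias.
* **Population structure.** Per-specimen `d1` targets are truncated
  normal (mean `mean_aspect`, SD `mean_aspect × cv_aspect`, truncated to
  (0.02, 0.98); a spec whose truncation would reject over half the draws
  errors out as infeasible). Defaults are at murine cauda-epididymal
  scale: mean 0.5, CV 5.3 %, semi-major ≈ 80 px, with random rotation,
  log-normal scale jitter (8 %) and translation. Identical spec + seed
  gives byte-identical output; the generator restores the caller's RNG
  state.
* **Abnormal admixture.** A requested fraction becomes hook-lacking
  outliers: near-round first harmonics (`d1 ≈ 0.85`) over a deep radial
  petal pattern (3 or 4 petals, relative depth ≈ 0.82, drawn once per
  population so the outliers form one coherent cluster) at 1.6× scale.
  The petal pattern collapses the first-harmonic magnitude that
  normalizes the coefficients, so these shapes sit ≈ 0.7 away from the
  normal population in coefficient space — safely past the 0.55 PC1 gate
  after the admixture shifts the pooled mean — while remaining
  star-shaped and simple. The size of this deviation is dictated by the
  fixed threshold: an outlier family a few within-population SDs from the
  mean (≈ 0.08 here) could never cross an absolute gate at 0.55.
* **Rasterization.** Scanline fill with the unambiguous lattice rule — a
  pixel is foreground iff its center lies inside or on the polygon — then
  optional Gaussian PSF blur and additive grey noise clipped to [0, 255].

What it does **not** emulate: acrosomes, midpieces, tails, debris,
touching cells, uneven illumination, or any quantitative hook geometry
(only qualitative hook presence/absence distinguishes normal from
abnormal). Passing tests therefore demonstrate that the pipeline recovers
planted aspect-ratio structure through contour extraction, normalization
and statistics — not that segmentation is robust to real microscopy
artifacts.

## 6. Problem sizes and numerical choices

The validation suite and the acceptance script run at the study's scale:
two groups of 150 (strain contrast, planted 5.7 %), 118 vs 133
(zona-penetration contrast, 5.4 %), 69/85/118 with CVs 8.4/6.0/5.3 %
(epididymal maturation), and 150 with a 10 % admixture for the filter —
averaged over 10 seeds for the percent-difference and filter checks and 4
for the CV recovery, sizes at which each check is comfortably inside its
tolerance without being wasteful. Contours default to 256 vertices
(512 in the analytic-recovery checks); estimator-vs-quadrature agreement
is asserted at 1e-6, normalization invariance at 1e-9, planted percent
differences at ±0.5 points.

Tie-breaks and edge cases, in one place: Otsu ties resolve to the lowest
maximizing grey level; boundary tracing uses Moore neighbors with Jacob's
stopping criterion and re-orients chains CCW by signed area; chain codes
must close (net displacement zero) or parsing fails naming the record;
zero-area chains are errors; self-crossing chains decode with a flag;
duplicate specimen ids are suffixed deterministically; rank ties in
Steel–Dwass use mid-ranks with the exact tie-corrected variance;
`significance_label(0.05)` is "n.s." (strict inequalities).

## 7. Known limitations

* Axis lengths are in pixels; physical units require a user calibration
  factor.
* The abnormality threshold (0.55) is an absolute score gate; it is only
  transferable to data whose coefficient variance structure resembles the
  populations it was defined on, and pass-1 scores should always be
  inspected.
* The Steel–Dwass p-values are asymptotic; at very small group sizes
  (n < 5) the permutation check in the test suite is the better guide.
* Holes, touching objects and multi-channel images are out of scope for
  the segmenter; one bright object per region is assumed, with debris
  removed by the `min_area` gate (default 200 px²).
* θ and the AP axis are vertex-based; their resolution is the vertex
  spacing of the traced boundary.
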