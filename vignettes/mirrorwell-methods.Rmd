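---
title: "mirrorwell: models and methods for dual orthogonal-view larva analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirrorwell: models and methods for dual orthogonal-view larva analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorwell)
```

## The measurement problem

A zebrafish larva swimming freely in a well moves in three dimensions, but a
single top-view camera records only the horizontal projection of that motion.
Speed, travel distance, acceleration and especially tail angle are all
systematically underestimated when the vertical component is discarded.
Mirrored multi-well plates address this optically: alternate wells of a
96-well-format plate are replaced with 45-degree mirrors, so one camera
simultaneously records a well's top view and, through the neighbouring
mirror, the side view of the same well. `mirrorwell` implements the
computational chain that turns the two 2D views into 3D measurements:

1. **geometry** — thin-lens pixel-to-millimetre conversion per view;
2. **optics** — a Snell's-law ray-tracing model of refraction through
   air/plastic/water, and slanted-edge MTF resolution estimation;
3. **fusion** — likelihood-based keypoint QC and triangulation of the two
   skeleton views into 3D skeletons;
4. **kinematics** — speed, acceleration, distance, tail angle, bouts,
   occupancy and depth profiles, with Mann-Whitney group comparison;
5. **bladder** — swim-bladder ellipsoid reconstruction from the two
   projected silhouette ellipses, with height-corrected volume;
6. **synthetic** — a virtual-larva simulator that generates ground-truth
   data for every other stage.

## Geometry and coordinate conventions

Each well is 8 x 8 mm in footprint and 12 mm deep, on a 9 mm pitch; each
micro-camera has a 25.05 mm lens at a 240 mm nominal object distance. The
per-well world frame puts the origin at the well-bottom center, x and y
horizontal and z vertical (upward). The top view images (x, y); the mirror
folds the horizontal side path into a vertical view sharing the y axis, so
the side view images (y, z). The mirror adds optical path length, so the two
views focus at different distances; magnification `m = f/(d - f)` is
calibrated per view (`view_calibration()`), with the side-view object
distance defaulting to the nominal distance plus one well footprint. The
sensor pixel pitch defaults to 1.1 um (the standard pitch of the 3120 x 4208
CMOS sensor used in this class of instrument) and is configurable, since the
pixel scale of every reported shift depends on it.

## Refraction model

Rays reaching a submerged larva cross refractive interfaces: the top view
passes air-to-water through the open well top; the side view (unfolded
through the mirror) crosses the plastic side wall and then water. For a ray
aimed at lateral field position `h` at object distance `d`, the incidence
angle is `atan(h/d)`; each slab of thickness `t` crossed at refracted angle
`theta_t` displaces the apparent position by `t (tan theta_1 - tan theta_t)`
relative to an all-air trace. Rays travelling through water are terminated
at the well wall, and the shift is reported up to the termination point.
Defaults the model needs but the plate drawing does not fix: the traced
water path is half the well depth for the top view (a mid-column larva) and
half the well footprint for the side view; the plastic wall is 1 mm; the
aperture diameter (used only for marginal rays) defaults to 25 mm, chosen so
the worst-case marginal incidence stays near 5 degrees — marginal-ray
results are therefore configuration-dependent and reported as such.

With water at n = 1.33 and plastic at n = 1.5, scanning chief rays in 0.1 mm
steps out to the farthest field point (8.5 mm: half pitch plus half
footprint) gives a maximum incidence near 2 degrees, a maximum pixel shift
around 5.5 px, and a maximum relative distortion (shift over field position)
of about 0.62% — comfortably below 1%, which is why keypoints can be fused
without a per-pixel distortion correction. `distortion_profile()` tabulates
the scan; `scripts/acceptance.R` recomputes the headline figure.

## Slanted-edge MTF and resolution

`mtf_from_edge()` follows standard spatial-frequency-response practice:
locate the edge per scanline from the gradient centroid, fit a straight
edge, project pixels onto the edge normal into a 4x-oversampled edge-spread
function, differentiate to the line-spread function, apply a Hann window,
and take the DC-normalized FFT magnitude on a 0-50 cycles/mm grid.
`resolution_from_mtf()` splits the curve into an exponential-decay region
and a noise region: the noise floor is the mean modulation over the top 20%
of the frequency axis, the decay region is the contiguous low-frequency
prefix above twice the floor (at least 5 points), the decay is fitted
log-linearly as `A exp(-k f)`, and the cutoff `f_c = ln(A/floor)/k` gives
the lateral resolution `1/f_c`. On an exactly exponential curve the cutoff
matches the closed form to 1e-6 relative. Limitation: a nearly unblurred
edge (Gaussian sigma below about 1 px) has no identifiable decay region
within 0-50 cycles/mm — the aliasing-dominated floor sits too high — and the
function reports an error rather than a fabricated resolution; real optics
at this scale always decay well within that band.

## Keypoint QC and fusion

Eight landmarks are tracked per view: one midline nostril point, both eyes,
the swim bladder, and four tail points. A frame-view passes QC only when all
eight keypoints have detector likelihood strictly above 0.7; a video is
flagged for exclusion when more than one-third of its frames fail. Fusion
takes x from the top view, z from the side view, and y — seen by both — as
the unweighted mean of the two readings, recording the absolute gap as a
consistency residual (warning above 0.5 mm). Averaging y is the one place
the redundancy of the two views reduces noise (by sqrt(2) in that axis).

A consequence worth stating precisely: with independent Gaussian pixel noise
of s.d. sigma in each view, the Euclidean 3D keypoint error `e` satisfies
`e^2 = (sigma * p)^2 (g1^2 + g2^2/2 + g3^2)` with `p` the object pixel size
and `g_i` standard normal, so `P(e > 3 sigma p)` is about 1.4% — a
three-sigma radius captures roughly 98.6% of fused keypoints, not the 99.7%
a one-dimensional intuition would suggest. The acceptance tests measure
exactly this.

Accuracy against ground truth is summarized by Euclidean pixel RMSE and by
distance-threshold detection rates at 3, 5 and 10 px. These rates are
deliberately not called mAP/mAR: no average-precision matching rule is
defined here, and renaming avoids a false equivalence.

## Kinematics

The kinematic reference point is the midpoint of the eye pair — the head is
the only rigid part of the larva. Speed is the inter-frame Euclidean
displacement of that point times the frame rate; acceleration is the signed
forward difference of the speed series times the frame rate (a scalar rate
of change of speed, not the vector second derivative — summaries report its
magnitude); total distance is the sum of displacements over valid
consecutive pairs. Frames failing QC are excluded, never interpolated, so
summaries cover valid segments only. The tail angle is the angle between the
nostril-to-reference vector and the nostril-to-tail-tip vector (the tip,
`tail4`, rather than a fitted tail line; the fitted-line alternative would
smooth digitization noise at the cost of sensitivity to tip curvature). 2D
variants project onto a view plane first, which collapses out-of-plane
bending — the mechanism by which top-view-only analysis underestimates every
motion metric. A "move" (bout) is a maximal run of frames with speed above
2 mm/s lasting at least 2 frames; both settings are analysis choices exposed
as parameters, since bout-calling conventions vary across laboratories.
Depth profiles report per-time mean and sample (n-1) standard deviation
across larvae. Group comparison uses the Mann-Whitney U test: exact when
both groups have at most 10 observations without ties, normal approximation
with continuity and tie correction otherwise.

## Swim-bladder ellipsoid reconstruction

Each view's segmentation mask yields a silhouette ellipse
(`mask_to_contour()` then `fit_ellipse()`, a numerically stable direct
least-squares conic fit constrained to ellipses). In matrix form an ellipse
is `u' M2 u = 1` and an ellipsoid `v' M3 v = 1` with
`M3 = R' B R`, `B = diag(1/a^2, 1/b^2, 1/c^2)` and `R` composed of three
elementary rotations (x-tilt, then the z-type and y-type blocks). The
orthogonal silhouette of an ellipsoid on a coordinate plane is the Schur
complement of the out-of-plane entry: partition M3 into in-plane block S,
cross vector w and scalar q; the shadow matrix is `S - w w'/q` (verified in
the tests against a 1e5-point surface-projection oracle). Frames where the
larva faces a camera are discarded first by the visibility criterion: the
ratio of the shorter projected skeleton length to the true 3D length must
reach 0.5.

### Identifiability: what two silhouettes can and cannot determine

The reconstruction minimizes the elementwise absolute difference between
the model's two shadow matrices and the two fitted ellipse matrices. This
problem is fundamentally under-determined: the shadow matrices T (top) and
S (side) of *any* ellipsoid obey

```
det(T) * S[2,2] = det(S) * T[1,1]
```

(both sides equal `det(M3) (m11 m33 - m13^2) / (m11 m33)`), so the six
measured numbers carry only five degrees of freedom, and a one-parameter
family of ellipsoids — conveniently parameterized by the xz entry `m13` —
shares both silhouettes exactly. Volume varies along the family, by tens of
percent for strongly anisotropic shapes. No estimator can recover the
volume of a freely rotated ellipsoid from two orthogonal silhouettes alone.

`fit_ellipsoid()` therefore proceeds in two stages. First it sweeps the
family algebraically: given `m13`, the remaining entries follow in closed
form from five of the six shadow equations, and the sixth (the shared-y
entry) measures consistency. Along the sweep it selects the member that
combines a small residual with a minimal-rotation preference (a
scale-invariant off-diagonal score), reflecting the near-horizontal posture
of a swimming larva; the assumed measurement noise (default 2%) sets the
exchange rate between the two terms. Second, a derivative-free simplex
polish of the full L1 objective runs from that member, from the
axis-aligned closed-form start, and from any user initialization, keeping
the best. The final residual is attached to the result so near-degenerate
fits remain visible.

What this buys, concretely: axis-aligned ellipsoids, spheres, and
single-in-plane-rotation cases are recovered essentially exactly; for
freely rotated truths with rotations within 15 degrees the median volume
error is about 2% with occasional large errors for strongly anisotropic,
y-rotated shapes (the direction the data genuinely do not see); under 2%
perturbation of the ellipse matrices the median volume error stays near
3%. Downstream volume series should be read with this in mind: per-frame
volumes are most trustworthy when the larva swims roughly level.

Because the top view assumes the nominal object distance, a larva at height
z is closer to the camera and its top-view-derived axes are biased; the
volume correction rescales those two axes by the magnification ratio
`m(d)/m(d-z)` before computing `V = 4/3 pi a b c`. Mask quality is
quantified with the Dice coefficient, defined as 1 for two empty masks.

## The synthetic larva

The simulator is the oracle for every stage: it generates what the
instrument would measure, with known truth. Its defaults are the recording
conditions the package targets: a 4 mm (7 dpf) larva in one 8 x 8 x 12 mm
well, 20 fps, 30 s. The head follows an Ornstein-Uhlenbeck velocity random
walk (cruise scale 3 mm/s, 0.5 s relaxation) with specular reflection at
the walls and an optional depth bias (surface/bottom priors for
axial-behavior phenotypes); the rigid head carries nostril, eyes and
bladder at fixed body-frame offsets, and four tail points ride a
circular-arc bend modulated sinusoidally at 2 Hz with 25-degree amplitude,
in a configurable mix of horizontal and vertical bend planes (so 2D-vs-3D
underestimation experiments are constructible). The swim bladder (semi-axes
0.45 x 0.30 x 0.28 mm, a typical inflated larval bladder) rides at the
bladder keypoint, aligned with the body axis. Rendering projects to both
views through the calibrations, adds Gaussian pixel noise, demotes random
keypoints to a low likelihood (the detector-failure model; the default rate
of 0.4% per keypoint per view reproduces the ~94% all-keypoint frame
success rate typical of trained detectors on this instrument), and rasterizes
exact Schur-complement bladder shadows as masks. All randomness flows
through the single config seed; identical configs give identical output.

What the simulator does not emulate: photorealistic appearance, defocus
blur and the shallow depth of field of the real instrument, occlusion of
the bladder by the eyes (it is emulated only through the visibility
criterion's geometry), segmentation errors with spatial structure, and
multi-larva interaction. Passing tests therefore demonstrate correctness of
the geometry, QC logic, estimators and statistics — not robustness to the
image-domain failure modes of real detectors.

## Numerical choices and test scale

Ellipse fitting centers and scales points before solving the constrained
eigenproblem; degenerate (collinear) input raises an error. The ellipsoid
family sweep uses 201 grid points with local refinement, and the simplex
polish caps at 1000 iterations per start. Mask contours are the 0.5 level
set of the largest 4-connected component (half-pixel accuracy). The MTF
pipeline oversamples the edge-spread function 4x and reports frequencies to
50 cycles/mm. The test suite simulates at 10-50 s of video per case and
uses 100-case ellipsoid batches and 1000-trajectory kinematic sweeps,
sizes chosen to exercise every code path while keeping the whole suite
under a minute on one CPU.
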