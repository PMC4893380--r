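---
title: "Quasi-dense stereo, deformation recovery and vision-based force estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-dense stereo, deformation recovery and vision-based force estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuedeform)
```

## The problem

During microsurgery a blunt instrument pressing on soft tissue exerts forces
that are often below what the surgeon can feel — in microneurosurgery,
dissection forces frequently stay under 0.3 N.  A calibrated stereo
microscope already watches the scene, so the tissue's visible deformation is
an indirect force sensor: if we can (i) reconstruct the tissue surface in 3D,
(ii) measure how much each surface point has moved since the tool arrived,
and (iii) convert the displacement at the (occluded) tool tip into newtons
through a material model, we obtain force feedback with no added hardware.
`tissuedeform` implements that pipeline end to end, together with a synthetic
scene generator that renders fully ground-truthed stereo sequences so every
stage can be validated without any external data.

## Stereo reconstruction

Images are first rectified (Fusiello-style rectifying rotation, shared
rectified intrinsics) so corresponding points share a row and matching is a
1-D search.  All 3D quantities live in the left camera frame, in millimeters;
pixel coordinates are 0-based `(col, row)` floats.

**Salient regions.**  Each image is described by affine-covariant elliptical
regions from a scale-normalized determinant-of-Hessian detector with
second-moment (structure tensor) affine adaptation.  A feature carries a
sub-pixel center, a positive saliency strength `c` (the detector response), a
2x2 SPD shape matrix, and a patch resampled from the ellipse to a fixed 21x21
grid.  This detector is an interface-compatible stand-in for the real-time
anisotropic detector the method was originally built on; everything
downstream consumes only the (location, saliency, ellipse, patch) interface.

**Constrained matching.**  A left feature `i` and right feature `j` are
scored by

> `M = |R_i ∩ R_j| / |R_i ∪ R_j| + min(c_i, c_j) / max(c_i, c_j)`,

the relative overlap of the two elliptical regions plus the agreement of
their saliencies, so `M` is in `[0, 2]`.  The candidate set for `i` is the
features on the epipolar line — implemented as a band of ±1.5 px, since
sub-pixel detections never sit exactly on the line.  A match must satisfy
overlap > 60 % and appearance similarity > 90 % (histogram-equalized NCC of
the patches, equalization absorbing illumination differences between the two
cameras); among admissible candidates the highest `M` wins.  Two details the
scoring leaves open are resolved as follows: the overlap is computed after
translating the right ellipse onto the left center, because any nonzero
disparity would otherwise destroy the overlap ratio; and ties are broken
deterministically (higher appearance, then smaller disparity), with
left-right uniqueness enforced by keeping the highest-`M` claim on each right
feature.  The ellipse IoU itself is computed by slicing both ellipses along
x on Chebyshev-distributed nodes and integrating the y-interval overlap —
accurate to ~1e-6 against closed-form circle-lens areas.

**Densification and propagation.**  Matching is repeated at a finer detector
threshold inside the areas covered by the matched ellipses (`stage =
"local"`).  Remaining unmatched features are transferred by affine
propagation: a seed match defines the local affine map `M_R^{-1} R M_L`
between camera planes, where `M_L`, `M_R` normalize the seed ellipses to unit
circles and `R` is the relative orientation of the normalized patches.  A
candidate is transferred only if it lies within a seed's (inflated) ellipse
and the shape-from-shading surface normals at candidate and seed differ by
less than 1 degree; the transferred match is kept only if the appearance
similarity at the predicted right-image location is at least 0.80.  Because a
single detection's ellipse is noisy, the linear part is averaged over the
nearest few seed maps and the anchor is the nearest admissible seed; the
rotation `R` is shrunk by the patches' orientation coherence (nearly
isotropic patches carry no reliable orientation, and the true relative
orientation for a small-baseline rig is near zero).  Propagated positions are
finally refined by gradient-based (Lucas-Kanade) alignment, which restores
deep-sub-pixel accuracy before triangulation.

**Surface normals.**  With the light effectively co-located with a
microscope's optics, a Lambertian surface obeys `I ∝ cos θ / r²`.  After
dividing out the known radial/viewing falloff `(cos³ α)` per pixel (this must
happen *before* smoothing — blurring the curved falloff field first creates
exactly the kind of small bias that the inversion amplifies), the slope
magnitude follows from `sqrt((I0/I)² − 1)` on generously smoothed
intensities, and the slope direction opposes the intensity gradient.  Normals
are `N = (p, q, −1)/sqrt(p² + q² + 1)`, always unit length with negative z.
On textured surfaces these normals are only smooth estimates — adequate for
the 1-degree propagation gate, which compares nearby points of the same
field, not for absolute shape recovery.

**Triangulation** uses the rectified closed form `Z = f·b/d` and maps points
back to the (unrectified) left camera frame.  On the default noiseless
synthetic fixture the quasi-dense cloud has a mean absolute surface error of
about 0.05–0.2 mm at 100 mm stand-off — the disparity accuracy of the
detector itself (~0.02 px mean) is what makes this possible.

## Deformation recovery

Deformation is measured against the reconstruction of a reference frame
(frame 1 by default; configurable).  The distinctive global-stage features
are tracked on the left image plane with pyramidal Lucas-Kanade patch
tracking against their frame-1 templates, followed by an affine-extended LK
refinement at the finest level — under the local scale change of an
indentation, a translation-only tracker lags systematically along the radial
direction.  The confidence of a track is the
NCC of the current patch against its template, and a track whose confidence
drops below 0.7 (or that jumps beyond a per-frame displacement bound) is
declared lost.  A tracked feature is re-associated across cameras per frame
by epipolar-constrained LK alignment initialized at its reference disparity,
and triangulated; its deformation is `D = ||S_t − S_ref||`.  One subtlety
matters in practice: the reference positions of the stable features are
measured with the *same* LK estimator, so each feature's systematic
sub-pixel bias cancels in the difference — otherwise a perfectly static
scene shows ~0.1 mm of phantom deformation.

Points with 3D data but no reliable track — the local/propagated matches and
lost tracks — are mapped by a 3D thin-plate spline fitted on the stable
features (kernel `U(r) = r`, the 3D biharmonic Green's function; `lambda = 0`
interpolates the controls exactly and is the default, with regularization
exposed for noisy tracking).  Each unstable reference point is warped,
projected into the left image, and if the current frame's quasi-dense
reconstruction has a point within 2 px of the projection, the surface depth
*at the projection itself* is evaluated from a local plane over the
neighboring cloud points and its deformation reported (high confidence) —
adopting the single nearest point instead would bias the depth outward
wherever the cloud is one-sided, as it always is at the tool-occlusion
boundary; otherwise the warped position
itself is used and flagged low-confidence.  A second TPS pass then treats the
successfully confirmed points as additional controls, which anchors the warp
near the indentation before it extrapolates under the tool — without this
pass, points hidden by the instrument inherit a strongly underestimated
deformation.

## Force estimation

A quadratic force-displacement model `F = a2 d² + a1 d + a0` is calibrated by
least squares from (displacement mm, force N) pairs; degree 2 is the
standard empirical choice for blunt indentation of brain-like soft material.
The intercept is fitted freely by default (flag to force `a0 = 0`); the model
records its valid range `[0, d_max]` and residual RMS, and readouts beyond
`d_max` are flagged (beyond `1.2 d_max` they are an error).  The package
ships `demo_material_model()` (0.01, 0.02, 0) for demos and closed-loop
simulation only — it is explicitly non-physical and any real use requires
calibrating the actual material.

The tool occludes the contact point, so its displacement is inferred: the
deformation magnitudes around the tool are modeled as an isotropic Gaussian
over lateral surface coordinates (tangent-plane parameterization of the
displacement field), `D(u) = A exp(−||u − c||²/(2σ²)) + b`, fitted by
Levenberg-Marquardt with the occluded disk excluded.  A baseline term is
included (default 0 when the data carry none) because the reference field
may carry a small global offset.  Only high-confidence points enter the fit
by default: the low-confidence extrapolated points sit exactly where the
peak is inferred and would bias it.  Samples are labeled at the lateral
position where the surface was actually measured (the current position):
TPS-mapped points near the occlusion carry a small outward lateral bias, and
labeling their displacement at the reference position would systematically
flatten the fitted peak.  The tool-tip displacement is the peak
`A + b`, and the force is the calibrated polynomial evaluated there.

## The synthetic scene generator

`make_scene()` builds the study conditions the pipeline is validated under: a
textured heightfield at a 100 mm stand-off (80–150 mm admissible), a
fronto-parallel stereo rig with 5 mm baseline (4–8 mm) and 1000 px focal
length (800–1500 px), band-limited procedural texture (smoothed uniform
noise at 0.1 mm resolution, two spatial scales, detector-friendly blobs of
roughly 3–6 px), gentle 2 mm low-frequency relief, and a scheduled Gaussian
indentation (σ = 6 mm, amplitude ramping from 0 to 10 mm over the frames —
the regime of interest, deformations up to 10 mm and forces ≲ 1.2 N with the
demo model).  Rendering is per-pixel inverse mapping: each camera ray is
intersected with the heightfield by fixed-point iteration (the relief is
shallow against the stand-off, so a handful of iterations converge to
~1e-9), shaded Lambertian under a camera-co-located light.  An opaque dark
tool (shaft plus tip disk) follows the indentation center so occlusion
handling in tracking and peak inference is exercised.  Ground truth — per
pixel depth, per-pixel 3D displacement, stereo correspondences, and the
force label through the scene's own material model — is exact by
construction, and the principal point is placed on an integer pixel so the
scheduled amplitude is attained exactly at a pixel ray.

What the generator does *not* emulate: specular wet-tissue reflections,
smoke/blood artifacts, photometric noise, rolling shutter, imperfect
calibration, and physically coupled lateral tissue motion (material points
move only along z).  Passing the synthetic checks therefore demonstrates the
geometric and numerical correctness of the pipeline under its stated
assumptions, not robustness to every nuisance of real intraoperative video.

## Numerical choices and degenerate inputs

* Pixel coordinates 0-based `(col, row)`; 3D in mm in the left camera frame
  (x right, y down, z forward).  The calibration file round-trips bit-exactly
  (17 significant digits).
* Zero baseline, non-SPD ellipse shapes, non-positive disparity, points
  behind the camera, fewer than 4 non-coplanar TPS controls, fewer than 3
  distinct calibration displacements, and fewer than 5 unoccluded Gaussian
  samples are all classed errors, not warnings.
* A constant image yields an empty feature list; a zero-variance patch has
  appearance similarity 0 (unmatchable); an all-zero displacement field fits
  a zero-amplitude indentation.
* TPS systems are solved with one step of iterative refinement; kernel
  distances use the coordinate-difference form (the expanded sum-of-squares
  identity loses ~1e-7 at 100 mm coordinates).
* The Gaussian fit uses `minpack.lm::nls.lm` on a residual function with a
  lower bound σ > 0; moment-based starting values (weighted centroid and
  spread) make the 100-trial recovery checks converge without restarts.
* Problem sizes in the test-suite: the full-geometry fixture is one
  640x480 pair; the deformation sequence is four 320x240 frames.  These
  sizes were chosen as the smallest at which the detector still produces a
  quasi-dense (> 500 point) cloud and the indentation spans many feature
  spacings.

## Known limitations

* The detector stand-in's one-shot affine adaptation leaves a systematic
  ~0.5 px bias in raw affine-propagated predictions under a known warp;
  the pipeline's LK refinement step removes it before triangulation, but
  consumers of `propagate_matches()` output alone should expect sub-pixel,
  not deep-sub-pixel, accuracy.
* Shape-from-shading normals assume a single co-located light and Lambertian
  reflectance; they are gate-quality, not reconstruction-quality.
* The tracker uses fixed frame-1 templates: under large appearance change
  (strong scale change or rotation) tracks die rather than drift, which is
  the conservative failure mode for a deformation sensor; the TPS mapping
  then carries those points.
* Only the indentation-axis force is estimated; lateral components and
  viscoelastic (time-dependent) behavior are out of scope.
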