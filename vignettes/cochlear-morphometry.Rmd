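---
title: "Template-based cochlear morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based cochlear morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oticfit)
```

## The problem

Cochlear implant planning benefits from patient-specific knowledge of
cochlear size and shape, but clinical CT resolves the cochlea at only a few
dozen voxels.  `oticfit` implements a practicable route around this: fit a
high-resolution template surface of the otic capsule (cochlea, vestibule
region and semicircular-canal structures) to the clinical volume, then make
the clinically relevant measurements on the fitted surface rather than on
the raw image.  Because real micro-CT reference scans of temporal bones are
generally not shareable, the package also provides a synthetic phantom
generator with analytic ground truth, and a pseudo-clinical CT simulator, so
that the whole pipeline can be validated end to end by parameter recovery.

## The fitting pipeline

1. **Landmark initialization.**  Three point landmarks — the cochlear apex,
   the centre of the oval window, and the posterior–anterior canal
   bifurcation — are matched with predefined template landmarks by the
   closed-form least-squares similarity transform (rotation, isotropic
   scale, translation).  A left/right mismatch is handled by an optional
   mirror.  Note that chirality cannot be inferred from three landmarks
   alone: a labelled triad and its mirror image are always related by a
   proper rotation (two reflections compose to a rotation), so the
   reflection decision is an explicit input (`reflect = "force"`), exactly
   as it is an operator decision in practice.
2. **Threshold segmentation.**  The operator picks a grayscale threshold
   (160/170/180 on the synthetic 0–255 scale); marching squares with linear
   interpolation extracts iso-contours on every axial slice, giving a
   boundary point cloud in millimetres.  The cloud deliberately keeps all
   clutter — other bone boundaries, canal structures, noise-broken
   contours — because robustness to that clutter is the registration's job.
3. **Similarity ICP.**  Classic iterative closest point with a closed-form
   similarity update.  Pairing runs template vertex to nearest cloud point;
   pairs beyond `trim_factor` (default 3) times the median pair distance
   are dropped from the update.  Fifty iterations are the default budget,
   with an early stop when the mean pair distance changes by less than
   1e-6 mm.
4. **Nonrigid refinement**, by either of two regularized methods:
   - **Locally affine deformation (LAD).**  Each vertex carries a
     neighbourhood of all vertices within a distance `d` (default 5 mm, a
     deliberately stiff setting suited to noisy low-resolution data).  Per
     iteration, a least-squares *rigid* transform is fitted over each
     neighbourhood's vertex/cloud pairs, and every vertex moves to the
     proximity-weighted average of its images under its neighbours'
     transforms.  `d` is the only shape parameter: small `d` permits local
     deformation, large `d` approaches — and at `d` beyond the mesh
     diameter exactly reaches — a single global rigid fit.  Because the
     blended update is not a strict descent step, the iteration tracks the
     pairing objective, stops after eight non-improving iterations, and
     returns the best-scoring configuration seen; this is also why a
     doubled iteration budget leaves the measurements essentially
     unchanged.  On these phantoms the d = 5 mm setting is kept for clean
     high-resolution volumes as well: smaller neighbourhoods fit the cloud
     more tightly but let the template's material correspondence slide
     along the smooth tube, which costs more measurement accuracy than the
     tighter surface fit gains.
   - **Statistical shape model (SSM).**  Corresponded training surfaces are
     standardized by Procrustes analysis (centred, scaled to unit centroid
     size, rotated onto the template; reflection never introduced) and
     decomposed by PCA through the thin SVD of the centred data matrix.
     A shape is the mean plus a linear combination of the n−1 modes.
     Fitting alternates pairing, similarity re-estimation, and a linear
     least-squares solve for the mode coefficients, using all modes with no
     coefficient bounds.

## Design choices in the open spots

Several details are not fully pinned down by the published description of
this family of algorithms; the package resolves them as follows.

- **LAD proximity weights.**  A truncated Gaussian
  `w = exp(-r^2 / (d/2)^2)` over the neighbourhood, renormalized.  Smooth,
  and its support matches the neighbourhood definition.
- **Transform blending.**  The *positions* of a vertex under its
  neighbours' rigid transforms are averaged (position blending), avoiding
  rotation-averaging ambiguities.
- **Neighbourhoods** are Euclidean balls in the current (deformed)
  configuration, recomputed every iteration.
- **Pose-first coefficient solve in the SSM fit.**  The pose (similarity)
  and shape coefficients are redundant where the modes can mimic small
  rotations and rescalings.  Solving the coefficients before settling the
  pose lets the coefficients absorb pose error and drifts to equilibria
  with inflated coefficients; the package therefore runs a few
  similarity-only ICP iterations first and re-estimates the pose before
  each coefficient solve.  With this ordering, fitting a cloud sampled from
  the mean shape returns coefficients at numerical zero.
- **ICP/LAD trimming** uses 3x the current median pair distance.  The
  thresholded clouds contain a second, outer bone/air shell a full wall
  thickness away, plus canal structures; median-relative trimming excludes
  them from the updates without any absolute distance tuning.
- **Turning angle** along the outer-wall contour is the running sum of
  angles between consecutive 3-D tangent segments, starting at the round
  window.  This is well defined past 180 degrees and needs no modiolar
  axis estimate; it reads slightly differently from round-window/modiolar
  polar angle (the basal window in this convention ends somewhat earlier
  along the duct).

## Measurements

All measurements are made on the outer (lateral) wall contour: traced once
on the template as the path through points whose surface normal is
perpendicular to the coiling axis (on the laterally outward side), then
resampled to 101 points at equal arc-length intervals and carried through
every deformation as barycentric anchors on the template topology.

- **Duct length**: total polyline length of the 101 points, round window to
  apex.
- **Reach**: the maximum distance from the round window to any point within
  the first 270 degrees of turning; comparable to the clinical A-value.
- **Basal plane**: total-least-squares plane through the 270-degree window
  (smallest principal direction of the centred points), oriented so the
  apex has positive height.
- **Non-planarity**: mean absolute distance of the window points from the
  basal plane.  This is the package's insertion-trauma-relevant shape
  metric; note it is a blunt summary — a series of small ripples can score
  like one significant hurdle.
- **Vertical trajectory**: per-point (turning angle, signed height) pairs,
  the replacement for modiolar-axis height profiles, which are sensitive to
  how the modiolar axis is estimated.

## The phantom generator

The phantom stands in for a cohort of cadaveric micro-CT specimens.  Each
specimen is a tube swept along a logarithmic spiral
`R(theta) = spiral_scale * exp(-decay_rate * theta)` (the outer wall), with

- about 2.5 turns (`total_turn` ~ U(2.35, 2.6) turns),
- `spiral_scale` ~ U(5.0, 5.8) mm, chosen so outer-wall duct length spans
  roughly 37-44 mm across a cohort (matching the published normal range)
  with at least a 4 mm spread at n = 18,
- a geometrically tapering duct radius (base U(0.72, 0.84) mm, apex
  U(0.42, 0.50) mm),
- a cubic vertical trend (height U(2.0, 2.8) mm, base slope
  U(-0.25, 0.15) mm/rad; negative base slopes give the down-then-up
  "rollercoaster" profiles), plus a basal vertical undulation
  `a * sin(f*theta) * exp(-theta/3)` with amplitude U(0.2, 1.4) mm.  The
  undulation is what generates genuine basal non-planarity: a smooth cubic
  is almost entirely absorbed by the best-fit basal plane, and with the
  cubic alone the whole cohort came out nearly planar (non-planarity below
  0.05 mm), unlike published vertical trajectories whose basal-window
  height deviations reach several tenths of a millimetre.  The resulting
  cohort non-planarity spans roughly 0.05-0.25 mm,
- a flaring continuation of the duct 0.6 rad beyond the round window,
  standing in for the widening toward the vestibule.  Without it the basal
  end of the tube is a featureless cap and template correspondence can
  slide a millimetre along the duct, which real capsule anatomy does not
  permit; the flare anchors the round-window end of the carried contour,
- a mildly elliptic basal turn (radius modulation `1 + a cos(2 theta +
  phase)`, amplitude up to 0.05) giving reach a component independent of
  overall size, as in real cochleae where the A-value is
  direction-specific.  Amplitudes much above this expose a genuine
  limitation of carried-contour measurement on a bare tube: the
  locally-rigid fit can "roll" the template circumferentially, improving
  the surface fit while sliding the contour off the lateral ridge,
- an oval duct cross-section (vertical semi-axis 0.85 of the radial one),
  matching the non-circular cochlear duct and breaking the rotational
  symmetry that would otherwise let registration roll the tube about its
  centreline,
- per-specimen idiosyncratic surface detail: random radial and vertical
  harmonics at angular frequencies 3–8 (24 independent coefficients,
  standard deviations 0.09/k mm radial and 0.12/k mm vertical,
  apex-decayed).  Real specimens carry individual wall detail that no
  small parametric family reproduces; without it, 17 training specimens
  span a held-out one and the leave-one-out shape model fits as well as
  the full one, hiding the generalization failure the validation is meant
  to exhibit,
- a torus-arc canal appendage whose far end is the canal-bifurcation
  landmark.  The canal co-scales with the cochlea so that one similarity
  transform is size-consistent for the whole structure; with a fixed-size
  canal the similarity scale was pinned near 1 while cochlear size varied,
  and small or large specimens misfit grossly,
- left or right chirality (mirrored x), and a random rigid pose (rotation
  up to 20 degrees, translation up to 3 mm per axis).

Every specimen shares one vertex topology (same angular sampling), so
cohorts are natively in vertex correspondence for SSM training — the
counterpart of sliding-semilandmark registration, which is out of scope.

Ground truth is computed from the analytic outer-wall curve
`(R(theta) cos(theta), R(theta) sin(theta), z(theta))` sampled at 12001
points, using the same measurement definitions as the morphometry code.
Because cross-sections are swept in the radial-vertical plane, the point of
the tube farthest from the coiling axis at each angle is exactly on this
curve, and its surface normal is exactly perpendicular to the axis — so the
analytic curve is the true outer-wall contour, not an approximation.

What the phantoms do *not* emulate: scalae separation, the modiolus,
round/oval window membranes, Hounsfield calibration, beam hardening, and
real anatomical covariation of canal and cochlear shape.  Passing the
recovery experiments therefore shows the pipeline is sound under realistic
resolution, noise, clutter and shape variation — not that clinical accuracy
on real scans is guaranteed.

## Pseudo-clinical CT synthesis

A micro-CT-like volume is rendered from the specimen mesh as three
intensity zones on a 0-255 scale — duct lumen 90, a 1.5 mm bone shell 230,
air 20 — with one-voxel partial-volume ramps from the signed distance to
the surface (so the capsule boundary crosses grayscale 160 at the surface
itself, and the 160/170/180 thresholds bracket it within a fraction of a
voxel).  Degradation then proceeds per axial slice: anti-aliased
downsampling to the clinical pitch, a parallel-beam Radon transform,
i.i.d. Gaussian detector noise scaled to the sinogram dynamic range, and
ramp-filtered backprojection.  Three presets emulate next-generation CBCT
(0.15 mm, sigma 0.4%), standard MDCT (0.3 mm, 1.0%) and poor MDCT
(0.45 mm, 1.8%); the noise levels are meaningful only relative to each
other and were fixed once so that the reconstructed appearance spans
"clearly better than" to "clearly worse than" a typical temporal-bone MDCT
(image-domain noise roughly 6/11/16 grayscale units against a bone-lumen
contrast of 140).

Numerical choices: the projector integrates with detector pitch and step
equal to the pixel pitch divided by an oversampling factor (3 by default, 2
inside the volume pipeline), which keeps the noiseless
project-then-reconstruct round trip below 2% RMSE of the dynamic range in
the slice interior; the ramp filter is the discrete-space Ram-Lak kernel
(frequency-sampled ramps produce low-frequency cupping); the angle count
defaults to 1.5x the projection Nyquist criterion for the slice width.

## Validation experiments and problem sizes

`run_experiment()` reproduces the study design at phantom scale: an 18
specimen cohort, micro-CT surrogate volumes at 0.15 mm, degradation
presets, thresholds 160/170/180, fitting by LAD (d = 5 mm, 50 iterations)
and/or full and leave-one-out SSMs, measurement, and a summary of mean
absolute error as a percentage of the cohort's gold-standard range — the
same normalization as the published tables, including the unfitted-template
baseline (template measured after similarity alignment only).  Landmark
placement is jittered by 0.25 mm (one-sigma, per axis) to emulate manual
clicks.

These sizes (0.15 mm source pitch, 2346-vertex meshes, 101-point contours)
were chosen so a full cohort experiment runs in minutes while every
geometric feature — duct taper, ripple, clutter shells, canal — is resolved
by several voxels and mesh chord error stays near 0.01 mm.

## Known limitations

- Duct length is the hardest metric at the ends: one-directional pairing
  (template vertex to nearest cloud point) cannot pull the template's apex
  past itself into unclaimed cloud, so specimens with substantially more
  coiling than the template read short.  The published variant of the
  method shares this pairing direction.
- Non-planarity inherits a small positive bias from any residual surface
  wobble, because it averages |height|.
- LAD is not a descent method (the blended update is not a line search on
  the pairing objective); with hundreds of iterations on clinical-quality
  clouds the fit can drift slowly after convergence.  At the default
  50-iteration budget the drift is negligible.
- Reflection cannot be decided from the landmark triad (see above); the
  pipeline decides it from the specimen's known side, as an operator would.
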