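# oticfit

Template-based cochlear morphometry from CT volumes.

The size and shape of the human cochlea vary considerably between people,
with direct consequences for cochlear implant planning: electrode choice,
insertion depth, and the risk of insertion trauma all depend on anatomy
that clinical CT resolves at only a few dozen voxels.  `oticfit`
implements a practicable way around the resolution limit: fit a
high-resolution template surface of the otic capsule to the CT volume,
then measure the cochlea on the fitted surface.

The pipeline is:

1. **Landmark initialization** — a closed-form least-squares similarity
   transform (rotation `R`, isotropic scale `s`, translation `t`) matching
   three operator landmarks (cochlear apex, oval-window centre,
   posterior–anterior canal bifurcation) to predefined template landmarks,
   with an optional mirror for left/right.
2. **Threshold segmentation** — marching-squares iso-contours per axial
   slice at an operator-chosen grayscale threshold give the boundary point
   cloud.
3. **Similarity ICP** — iterative closest point with a closed-form
   similarity update and median-relative pair trimming.
4. **Regularized nonrigid refinement** — either a *locally affine
   deformation* (LAD: per-vertex least-squares rigid transforms over
   distance-`d` neighbourhoods, blended with proximity weights
   `exp(-r²/(d/2)²)`), or a *statistical shape model* (Procrustes
   standardization to unit centroid size + PCA;
   `X = X̄ + Σᵢ Sᵢ mᵢ` with the coefficients `Sᵢ` solved by linear least
   squares inside the ICP loop).

Measurements are made on the 101-point outer-wall contour carried on the
template: **duct length** (polyline length, round window to apex),
**reach** (maximum distance from the round window within the first 270° of
tangent turning; comparable to the clinical A-value), and
**non-planarity** (mean absolute distance of that basal window from its
total-least-squares plane — a candidate insertion-trauma correlate).

Because reference micro-CT scans of temporal bones are generally not
shareable, the package includes a synthetic cochlea phantom generator
(logarithmic-spiral duct with analytic ground truth, canal-like landmark
structure, controllable size/taper/vertical profile) and a pseudo-clinical
CT simulator (parallel-beam sinogram, Gaussian detector noise, filtered
backprojection, with CBCT/MDCT/poor-MDCT presets), so the whole method is
validated end to end by parameter recovery.

## Worked example

```r
library(oticfit)

template <- build_template()                  # mean-shape template + traced contour
specimen <- sample_cohort(2, seed = 7)[[2]]   # a synthetic "patient"

micro <- phantom_volume(specimen, spacing = 0.15)          # micro-CT-like
clinical <- degrade_volume(micro, degrade_config("mdct"))  # 0.3 mm + noise

cloud <- extract_threshold_cloud(clinical, threshold = 170)
init  <- landmark_similarity(template$landmarks, specimen$truth$landmarks,
                             reflect = if (specimen$truth$side != template$side)
                                         "force" else "never")
icp   <- icp_similarity(template$mesh, cloud, init, iters = 200,
                        anchors = list(src = template$landmarks,
                                       dst = specimen$truth$landmarks))
fit   <- lad_fit(apply_transform(icp, template$mesh), cloud,
                 lad_config(d = 5, iters = 50))

measure_fitted(fit$mesh, template)[c("non_planarity", "reach", "duct_length")]
#> $non_planarity
#> [1] 0.129911
#> $reach
#> [1] 9.097407
#> $duct_length
#> [1] 40.82285

unlist(specimen$truth[c("non_planarity", "reach", "duct_length")])
#> non_planarity         reach   duct_length
#>     0.1359426     9.3139899    41.2850138
```

From a noisy 0.3 mm pseudo-clinical volume, the fitted surface recovers
this specimen's non-planarity within 0.006 mm, reach within 0.22 mm and
outer-wall duct length within 0.5 mm.  `run_experiment()` repeats this over an
18-specimen cohort, three degradation presets and three thresholds, and
summarizes mean absolute error as a percentage of the cohort's
gold-standard range (including the unfitted-template baseline);
`sensitivity_sweep()` varies the threshold, `d`, the iteration budget or
the template.

A command-line interface over the same functions is installed at
`inst/cli/oticfit-cli.R` (subcommands `phantom`, `degrade`, `segment`,
`init`, `icp`, `fit-lad`, `build-ssm`, `fit-ssm`, `measure`, `experiment`,
`sweep`).

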