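---
title: "Geometry and design of the annulus-extraction pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and design of the annulus-extraction pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`annulaR` delineates the aortic valve annulus from cardiac CT
segmentations or per-slice detections by geometry alone: no model fitting
beyond PCA, no learned components. This vignette records the model, its
assumptions, the parameters that matter, and the design decisions taken
where more than one reasonable convention exists.

## The model and its assumptions

The annulus is modelled as the planar interface between the left ventricle
and the aorta. Three assumptions follow:

1. **The interface is (nearly) planar.** The optimal plane is the PCA
   least-squares plane of the LV–Ao boundary cloud: the plane through the
   centroid whose normal is the eigenvector of the smallest covariance
   eigenvalue. This minimizes the sum of squared point–plane distances,
   and that sum equals $n\lambda_3$ (the covariance uses the $1/n$
   convention precisely so this identity holds and so that $\lambda_3$
   estimates the out-of-plane noise variance). Whether this plane truly
   coincides with the anatomical annulus plane is an assumption of the
   method, not something the pipeline can verify.
2. **The periphery of the projected cloud is the annulus contour.** After
   projection the cloud fills the valve orifice; its outermost points are
   taken as the contour. For a convex (elliptical) orifice the convex hull
   is exact; for concave outlines an alpha shape is available.
3. **A slice through the ring cuts it twice.** Sections reconstructed
   about the plane normal through the centroid each contain the rotation
   axis, so the annulus appears as two cross-sections per slice — which is
   why detections arrive as up to two boxes per angle, and why angles only
   need to cover (0°, 180°]: the frame at $\theta+180°$ spans the same
   plane with the in-plane direction negated.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `connectivity` | 6 | – | face adjacency defines the interface most conservatively; 18/26 add edge/corner contacts |
| `method` | `convex_hull` | – | parameter-free, exact for convex orifices |
| `alpha_scale` | 2.0 | × median NN distance | alpha large enough to bridge sampling gaps, small enough to follow real concavities |
| `raster_mm` | 0.1 | mm/px | raster DSC error well below the 0.5 mm voxel scale |
| `angles` | 1…180 step 1 | degrees | half revolution covers all slice planes through the axis |
| slice grid | 128 × 128 | px | at the volume's min spacing, covers a 64 mm field around the centroid — ample for an adult annulus |
| `pixel_mm` | min voxel spacing | mm/px | no information is created or destroyed at reslice time |
| ROI size | 32 × 32 | px | the detector-side ROI convention for structures of this scale |
| `iou_thresh` | 0.5 | – | the standard correct-detection threshold |

## Conventions chosen where none was forced

* **Boundary points** are midpoints of adjacent voxel-center pairs. This
  is sub-voxel, symmetric in the two classes, and deterministic. Classes
  other than LV/Ao sitting between them break adjacency: the annulus is
  the *direct* LV–Ao contact surface.
* **Normal sign and in-plane basis.** An eigenvector's sign is arbitrary,
  so the normal is oriented towards +z (then +y, then +x), and $e_1$ is
  the normalized projection of world +x onto the plane (+y fallback),
  $e_2 = n \times e_1$. Every frame in the package — fitted planes,
  phantom truth, slice frames — uses this same construction, which makes
  2D coordinates and JSON outputs reproducible across runs. A near-tie
  between the two smallest eigenvalues is broken by the lexicographically
  largest sign-normalized eigenvector and flagged with a message.
* **Raster DSC.** The overlap of two annulus areas is *defined* on a
  shared raster: the truth plane is the reference frame, the estimated
  contour is lifted to 3D and re-projected into it, and both polygons are
  filled on a common grid. Rasterized-set semantics (rather than exact
  polygon intersection) keeps the definition identical to the voxel DSC
  and makes the raster pitch an explicit, testable tolerance.
* **Detection matching** is greedy in descending confidence, one-to-one:
  a detection matches the unmatched ground-truth box of highest IoU and
  counts TP only if that IoU reaches the threshold; a sub-threshold best
  match leaves the ground-truth box available (this keeps
  TP + FN = #truth). Tests verify the greedy result equals exhaustive
  optimal assignment on all small instances.
* **AP and AM.** AP here is single-operating-point precision
  $TP/(TP+FP)$ at IoU ≥ 0.5 — deliberately *not* the PR-curve AP of the
  COCO tradition, which would require score sweeps. The average miss rate
  is the per-slice missed fraction $FN/GT$ averaged over slices with
  ground truth; this standard miss-rate reading is the package's fixed
  definition.
* **Fold summaries** use the sample SD ($n-1$); a `population` flag
  exposes the other convention since published tables do not always say
  which was used. Summaries are reported at full precision.
* **Configuration files** are YAML with flag overrides
  (flags > file > defaults), matching the tooling available in the R
  ecosystem this package targets.

## Numerical details

* PCA eigenvalues are clamped at zero; a cloud is "collinear" when
  $\lambda_2 \le 10^{-12}\lambda_1$.
* The alpha shape uses an in-package Bowyer–Watson Delaunay
  triangulation. Grid-projected clouds are massively cocircular, which is
  degenerate for incremental Delaunay; a deterministic perturbation of
  $10^{-7}\times$ the cloud diameter is applied for the triangulation
  only — emitted vertices are always original points. The boundary is the
  set of edges used by exactly one triangle of circumradius ≤ alpha,
  chained into loops; the largest-area loop is returned.
* Polygons are validated as simple (no properly crossing edge pair) and
  re-oriented counterclockwise; areas are shoelace sums.
* Reslicing samples voxel-center world coordinates; label volumes use
  nearest-neighbor (trilinear is available for scalar volumes), and
  samples outside the volume return background. Back-projection inverts
  the same pixel↔world mapping, so the two directions agree to machine
  precision.
* Degenerate inputs fail with classed errors (`annulaR_input_error`,
  `annulaR_degenerate_error`) that the CLI maps to exit codes 2 and 3.

## What the phantom does and does not emulate

The phantom provides exactly what the pipeline consumes — labels and
detections with analytic truth. An elliptical cylinder (aorta) is extruded
from a tilted plane; a half-ellipsoid (LV) caps the other side, so their
contact surface is a planar elliptical disk of area $\pi a b$ and true
equivalent radius $R_t=\sqrt{ab}$. Optional LA/OCS blobs verify that other
classes neither join nor break the LV–Ao interface. Defaults — 160³ voxels
at 0.5 mm, semi-axes 12 × 10 mm — put the annulus at adult scale.

Deliberately absent: CT intensities, noise and contrast (the pipeline
never reads Hounsfield values), segmentation errors of a real model,
calcifications, non-planar or saddle-shaped annuli, and prosthetic valves.
Passing the phantom suite therefore demonstrates the *geometry* is
correct — boundary sampling, plane fit, projection, contour, reslicing,
back-projection and all metrics — but says nothing about the upstream
segmentation or detection quality on clinical data, which dominates
real-world error.

The detection simulator places the two analytic slice–ellipse
intersections as 32 × 32 ROIs, then applies isotropic Gaussian center
jitter (mm), independent per-ROI misses, and Poisson-distributed uniform
spurious boxes. Confidences are U(0.7, 1) for true and U(0.1, 0.7) for
spurious boxes — a detector that ranks real structure above clutter; this
choice matters only through confidence-ordered matching. All randomness
flows through an explicit seed and leaves the caller's RNG state intact.

## Problem sizes in the test suite

Unit tests run on small grids (≤ 96³) and small point sets so the full
suite stays under a minute. The end-to-end recovery checks use the default
160³ phantom across 10 random orientations, 180-frame reslice sets, and
1000-ROI calibration runs — the same sizes `scripts/acceptance.R` uses.

## Known limitations

* The optimal plane is a least-squares construct; systematic tilt of the
  true anatomical plane relative to the boundary cloud is not corrected.
* Perfectly axis-aligned annuli at coarse spacing under-estimate area:
  with no lateral staircase faces, the boundary cloud samples only lattice
  points strictly inside the ellipse (an inscribed-polygon deficit of
  roughly half a voxel per semi-axis). Oblique orientations — the
  clinically realistic case — gain compensating lateral midpoints.
* The alpha-shape triangulation is $O(n \cdot T)$ and intended for
  projected clouds of a few thousand points, not for bulk meshes.
* The reader honors axis-aligned NIfTI geometries (scales + translation);
  oblique orientation matrices are reduced to their per-axis scales with a
  warning.
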