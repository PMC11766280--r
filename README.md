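# annulaR

Automatic aortic valve annulus extraction from contrast-enhanced cardiac CT,
as geometric post-processing. Before transcatheter aortic valve implantation
(TAVI), the prosthesis size is chosen from measurements of the aortic
annulus — the virtual ring at the junction of the left ventricle (LV) and
the aorta (Ao). `annulaR` implements the full geometric pipeline that turns
either a multi-class cardiac **label volume** (from any segmenter) or
per-angle **ROI detections** (from any object detector) into a delineated
annulus contour with its area, equivalent radius, and accuracy metrics. It
is aimed at medical-image-analysis researchers who have segmentations or
detections in hand and need the downstream annulus geometry and its
evaluation, reproducibly and without any trained models.

## The method

**Segmentation path.** From a five-class label volume (BG/LV/LA/Ao/OCS),
the LV–Ao interface is sampled as a 3D point cloud: the midpoint of every
face-adjacent LV–Ao voxel pair, in mm. The *optimal plane* of this cloud is
its PCA least-squares plane — centroid $\bar{p}$ plus the unit eigenvector
$n$ of the smallest eigenvalue of the covariance matrix. All points are
projected onto the plane, $u = (p-\bar p)\cdot e_1$,
$v = (p-\bar p)\cdot e_2$, and the periphery of the projected cloud (convex
hull, or an alpha shape for concave outlines) is taken as the annulus
contour. Its shoelace area $A$ gives the equivalent-circle radius

$$R_e = \sqrt{A/\pi}.$$

**Detection path.** Using the plane normal through the cloud centroid as a
rotation axis, oblique sections are reconstructed at 1°–180°; each section
cuts the annulus ring twice, so a detector (or the bundled simulator)
supplies up to two bounding boxes per slice. Box centers are back-projected
through the slice geometry into a 3D cloud, and a second PCA + projection +
periphery pass yields the annulus estimate.

**Evaluation.** Overlap against ground truth uses the Dice similarity
coefficient $\mathrm{DSC}=2|A\cap B|/(|A|+|B|)$ on voxel sets or on a
shared 2D raster; detections are matched one-to-one at IoU ≥ 0.5 giving
$\mathrm{AP}=TP/(TP+FP)$ (single-threshold precision) and the average miss
rate; sizing error is $|R_t - R_e|$ with $R_t$ the equivalent radius of the
truth. Rotation (−30°…30° by 5°) and scale (0.8…1.2 by 0.1) augmentation
grids and the associated cross-validation image arithmetic are included.

Because clinical CT and trained models are not distributable, the package
ships a **synthetic phantom**: a tilted elliptical aortic tube meeting an
LV half-ellipsoid so the LV–Ao interface is a planar elliptical disk of
known area $\pi a b$, plus a detection simulator with controllable jitter,
miss and false-positive rates. Every stage is validated against this
analytic truth.

## Worked example

```r
library(annulaR)

# phantom with an oblique annulus: ellipse 12 x 10 mm, area 120*pi
ph <- generate_phantom(phantom_spec(annulus_normal = c(1, 1, 4)))
ph$volume
#> <label_volume> 160 x 160 x 160 voxels, spacing 0.5 x 0.5 x 0.5 mm
#>   voxels per class: BG=3903380, LV=118999, LA=5926, Ao=60457, OCS=7238

# segmentation path
pts <- extract_boundary_points(ph$volume, "LV", "Ao")   # 2120 points
est <- estimate_annulus(pts)
est
#> <annulus_estimate> area 370.91 mm^2, equivalent radius 10.866 mm, 34 contour vertices
glance(est)
#> # A tibble: 1 x 4
#>   area_mm2 r_equiv_mm n_vertices plane_rms_mm
#> 1     371.       10.9         34        0.116

area_dsc_2d(est, ph$truth)     # 0.989  overlap with the true disk
radius_error(est, ph$truth)    # 0.089 mm  |Rt - Re|

# detection path with an imperfect detector
frames <- make_slice_frames(ph$truth$plane, pixel_mm = 0.5)
dets <- simulate_detections(ph$truth, frames, jitter_mm = 0.5,
                            p_miss = 0.1, fp_per_slice = 0.2, seed = 11)
gt <- simulate_detections(ph$truth, frames)   # noise-free reference boxes
match_detections(dets, gt)
#> <detection_eval> TP 329, FP 28, FN 31 | AP 0.922, AM 0.086 (IoU >= 0.50)

est2 <- estimate_annulus_from_detections(dets[dets$confidence >= 0.7, ], frames)
radius_error(est2, ph$truth)   # 0.816 mm

summarize_folds(c(0.729, 0.646, 0.800, 0.726, 0.664))
#> <fold_summary> 0.729 0.646 0.8 0.726 0.664 | mean 0.7130 +/- 0.0610 (sample SD, n=5)
```

The interpretation: on a 0.5 mm phantom the segmentation path recovers the
annulus area within ~1–2 % (DSC ≈ 0.99 against truth) and the equivalent
radius within a tenth of a millimetre; a detector with 0.5 mm center
jitter still keeps the sizing error under 1 mm, comfortably below the 3 mm
granularity of prosthetic valve sizes.

`autoplot()` methods draw the contour with its equivalent-area circle and
per-slice detection outcomes; `tidy()`/`glance()` return tibbles for use in
dplyr pipelines.

## Command line

A thin wrapper over the same functions (exit codes: 0 ok, 2 input error,
3 degenerate geometry):

```sh
Rscript inst/cli/annulus.R simulate out/ --seed 1
Rscript inst/cli/annulus.R estimate-from-labels out/phantom.nii.gz out/annulus.json
Rscript inst/cli/annulus.R estimate-from-detections out/detections.csv out/frames.json out/annulus_det.json
Rscript inst/cli/annulus.R eval out/annulus.json out/truth.json out/metrics.csv
```

Configuration is a YAML file plus flag overrides (flags > file > defaults).

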