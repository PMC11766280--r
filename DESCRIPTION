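Package: annulaR
Title: Aortic Valve Annulus Extraction from Cardiac CT Label Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Geometric post-processing pipeline that delineates the aortic
    valve annulus from multi-class cardiac CT label volumes or from per-angle
    region-of-interest detections. Extracts the left-ventricle/aorta boundary
    as a 3D point cloud, fits the optimal annulus plane by principal component
    analysis, projects the cloud onto that plane, traces the peripheral
    contour (convex hull or alpha shape), and reports annulus area, the
    equivalent-circle radius, and overlap/detection accuracy metrics (Dice
    similarity, IoU-matched precision, average miss rate). Includes an
    oblique reslicer about the annulus normal, a synthetic labeled cardiac
    phantom with analytically known annulus geometry, a detection simulator,
    and rotation/scale augmentation utilities, so every stage can be
    validated against closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
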