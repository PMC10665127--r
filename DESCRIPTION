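Package: seedhull
Title: Turntable Visual-Hull Reconstruction and Genetic-Variation Statistics for Wheat Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-to-genetics pipeline for wheat seed phenomics. Calibrates a
    single-camera turntable rig from checkerboard corner trajectories (pinhole
    intrinsics, per-view poses, rotation-axis fit from 3D circle centers),
    reconstructs seed shape by shape-from-silhouette voxel carving over the
    virtual views, extracts a watertight marching-cubes mesh, and measures nine
    multidimensional traits (length, width, thickness, surface area, volume,
    maximum projection area, roundness, cardioid-derived area, J index).
    A statistics layer assesses germplasm genetic variation from trait tables
    via the phenotypic coefficient of variation, nested analysis of variance,
    clustering evaluation, and a parent-offspring genetic variation factor.
    Includes synthetic fixture generators (rendered creased-seed silhouettes
    and checkerboards with ground truth, simulated germplasm trait tables) so
    the whole pipeline can be exercised without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    grDevices,
    utils,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0), yaml, tiff, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
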