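Package: shellmorph
Title: Morphometrics and Architecture of Scale-Built Protist Shells from
    Labeled 3D Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing segmented (labeled) 3D image volumes of
    scale-built shells of testate amoebae such as Paulinella micropora.
    Reads and writes multi-page TIFF label stacks, resamples anisotropic
    acquisitions to isotropic voxels, exports per-scale surface meshes as
    binary STL, and computes per-scale morphometrics (volume, centroid,
    surface area, and contact area with a cytoplasm label) by exact voxel
    face counting.  Aligns the cell long axis with the Z axis by iterated
    2D projection and image-moment ellipse fitting, quantifies the helical
    shell architecture (column/petal count, twist and handedness from
    centroid positions, volume-versus-Z profile outliers), and analyses
    the two-fold symmetry between mother and daughter shells.  Includes a
    fully parametric synthetic egg-shell phantom generator with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
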