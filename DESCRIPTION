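Package: dualocta
Title: Dual Acquisition Scheme 3D Optical Coherence Tomography Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs 3D microvascular angiograms from repeated-scan
    optical coherence tomography (OCT) complex field series. Computes
    repeated-B-scan dynamic contrast (OMAG complex differences) and
    repeated-A-scan adaptive decorrelation contrast (g1 autocorrelation with a
    per-voxel decorrelation horizon chosen from g1 phase stability), fuses the
    two inside/outside a diameter-thresholded large-vessel projection mask to
    suppress tail artifacts while preserving capillary sensitivity, and
    enhances capillaries with multiscale optimally-oriented-flux (Hessian
    eigenvalue) filtering. Includes a speckle-field phantom simulator with
    per-voxel ground truth, HDF5/TIFF container I/O, axial volume stitching by
    cosine similarity, and an evaluation report against phantom truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: HDF5 (libhdf5)
NeedsCompilation: yes
Config/testthat/edition: 3
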