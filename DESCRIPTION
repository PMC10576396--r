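Package: stereonav
Title: Stereo-Endoscopic Surface Reconstruction and Instrument Pose Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for guiding a bone harvester perpendicular to a joint
    surface from a speckle-illuminated stereo endoscope and an electromagnetic
    (EM) tracking system. Implements semi-global stereo matching with a census
    cost on rectified image pairs, triangulation to a metric point cloud,
    chaining of camera and EM sensor frames into a patient-fixed (femur)
    coordinate system, voxel rearrangement with non-interpolating isosurface
    extraction, surface-normal pose estimation from inscribed triangles, and a
    hemisphere-tabulation protocol that converts projected instrument rays into
    angular pose errors. A synthetic-scene module emulates the endoscope,
    speckle projector and EM tracker so the whole pipeline runs and is tested
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
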