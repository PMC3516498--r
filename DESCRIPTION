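Package: orbitovol
Title: Orbital Volume Measurement from Cone-Beam CT by Serial Coronal
    Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the volume of the bony orbit on cone-beam CT head
    volumes by the serial coronal slice method: landmark-based rigid
    reorientation into a canonical measurement frame, extraction of
    coronal slices at fixed ventrodorsal intervals from the orbital rim
    toward the apex, closed bony-contour segmentation with chord
    bridging of foramina and fissures, flood-fill area measurement in
    square millimetres, and Cavalieri estimation of orbital volume.
    Includes paired per-slice statistical comparison of the two orbits
    with case classification, rater-reproducibility summaries, and a
    synthetic phantom generator with analytically known cavity geometry
    for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
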