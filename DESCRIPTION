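Package: etmorph
Title: Eustachian Tube Morphometry from Cranial Landmarks
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measurement of Eustachian tube (ET) angle and length from named
    3D cranial landmarks, using classical cephalometric reference planes
    (Reid's standard plane, the Frankfort plane) and the mandibular-fossa
    plane suited to limited-window cone-beam CT of the temporal bone.
    Includes exact 3D geometry primitives, a synthetic-anatomy cohort
    generator with known ground truth, a minimal oblique multiplanar
    reformation (MPR) engine for voxel phantoms, and the two-sample
    statistics used for cohort comparison (unpaired t tests from raw or
    summary data, Fisher's exact test, sample-size calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
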