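Package: marrowdose
Title: Active Bone Marrow Dose Reconstruction from Radiotherapy Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs active bone marrow (ABM) dose and dose-volume
    metrics for photon external beam radiotherapy patients from DICOM-RT
    records. A pre-labeled whole-body voxel phantom, selected from a
    library by patient age, sex, height and weight, is rigidly registered
    to the patient's CT skeleton (Hounsfield-unit thresholding followed by
    the iterative closest point algorithm), giving bone-site contours in
    the DICOM patient frame. Age- and sex-specific marrow fractions are
    distributed homogeneously over each site's non-cortical voxels and the
    planned dose grid is sampled at those positions, yielding the
    marrow-weighted mean dose, exact weighted dose-volume histogram and
    D/V metrics per treatment session and cumulatively. Includes
    registration quality assurance (volume overlap fraction, overlay
    renders, rank-correlation bias checks), a record-completeness filter
    on prescribed versus recorded dose, and a synthetic DICOM-RT fixture
    generator so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
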