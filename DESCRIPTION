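Package: marrowdose
Title: Bone Marrow Dosimetry for Lu-177 Radionuclide Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organ-level bone marrow dosimetry for Lu-177-Octreotate and
    Lu-177-PSMA-617 radionuclide therapy. Implements the blood (plasma)
    method for the marrow self-absorbed dose, mass-scaled phantom S values
    for organ and remainder-of-body cross-absorbed doses, mono- and
    bi-exponential time-activity-curve fitting with analytic time
    integration, quantitative planar processing (triple-energy-window
    scatter correction, bilinear HU-to-mu calibration, projected
    attenuation maps, conjugate-view quantification, SPECT-anchored planar
    calibration, percent-isocontour volumes of interest), a hybrid
    single-planar plus sequential-SPECT protocol with pseudo-whole-body
    time-integrated activities, protocol comparison statistics, and a
    synthetic virtual-patient generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
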