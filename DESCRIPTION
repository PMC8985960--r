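Package: sweimm
Title: Single-Element Transducer Shear-Wave Elastography for
    Millimeter-Sized Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and estimation pipeline for shear-wave
    speed (SWS) measurements of millimeter-sized hydrogel samples with a
    single focused ultrasound transducer. An acoustic-radiation-force push
    launches shear waves that reflect off the four side boundaries of the
    sample at known distances; the same transducer records a pulse-echo
    A-line ensemble from which axial motion is recovered by 1D
    autocorrelation (Kasai) Doppler processing. Reflected wavefronts are
    isolated by f-k directional filtering, assigned to boundaries by a
    two-stage variance-minimizing search, timed by the time-to-centroid
    method, and converted to a single SWS by time-of-flight averaging.
    Includes an image-source wavefield simulator, a speckle RF synthesizer,
    an HDF5 container format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    rhdf5,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
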