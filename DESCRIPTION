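Package: leafplp
Title: Generative Calibration of Leaf-Clip Ultrasound Hydration Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting ultrasound transmit-receive voltage (V_TRx)
    readings from a leaf-clip sensor into relative water content (RWC).
    A conditional variational autoencoder, conditioned on five leaf
    morphometric features (area, perimeter, area-to-perimeter ratio,
    thickness, skewness), generates a per-leaf 10-point V_TRx-RWC
    characteristic curve; a polynomial transfer function fitted to that
    curve translates one-shot voltages and voltage time series into RWC.
    Includes image-based leaf morphometrics, RWC calibration from
    drying-loop mass records, a synthetic-leaf simulator for three sweet
    potato cultivars, and hold-out RMSE evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
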