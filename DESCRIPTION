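Package: hepaticMRI
Title: Quantitative MR Biomarkers of Liver Fibrosis, Steatosis and Iron Overload
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: ROI-based quantification of non-invasive liver biomarkers from
    magnitude MR images: linear calibration of T1 maps against human serum
    albumin (HSA) phantoms for fibrosis assessment, two-point Dixon fat-water
    separation with fat-fraction and signal-intensity-ratio estimation for
    steatosis grading, and multi-echo T2* relaxometry with noise-floor
    truncation and Gandon's R2*-to-LIC conversion for hepatic iron overload.
    Includes a synthetic phantom generator that emulates the acquisition
    protocol (HSA phantom T1 maps, Dixon in-phase/opposed-phase pairs, and
    multi-echo gradient-echo series with Rician noise) so every stage of the
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    jsonlite,
    RNifti,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
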