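Package: swiven
Title: Arterial Contamination Removal and Venous Volume Quantification
    for SWI Venography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Postprocessing of susceptibility-weighted imaging (SWI)
    venography contaminated by hypointense arterial signal. Arteries are
    localized on a time-of-flight MR angiogram (TOF MRA), rigidly
    coregistered to the SWI by normalized mutual information, segmented
    with a slice-wise multiscale Frangi vesselness filter, dilated
    in-plane, and excluded from the SWI before the sliding minimum
    intensity projection (mIP) is computed. The normalized visible venous
    volume (NVVV) above the M1 plane is quantified before and after the
    correction, together with the arterial contamination fraction.
    Includes a synthetic SWI/TOF vascular phantom generator with exact
    ground truth for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
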