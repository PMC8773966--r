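Package: spectsuv
Title: Quantitative SPECT-CT Bone-Lesion Analysis with SUVlbm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification of skeletal lesion uptake from reconstructed
    SPECT-CT activity volumes and cohort-level discrimination of metastatic
    from degenerative bone lesions. Implements lean-body-mass standardized
    uptake values (SUVlbm) with full radionuclide decay correction of the
    net injected activity, iterative global-maximum lesion extraction with
    threshold region growing, and the downstream statistics (Mann-Whitney,
    empirical ROC with DeLong confidence intervals, Youden cut-off, overlap
    and bin breakdowns). Ships a moment-calibrated truncated-lognormal
    cohort simulator and digital sphere phantoms so the whole pipeline is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
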