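Package: datSBR
Title: Count-Based Specific Binding Ratio Quantification for Dopamine
    Transporter SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semi-quantification of striatal dopamine-transporter binding in
    [123I]FP-CIT (DaT) SPECT volumes. Implements fixed-volume (11.2 mL)
    peak-seeded connected striatal VOI extraction, the count-based specific
    binding ratio (SBR) against an occipital reference region, and a
    reference implementation of the Tossici-Bolt large-VOI SBR. Ships a
    digital striatal phantom generator (ellipsoidal striata, Gaussian PSF,
    Poisson noise) with ground-truth SBR so the whole pipeline is testable
    without clinical data, plus evaluation utilities (coefficient of
    variation, variance-ratio test, ROC/AUC with Youden cutoff, method
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    pROC,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
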