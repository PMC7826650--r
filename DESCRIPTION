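Package: radrep
Title: Test-Retest Repeatability of MRI Radiomic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the test-retest repeatability of radiomic
    features from magnetic resonance images. Implements variable-flip-angle
    spoiled gradient-echo T1 mapping, linear intensity normalisation,
    fixed-bin-width grey-level discretisation, and a documented subset of 3D
    radiomic features (shape, first-order, and GLCM/GLRLM/GLSZM/GLDM/NGTDM
    texture classes). Feature repeatability is quantified with the one-way
    random-effects intraclass correlation coefficient ICC(1,1) and the
    repeatability coefficient (RC), both with 95% confidence intervals,
    after Shapiro-Wilk Gaussianity gating and Box-Cox transformation with
    optimal-lambda selection. ICCs from different datasets are compared with
    Fisher's Z-test under Bonferroni correction. A synthetic-data module
    generates two-visit feature tables with known variance components and
    multi-flip-angle phantom volumes with known T1 truth, supporting
    end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
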