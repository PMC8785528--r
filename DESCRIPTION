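Package: iamhiq
Title: Iam and hiQ Accuracy Indices for Imputed Genotype Dosages
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-imputation quality control for genome-wide association
    studies using the Iam/hiQ pair of per-marker accuracy indices computed
    directly from a-posteriori genotype probability (dosage) files. Provides
    streaming readers for Oxford GEN/SAMPLE dosage files, per-marker
    computation of the Hardy-Weinberg-anchored information indices Iam_chance
    and Iam_HWE and the Hellinger-distance heterogeneity index hiQ,
    data-driven filtering thresholds from a robust bivariate-normal random
    region, an exponentially weighted moving-average genome scan that calls
    "hot" and "very hot" regions enriched in poorly imputed markers,
    Manhattan-style and bubble-plot diagnostics, a synthetic dosage generator
    with controllable accuracy structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
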