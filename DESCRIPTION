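Package: msith
Title: Intratumor Heterogeneity Analysis for MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies molecular intratumor heterogeneity (ITH) from MALDI
    mass spectrometry imaging (MSI) peptide maps. Implements the full analysis
    chain: spectral preprocessing (mass-channel unification, baseline
    subtraction, outlier spectrum removal, peak alignment, TIC normalization),
    Gaussian mixture modeling of the average spectrum to define peptide
    components, abundance estimation per pixel, divisive iK-means (DivIK)
    spatial segmentation with region-driven feature selection, pairwise
    spectral similarity and Simpson diversity heterogeneity indices,
    effect-size (Cohen's d and h) differential analysis, contingency-table
    tests for clinical descriptors, and annotation of components against a
    tryptic peptide library by relative mass tolerance. Includes a synthetic
    MSI data generator with known ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
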