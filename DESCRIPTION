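Package: retroprev
Title: Retrotransposon Activity, Cancer Gene Load, and Cancer Prevalence
    Across Mammals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A comparative-oncology pipeline linking recent non-LTR
    retrotransposon (LINE-1 and SINE) activity and cancer-gene-ortholog
    load to neoplasia and malignancy prevalence across mammalian species.
    Builds per-species genomic predictors from RepeatMasker-style repeat
    annotations and gene interval sets (active-element classification,
    closest-feature distances with IQR-trimmed means, genic-insertion
    counts, OrthoFinder orthogroup parsing), transforms traits with
    Tukey's ladder of powers and min-max normalization, and fits
    necropsy-weighted phylogenetic generalized least squares regressions
    with jointly estimated Pagel's lambda and per-species sampling error,
    including AIC comparison of fixed-lambda models, Benjamini-Hochberg
    FDR control, variance inflation factors, and residual diagnostics.
    A seed-deterministic synthetic-data module generates phylogenies,
    traits, necropsy tallies, and annotation landscapes with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    nlme,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, Regression, Transposon
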