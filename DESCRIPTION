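Package: fxiloci
Title: Tail-Sampled Sequencing Association Analysis of FXI-Level Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of quantitative intermediate-phenotype
    association at targeted gene loci, modelled on the dissection of plasma
    coagulation Factor XI (FXI) activity at the KNG1 and F11 genes. Provides
    a synthetic cohort generator with block linkage-disequilibrium structure
    and a tail-sampled discovery design; minor-allele-frequency
    stratification of variants; variance-inflation-factor LD pruning and LD
    clumping of association signals; covariate-adjusted single-variant
    linear association with six multiple-testing corrections; a
    variance-component kernel (SKAT-style) score test over 2-kb sliding
    variant sets with min-p permutation family-wise error control and
    merging of significant sets into regions; and a rule-based screen for
    putative pathogenic mutations with splice-score consensus arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
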