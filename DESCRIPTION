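Package: crossGWAS
Title: Cross-Cohort QTL Identity Testing with Mixed-Model GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether association peaks found in two
    independently phenotyped and genotyped germplasm panels point at the
    same quantitative trait locus. Provides an EMMA-style linear
    mixed-model association engine (P3D/EMMAX approximation, kinship from
    genome-wide markers, quantitative Wald scans and binary score tests,
    conditional scans with marker covariates), SimpleM effective-marker
    significance thresholds, peak-region calling, a two-part peak identity
    test (conditional disappearance and correlation of -log10 P over
    shared markers), multi-environment phenotype adjustment by linear
    mixed models, standardized effect-size comparison across traits,
    haplotype-group pleiotropy analysis with Tukey-Kramer multiple
    comparisons, and a founder-mosaic simulator that generates rice-like
    diploid panels with block linkage disequilibrium for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    lme4,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
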