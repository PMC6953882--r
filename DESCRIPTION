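Package: chhscan
Title: Trans-Regulator Mapping of Transposon CHH Methylation in Inbred Line
    Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterize trans-acting regulators of
    CHH-context DNA methylation at transposable elements (TEs) from
    population bisulfite and genotype data of inbred lines.  Methylation
    counts are summarized into weighted methylation levels per TE and TE
    family, scanned with an EMMAX-style linear mixed model using
    identity-by-state kinship, and combined across phenotypes with Fisher's
    method; significance is calibrated by an a priori candidate-gene
    enrichment FDR with LD pruning of peaks.  Allelic effect profiles are
    validated against loss-of-function methylome panels via Spearman
    correlation with genome-wide SNP permutation nulls, and inter-locus
    structure is examined with standardized linkage disequilibrium (D')
    against matched-allele-frequency empirical nulls, genotype-combination
    frequencies, and longitudinal cline regressions with allele
    regression-out or BLUP structure correction.  A synthetic-data module
    emulates the statistical structure of such panels (geographic
    allele-frequency clines, two TE target classes, beta-binomial read
    noise, polygenic background) so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    MASS,
    ape,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
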