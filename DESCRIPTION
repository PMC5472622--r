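Package: methintegrate
Title: Cell-Type-Specific Integration of DNA Methylation, Gene Expression
    and Transcription-Factor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating reduced-representation bisulfite
    sequencing (RRBS) methylomes, 450K-style array betas, RNA-seq
    differential expression and transcription-factor ChIP-seq peaks across
    multiple cell types. Implements per-CpG differential methylation calling
    (Fisher exact test with Benjamini-Hochberg correction), tiling-window
    DMR construction, cell-type-specific DMR discovery by set deduction
    against all other cell types, a six-region CpG-island/shore/promoter
    genomic partition, a Bayesian Gaussian regression of differential
    expression on methylation, tumor-suppressor status and genomic segment
    (Gibbs sampling with Chib log marginal likelihood and Bayes-factor model
    selection), and a Beta-background Kolmogorov-Smirnov classifier of
    TF-methylation interplay. A synthetic-data module generates
    multi-cell-type methylomes, expression tables and peak sets with known
    ground truth so the whole pipeline is exercisable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    graphics,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
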