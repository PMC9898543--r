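Package: apatwas
Title: Alternative-Polyadenylation QTL Mapping and Transcriptome-Wide
    Association from 3'UTR Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies 3'UTR distal poly(A) site usage (PDUI) from per-base
    RNA-seq coverage by jointly fitting a two-segment breakpoint model across
    samples, maps cis-acting 3'UTR-usage quantitative trait loci (3'aQTLs)
    with permutation empirical p-values and q-value FDR control, trains
    heritability-gated cis-SNP prediction models of PDUI (BLUP, LASSO,
    Elastic Net with cross-validated selection), tests the association of
    genetically predicted PDUI with GWAS traits from summary statistics
    (3'aTWAS) with conditional and weight-permutation follow-up, and
    colocalizes 3'aQTL and GWAS signals via approximate Bayes factors.
    Includes a synthetic-data module that emulates genotypes with local LD,
    PDUI phenotypes with cis genetic effects, two-segment coverage profiles,
    and GWAS summary statistics, so the whole pipeline is testable without
    any cohort download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    MASS,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
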