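Package: mirshift
Title: Circular-Shift Enrichment of miRNA Target Genes in GWAS Top Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for family-based GWAS evidence tables:
    classifies SNPs by whether their posterior probability of association
    exceeds the prior, selects the top fraction of positive SNPs, maps them
    to candidate genes with a density-adaptive tiered window search
    (25 kb / 250 kb / 500 kb / 1 Mb), intersects the mapped genes with a
    miRNA target set built from CLIP-seq interaction tables, and assesses
    enrichment with a circular-shift permutation null that rotates the
    selection pattern along the genome-ordered SNP array. Includes a
    synthetic-study generator (genome, annotation, SNP array, interaction
    and association tables) so the whole pipeline runs and is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
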