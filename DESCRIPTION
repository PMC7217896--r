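Package: hspminer
Title: Genome-Wide Mining and Characterization of Heat Shock Protein Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide identification and characterization of heat
    shock protein (HSP) gene families in annotated plant genomes. Candidate
    genes are discovered by two evidence streams, position-specific scoring
    matrix (PSSM) profile scanning and Smith-Waterman homology search with
    Karlin-Altschul score statistics, then classified into the six canonical
    sub-families (SHSP, HSP40, HSP60, HSP70, HSP90, HSP100) by signature
    domain content and named by chromosomal position. Downstream stages detect
    tandem duplication arrays and identical duplicates, call expression-silent
    pseudogenes from TPM matrices, scan promoters for cis-acting regulatory
    elements, compute molecular weight and isoelectric point, and recover
    top-hit orthologs and per-chromosome synteny fractions against progenitor
    genomes. A synthetic-genome generator with machine-readable ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
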