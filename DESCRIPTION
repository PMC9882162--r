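Package: nlrdiv
Title: Allelic Diversity and Genomic Features of Plant NLR Immune Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking intraspecies allelic diversity of plant NLR
    immune receptors to genomic and epigenomic features. Classifies receptors
    as highly variable (hv) or non-hv from per-column Shannon entropy of
    population protein alignments; computes segregating sites, nucleotide
    diversity, Watterson's theta, Tajima's D and Nei-Gojobori piN/piS from
    codon alignments, genotype matrices, domain subsets and sliding windows;
    summarises per-gene expression (TPM), gene-body CG methylation and
    transposable-element proximity; and provides permutation, covariate-matched
    and empirical-tail enrichment tests. A seedable synthetic-data layer
    (neutral coalescent alignments, codon populations with a tunable
    nonsynonymous acceptance rate, feature tables with injected group effects)
    exercises every stage with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    vcfR
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
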