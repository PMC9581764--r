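Package: coqsplice
Title: Allele-Resolved Cryptic Splicing Analysis for CoQ10 Biosynthesis
    Gene Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterises cryptic splicing caused by intronic variants in
    coenzyme Q10 biosynthesis pathway genes from long-read RT-PCR amplicon
    sequencing. Provides a synthetic amplicon read generator with per-allele
    isoform mixtures, allele-tagging SNVs and a nanopore-like error model;
    junction-chain extraction and catalogue-based splice-isoform
    classification; read-backed allele calling and phasing via linked SNVs;
    per-allele splice-event quantification including a read-depth inclusion
    metric; an exact 2x2 association test with conditional
    maximum-likelihood odds ratio and test-inversion confidence interval;
    rare biallelic variant prioritisation over the CoQ10 pathway gene panel;
    and cross-family identity-by-state shared-haplotype detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    Rsamtools,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
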