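Package: mitohet
Title: Mitochondrial Heteroplasmy Detection, Annotation and Transmission Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying low-frequency mitochondrial heteroplasmy from
    deep-sequencing base counts. Parses samtools-style pileup text into
    strand-aware per-site base counts, computes alternative allele frequencies
    and calls heteroplasmic sites by a minor allele frequency threshold,
    annotates variants on a circular mitochondrial genome (region class,
    transition/transversion, synonymy under the vertebrate mitochondrial code),
    performs cohort-level analyses (polymorphism classification, tissue
    specificity, maternal-line concordance, genotype frequencies, exact and
    chi-square contingency tests), predicts PCR-RFLP genotyping outcomes by
    in-silico PCR and restriction digestion on circular genomes, summarises
    intergenerational transmission of heteroplasmy from pedigree allele-ratio
    tables, and simulates base-count cohorts and germline-bottleneck
    transmission for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    withr,
    seqinr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
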