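Package: rapidseq
Title: Hash-Index Read Mapping, Haplotype Variant Calling, and
    Phenotype-Driven Trio Interpretation at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained reimplementation, at desk scale, of a rapid
    clinical whole-genome sequencing analysis stack: a hash-table read
    mapper with dynamic seed extension, paired-end rescue, gapless and
    Smith-Waterman affine-gap alignment with MAPQ estimation;
    coordinate sorting and PCR-duplicate flagging; a haplotype-based
    small-variant caller built on active-region detection, De Bruijn
    local assembly, pair-HMM read likelihoods, and Bayesian diplotype
    genotyping; an ACMG-style variant categorizer with warehouse allele
    frequencies; and a phenotype- and inheritance-driven trio
    interpreter. A synthetic diploid genome and read simulator with a
    concordance evaluator makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
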