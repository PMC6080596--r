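Package: paralogdiv
Title: Divergence Analysis of Duplicated Genes Against an Outgroup
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising how two paralogous coding sequences
    have diverged since a gene duplication, using an outgroup ortholog to
    polarise changes. Reconstructs the pre-duplication ancestor by outgroup
    parsimony, assigns synonymous, nonsynonymous and indel events to each
    paralog lineage, and estimates per-lineage dS, dN and dN/dS by the
    Nei-Gojobori counting method with optional Jukes-Cantor correction.
    Includes Tajima's relative rate test on lineage-specific change counts,
    Grantham physicochemical classification of amino-acid substitutions, a
    resampling test (with an exact hypergeometric oracle) for non-random
    clustering of substitutions within a protein domain, qPCR delta-Ct
    relative-expression and stage-correlation analysis, and simulators that
    generate codon-alignment trios with planted substitution truth and
    synthetic Ct tables so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
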