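Package: farmfox
Title: Comparative Molecular Evolution of Farmed and Wild Foxes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for comparing coding sequences of farmed
    foxes (blue fox, silver fox) with their wild progenitors (arctic
    fox, red fox). Provides ORF extraction with a minimum-length CDS
    filter, reciprocal-best-hit single-copy ortholog pairing,
    codon-aware pairwise alignment, Nei-Gojobori (1986) counting
    estimation of Ka/Ks with positive-selection calling, a screen for
    lineage-exclusive amino-acid substitutions validated against a
    mammalian conservation panel, MISA-style microsatellite (SSR)
    detection with compound merging and primer-feasibility checks,
    hypergeometric term-enrichment testing, and neighbor-joining
    phylogenies with bootstrap support. A synthetic-data module
    generates ortholog quartets evolved under controlled omega,
    conservation panels with planted group-exclusive substitutions,
    and unigenes with planted SSRs, so the whole pipeline is testable
    without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
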