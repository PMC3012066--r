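Package: kirhaplo
Title: KIR Haplotype Motifs, Frequency Estimation, Diversity and Divergence Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the gene-content organisation of the human
    killer cell immunoglobulin-like receptor (KIR) locus. Models centromeric
    and telomeric gene-content motifs and the motif-based haplotype
    nomenclature; deduces haplotype pairs from presence/absence and linking
    (cis/trans) typing and estimates haplotype frequencies by
    expectation-maximisation; computes nucleotide diversity (pi) with
    sampling variance over regions, sliding windows and per-gene extracts;
    builds neighbor-joining trees from Tamura-Nei distances with bootstrap
    support and midpoint rooting; scans alignments for recombination
    breakpoints; and estimates divergence times under a calibrated strict
    molecular clock. Includes seeded generators for synthetic cohorts,
    alignments evolved on dated trees, and mosaic recombinants so every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
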