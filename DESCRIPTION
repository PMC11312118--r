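Package: m6ascreen
Title: Comparative Transcriptomic Screening of m6A Writers and Erasers in Microalgae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) writer and eraser genes across
    de novo assembled microalgal transcriptomes and reconciles transcriptome
    evidence with genome evidence. Provides ORF prediction with isoform
    collapsing, bidirectional-best-hit (BBH) orthology inference from BLAST
    tabular hits, automatic selection of the paralogy e-value cutoff that
    maximizes the number of duplicated-gene networks, typed ortholog/paralog
    network construction, gene-of-interest screening and presence/absence
    matrices, and genome-mapping reconciliation at an identity cutoff. A
    companion RT-qPCR toolkit implements reference-gene stability assessment
    (BestKeeper-, geNorm- and NormFinder-style), efficiency-corrected relative
    expression with significance testing, and net growth-rate estimation.
    A seeded synthetic-data generator produces ground-truthed gene families,
    hit tables, Cq tables and growth curves for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
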