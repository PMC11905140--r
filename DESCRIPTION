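Package: tilescreen
Title: Control-Anchored Scoring of Focused and Gene-Tiling CRISPR Dropout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for focused CRISPR-Cas9 dropout screens and
    high-density gene-tiling screens. Extracts sgRNA spacers from sequencing
    reads using the vector backbone anchors, builds count and frequency
    tables, computes control-anchored CRISPR scores (negative-control mean
    anchoring for gene panels; dual negative/positive median anchoring for
    tiling libraries), ranks genes by a robust-rank-aggregation order
    statistic with permutation p-values, converts tiling scores into Gaussian
    kernel smoothed per-residue essentiality profiles, scores per-residue
    sequence conservation from a multi-species protein alignment with a
    Jensen-Shannon divergence method against a BLOSUM62 background, and
    classifies transcription-factor target genes as CoREST-dependent or
    CoREST-independent from differential occupancy and expression tables.
    Includes generators that simulate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
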