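Package: striatarget
Title: Integrative Identification of Transcription-Factor Direct Targets
Version: 0.1.0
Authors@R: person("striatarget", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for identifying direct target genes of a
    transcription factor from ChIP-seq binding regions and two-group
    expression profiling. Peaks are annotated to transcription start sites
    by distance windows and genomic context, differential expression is
    filtered by fold-change and p-value thresholds, and the two evidence
    streams are intersected into a direct-target list with a direction
    split. Binding regions are scanned with log-odds position weight
    matrices against an empirically sampled genomic background (Z-score
    p-values), de novo k-mer motifs are enumerated with reverse-complement
    collapsing, and motif instances are filtered by a branch-length
    conservation score over a multi-species alignment and phylogenetic
    tree. Gene-set enrichment uses one-tailed hypergeometric (Fisher) and
    EASE statistics with Benjamini-Hochberg correction. A synthetic-data
    module generates repeat-masked genomes, gene models, peaks with planted
    motifs, evolved alignments and expression matrices with full ground
    truth, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
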