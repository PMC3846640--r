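Package: txscaffold
Title: Transcript-Guided Genome Scaffolding from Spliced Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders, orients and joins genome assembly contigs into scaffolds
    using long transcript reads (ESTs, mRNAs, assembled RNA-seq) as linking
    evidence. Spliced transcript-to-contig alignments in BLAT PSL format are
    screened by percent identity and length coverage to select 'guide' reads;
    each guide's alignment regions are clustered into exon blocks, adjacent
    blocks on different contigs become directed, oriented connections,
    connections implying introns larger than a maximal intron length are
    discarded, and the best-supported connection per contig end is walked
    into scaffold paths. Gap sizes are estimated from the median intron
    length observed in fully covered transcripts. Includes an assessor that
    classifies predicted joins against a reference layout into inversions,
    relocations and translocations and computes a corrected accuracy rate,
    and a synthetic-data generator (genome, contig fragmentation, transcript
    reads, truth alignments) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
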