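Package: selexr
Title: Analysis of Next-Generation Sequencing Data from In Vitro
    Selection and Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for analyzing multi-round
    next-generation sequencing data from in vitro selection/evolution
    (SELEX) experiments. Reads per-round FASTQ files (plain, gzip or
    zip), filters reads by Phred quality, dereplicates and counts unique
    sequences, trims to the randomized region by coordinates or flanking
    primers, and reverse-complements reverse-run reads. Sequence-level
    tools compute selection statistics, find and track the most abundant
    sequences, search and track IUPAC degenerate sequence motifs, and
    identify mutational intermediates and neutral paths between two
    sequences. Cluster-level tools group closely related sequences by
    edit distance around abundance peaks, track cluster peak enrichment,
    and quantify per-position nucleotide conservation with consensus
    sequences and information-content logos. Includes a synthetic
    selection-experiment simulator with exact ground truth for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    tibble,
    utils,
    stats,
    withr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
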