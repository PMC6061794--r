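Package: longreadqc
Title: Quality Control, Filtering and Decontamination for Long-Read Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control of long-read (nanopore/PacBio style)
    sequencing runs. Builds per-read feature tables from FASTQ, FASTA, SAM/BAM
    and basecaller sequencing-summary files (plain or gzip-compressed),
    computes summary statistics (N50, probability-averaged Phred quality,
    percent identity from alignment edit distance), produces numeric plot data
    and ggplot2 figures (length histograms, cumulative yield, flow-cell
    activity heatmaps, time-binned violins, hexbin/KDE bivariate plots),
    compares runs or barcodes, and provides constant-memory streaming
    filtering/trimming and contaminant-read removal for use in shell pipelines
    prior to alignment. A deterministic synthetic-data generator produces
    FASTQ/FASTA/SAM/summary fixtures with truth tables for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    tools,
    MASS,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
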