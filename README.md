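# longreadqc

Quality control, filtering and decontamination for long-read sequencing
data in R.

Long-read platforms (Oxford Nanopore, PacBio) produce reads whose lengths
span four orders of magnitude and whose per-base accuracy sits far below
short-read data, so the QC questions differ from the Illumina world: how
much yield did the run produce and when, how long are the reads (N50, not
just the mean), how accurate are they (mean Phred quality, percent
identity against a reference), which flow-cell channels worked, and did
quality decay as the run aged. `longreadqc` answers these for anyone
running or evaluating a long-read sequencing experiment, and provides the
two stream-processing steps typically applied before alignment: quality /
length / GC filtering with end-trimming, and removal of spike-in control
DNA (e.g. lambda phage).

## What it computes

Per read, from FASTQ/FASTA/SAM/BAM or basecaller sequencing-summary
files (plain or gzipped), a tibble with one row per read; on top of that:

* **Mean read quality** in probability space:
  Q̄ = −10·log₁₀( (1/n) Σᵢ 10^(−qᵢ/10) ).
  Phred scores are log error probabilities, so averaging the scores
  themselves would overstate accuracy; the probability-space mean is
  always within [min qᵢ, max qᵢ].
* **N50**: the largest length L such that reads of length ≥ L contain at
  least half of all sequenced bases (always an observed read length).
* **Percent identity** from the alignment:
  100 · (1 − NM / columns), where NM is the aligner's edit distance and
  columns = Σ lengths of CIGAR M/=/X/I/D operations. Aligned length is
  measured on the query (M/I/=/X, soft clips excluded), so aligned ≤
  effective length always holds.
* **Plot data** (numeric, render-independent): length histograms (linear
  or log10, with N50 marker), cumulative yield over time, per-channel
  flow-cell activity matrices on the 512-channel MinION grid, violin data
  of quality/length per 6 h interval, hexbin/2D-KDE bivariate payloads,
  and grouped comparisons across runs or barcodes. `autoplot()` renders
  each as a ggplot; `render_plots()` writes png/jpg/pdf/svg;
  `html_report()` assembles a self-contained HTML report plus per-read
  TSV.
* **Streaming tools**: `filter_fastq()` (trim + quality/length/GC filter,
  constant memory, stdin→stdout capable) and `screen_fastq()`
  (contaminant removal via a built-in exact-seed screen or an external
  minimap2), both also exposed as the `filt` and `lyse` subcommands of
  the `exec/longreadqc` command-line script.
* **Synthetic data**: `make_fastq()`, `make_summary()`,
  `make_alignments()`, `make_contaminated_set()` generate deterministic
  fixture files with truth tables, used throughout the test suite.

## Worked example

Simulate a 48 h run whose basecall quality decays by 0.08 Phred/h, then
summarize it:

```r
library(longreadqc)

make_summary("sequencing_summary.tsv", 5000, channels = 512,
             run_hours = 48, quality_drift = 0.08, base_quality = 13,
             seed = 42)
reads <- read_summary("sequencing_summary.tsv", label = "flowcell_A")
summarize_reads(reads)
#> Summary of dataset 'flowcell_A' (summary input)
#>   reads:           5,000
#>   total bases:     40,178,444
#>   mean length:     8,035.69
#>   median length:   4,855.5
#>   length N50:      13,215
#>   mean quality:    11.06 (over 5000 reads)
#>   median quality:  11.02
#>   reads >= Q5:     5000
#>   reads >= Q7:     5000
#>   reads >= Q10:    3872
#>   reads >= Q12:    1306
#>   reads >= Q15:    0
#>   longest reads:
#>     read002924 (191561 bases)
#>     ...
```

Half the 40 Mb yield sits in reads of 13.2 kb or longer (the N50), and
the quality tiers show most reads above Q10 but none reaching Q15. The
programmed quality decay is visible in 6 h bins:

```r
bin_by_time(reads, "mean_quality")
#>     bin start_hours end_hours     n  mean
#> 1     0           0         6   625  12.8
#> 2     1           6        12   621  12.3
#> 3     2          12        18   613  11.8
#> 4     3          18        24   617  11.3
```

Plots chain off the same table:

```r
autoplot(length_histogram(reads, log_scale = TRUE, mark_n50 = TRUE))
autoplot(cumulative_yield(reads))
autoplot(activity_matrix(reads))          # flow-cell heat map
autoplot(time_violin(reads, "mean_quality"))
html_report(summarize_reads(reads),
            list(length_histogram(reads), cumulative_yield(reads)),
            path = "report.html", table = reads)
```

In a shell pipeline, filtering and lambda decontamination sit in front of
the aligner:

```sh
gunzip -c reads.fastq.gz \
  | exec/longreadqc filt -q 7 -l 1000 --headcrop 50 \
  | exec/longreadqc lyse --reference lambda.fa \
  | minimap2 -x map-ont ref.fa - > aln.paf
```

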