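---
title: "Methods: statistics and design choices in longreadqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and design choices in longreadqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longreadqc)
```

`longreadqc` computes per-read features and run-level summaries for
long-read sequencing data, filters and decontaminates read streams, and
produces the numeric content of QC figures. This vignette explains the
statistics it computes, the parameters that matter, what the synthetic
data generator does and does not emulate, and the design decisions taken
where more than one defensible convention exists.

## Per-read features and their sources

A `read_tbl` holds one row per read with a fixed schema (length, mean
quality, start time, channel, barcode, aligned length, percent identity,
mapping quality, GC fraction). Which columns carry data depends on the
input format, and the table records that provenance in `source_kind`:

* **FASTQ** gives length, GC, and mean quality recomputed from the
  quality string (Phred+33; offset-64 encodings are deliberately out of
  scope — they do not occur in modern long-read data).
* **FASTA** gives length and GC only. Quality is never invented.
* **SAM/BAM** gives query length (soft clips included; hard-clipped bases
  are unrecoverable from the file and are not counted — a caveat for
  alignments produced with hard clipping), aligned length, percent
  identity, mapping quality, and quality/GC when the record stores the
  sequence. Exactly one record per primary alignment is kept; secondary
  (0x100) and supplementary (0x800) records are skipped, so a read is
  never double-counted.
* **Sequencing-summary TSV** gives length, channel, start time and the
  basecaller's own mean qscore. That qscore is trusted verbatim: the file
  contains no per-base qualities, and silently mixing a recomputed
  definition with the basecaller's would make FASTQ- and summary-derived
  numbers incomparable without warning. Column names are matched against
  an alias list because basecaller dialects drifted; the albacore names
  are the defaults.

Missing values are real `NA`s, never sentinel numbers; every statistic
skips them and the summary reports how many reads entered the quality
block (`n_with_quality`). Duplicate read ids are kept — nothing in the
formats guarantees uniqueness.

Start times are normalized to seconds since the earliest read across the
input files, because basecaller versions differ in whether stamps are
absolute or run-relative; after normalization both conventions coincide.

## The three core statistics

**Mean read quality.** Phred scores are log-scaled error probabilities,
so the package averages in probability space:

$$\bar{Q} = -10\,\log_{10}\!\Big(\tfrac{1}{n}\sum_i 10^{-q_i/10}\Big).$$

The arithmetic mean of Phred values would weight a Q5 base (32% error)
and a Q25 base (0.3% error) equally and systematically overstate
accuracy. The probability-space mean is bounded by the extreme per-base
scores and reduces to the constant for constant input; both properties
are tested.

**N50.** The convention used is the standard assembly-statistics one:
the largest length $L$ such that reads of length $\ge L$ contain at
least half of all bases, with the tie broken by inclusion ($\ge$, not
$>$). The returned value is always an element of the input. Tests check
agreement with an independent sort/cumulative-sum oracle on 1,000 random
length lists per run.

**Percent identity.** From a mapped record,
$100\,(1 - \mathrm{NM}/\mathrm{columns})$ with columns the summed
lengths of CIGAR M/=/X/I/D operations. Including indel columns in the
denominator counts every error the aligner reports in NM exactly once;
dividing by matched columns only (an alternative convention some tools
use) would double-penalize indels. The choice is documented rather than
asserted as universal — users comparing against other tools should check
which denominator those use. Aligned length is measured on the query
(M/I/=/X), which guarantees aligned ≤ effective length and lets both be
drawn on one axis in the partial-alignment plot.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| quality tiers | 5, 7, 10, 12, 15 | Phred | spans the practically relevant long-read range (Q5 ≈ 32% error to Q15 ≈ 3%); configurable since no standard exists |
| time bin width | 6 | hours | resolves quality decay over a 48–72 h run without starving bins |
| histogram bins | 50 | — | adequate for 10³–10⁶ reads |
| hexbin columns | 35 | cells across x | balances cell occupancy and resolution |
| KDE bandwidth | Scott's rule per axis | data units | classical default; recorded in the payload annotations so a figure is reproducible from its numbers |
| seed screen | k = 15, 3 seeds, 500-base window | bases | 15-mers are specific at genome scale; 3 co-located hits suppress chance matches |
| downsample seed | 1 | — | fixed so repeated runs of a report are identical |

## Streaming filter semantics

`filter_fastq()` processes bounded chunks, so memory use is independent
of stream length and the tool composes in shell pipelines. Semantics
that matter for interpreting its report:

* Trimming (headcrop, then tailcrop) happens first; a read shorter than
  the combined crop is dropped and counted as `trim`.
* All tests apply to the **trimmed** read — trimming exists to remove
  low-quality ends, so the retained read is judged as it will be
  emitted. (Whether to judge before or after trimming is a genuine
  convention choice; the post-trim choice is stated here so users can
  account for it.)
* Each rejected read is counted under exactly one reason, the first
  failing test in the fixed order length → quality → GC, which makes
  `input = emitted + Σ rejections` an identity the tests enforce.
* A GC bound expresses intent to screen on composition, so a read with
  no unambiguous A/C/G/T base is rejected under `gc` when any GC bound
  is set, and passes when none is. GC is always computed over
  unambiguous bases only (ambiguity codes are excluded from numerator
  and denominator) so N-rich reads do not bias toward 0% GC.
* Output preserves header lines verbatim, order is preserved, and
  filtering a concatenation equals concatenating filtered streams
  (tested).

## Contaminant screening

`screen_fastq()` drops any read the aligner maps to the contaminant
reference, with no identity or length threshold by default: for a
spike-in control the cost of a false negative (contaminant kept) is
higher than a false positive, though reads from genomic regions highly
similar to the contaminant will be lost — the known trade-off of this
approach.

The aligner is a port with two implementations. The built-in
`seed_aligner()` indexes all reference k-mers on both strands and calls
a read mapped when ≥ 3 of its k-mers hit within a 500-base window; it is
deterministic, dependency-free and strand-aware, and is the default.
`minimap2_aligner()` shells out to a minimap2 binary when one is
available, for production screening against real genomes where
sensitivity to diverged matches matters; the exact-seed screen requires
intact 15-mers and therefore loses sensitivity above roughly 10–15%
divergence, which is adequate for spike-in controls but not for distant
homology.

## The synthetic data generator

Every test input is generated by the fixtures module, deterministically
from a seed (byte-identical reruns, which is itself tested), with a
truth table written alongside so downstream statistics are checked
against generation-time bookkeeping instead of being re-derived.

What it emulates: long-tailed lognormal read lengths (default meanlog
8.5, sdlog 1 in log-bases — median ≈ 5 kb with a tail beyond 100 kb, the
shape typical of long-read libraries); per-base qualities from a clipped
normal (default mean 12, the mid-range of nanopore basecalls); uniform
channel usage; uniform start times with an optional linear quality drift
(Phred/hour) reproducing late-run quality decay; alignments with exact
NM/CIGAR bookkeeping and optional soft-clipped ends; and a contaminated
read set whose clean genome is regenerated until it shares no 15-mer
with the contaminant genome on either strand, so the seed screen
provably has zero false positives on clean reads.

What it does not emulate: nanopore error structure (homopolymer
compression, indel bias), channel-death spatial correlation on the flow
cell, barcode cross-talk, or basecaller-specific qscore calibration.
Passing tests therefore demonstrate arithmetic and bookkeeping
correctness on realistic marginals, not robustness to every artifact of
real data.

## Numerical choices and degenerate inputs

* Histogram bins are half-open with the last bin closed; a degenerate
  range (all lengths equal) is widened by ±0.5 so binning stays defined.
* Log-scale histograms and log-x bivariate plots exclude zero-length
  reads (log undefined) and tally them in the annotations, so count
  conservation remains checkable: bins + exclusions = reads.
* The 2D KDE grid is extended beyond the data range by the full
  bandwidth (four kernel standard deviations) on each side, so the
  trapezoid-rule integral of the density over the grid is 1 to well
  within 1% — tested, since a density that silently loses mass at the
  grid edge misrepresents dense regions.
* A zero bandwidth (constant data) falls back to a small positive value
  instead of failing.
* Hexagonal binning assigns each point to the nearer of its two
  candidate lattice centers, so counts are conserved exactly; identical
  points collapse into one cell.
* The MinION channel-to-grid wiring is data, not code: a packaged TSV
  maps channels 1–512 onto a 16×32 grid in four column-major blocks of
  128 channels. Vendor wiring is not derivable from first principles,
  so the map is best-effort and swappable — any bijective
  channel/row/col TSV can be supplied, and bijectivity is validated at
  load. A table whose maximum channel exceeds the layout produces an
  error suggesting a larger layout rather than silent truncation.
* Sub-seeds derived in the acceptance script stay below 2³¹ (R integers
  are 32-bit).

## Problem sizes

The test suite works at the scales the statistics need: 10⁴-read FASTQ
round-trips, 10³ random lists for the N50 oracle, 10³ simulated
alignments at 90% identity, 500 + 500 contaminated mixtures, and
10³–10⁴-read streams for filter enumeration. These sizes make binomial
sampling-error bounds (3 standard errors) tight enough to detect real
defects while keeping the full suite around a minute.

## Known limitations

* CRAM, fast5/pod5 signal data and basecalling are out of scope.
* BAM read lengths exclude hard-clipped bases.
* The packaged flow-cell map's block ordering is a documented
  convention, not vendor-verified wiring; spatial conclusions should
  rely on a user-supplied layout when exact positions matter.
* The built-in seed screen is not a general-purpose aligner; use the
  minimap2 port for diverged contaminants.
* `compare_reads()` assumes datasets fit in memory; only the filter and
  screen are streaming.
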