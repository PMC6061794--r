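# Deterministic synthetic-data generators. Every generator is a pure
# function of its parameters and seed (byte-identical reruns) and writes a
# truth table alongside the data file so downstream statistics can be
# checked against generation-time bookkeeping instead of being re-derived.

random_bases <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

paste_groups <- function(chars, group) {
  vapply(split(chars, group), paste, character(1), collapse = "",
         USE.NAMES = FALSE)
}

sample_lengths <- function(n, length_dist) {
  switch(length_dist$kind,
    fixed = rep(as.integer(length_dist$length), n),
    lognormal = pmax(1L, as.integer(round(
      stats::rlnorm(n, meanlog = length_dist$meanlog,
                    sdlog = length_dist$sdlog)))),
    stop("unknown length distribution '", length_dist$kind, "'", call. = FALSE)
  )
}

#' Length and quality distributions for synthetic reads
#'
#' `length_lognormal()` emulates the long-tailed read-length profile of
#' long-read runs (defaults: meanlog 8.5, sdlog 1 in log-bases, i.e. a
#' median around 5 kb with a tail beyond 100 kb); `length_fixed()` gives
#' constant lengths. `quality_normal()` draws integer per-base Phred
#' scores from a clipped normal; `quality_fixed()` gives a constant score.
#'
#' @param meanlog,sdlog log-scale parameters of the lognormal.
#' @param length,q fixed read length / Phred score.
#' @param mean,sd per-base Phred score distribution parameters.
#' @param min,max clip range for sampled scores.
#' @return a distribution descriptor for [make_fastq()].
#' @export
length_lognormal <- function(meanlog = 8.5, sdlog = 1) {
  stopifnot(sdlog >= 0)
  list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' @rdname length_lognormal
#' @export
length_fixed <- function(length) {
  stopifnot(length >= 1)
  list(kind = "fixed", length = length)
}

#' @rdname length_lognormal
#' @export
quality_fixed <- function(q) {
  stopifnot(q >= 1, q <= 93)
  list(kind = "fixed", q = as.integer(q))
}

#' @rdname length_lognormal
#' @export
quality_normal <- function(mean = 12, sd = 3, min = 1, max = 40) {
  stopifnot(sd >= 0, min >= 1, max <= 93, min <= max)
  list(kind = "normal", mean = mean, sd = sd, min = min, max = max)
}

sample_qualities <- function(n, quality_dist) {
  switch(quality_dist$kind,
    fixed = rep(quality_dist$q, n),
    normal = pmin(quality_dist$max,
                  pmax(quality_dist$min,
                       as.integer(round(stats::rnorm(n, quality_dist$mean,
                                                     quality_dist$sd))))),
    stop("unknown quality distribution '", quality_dist$kind, "'",
         call. = FALSE)
  )
}

#' Generate a synthetic FASTQ file with a truth table
#'
#' Writes `n` reads with lengths, per-base qualities and base composition
#' drawn from the requested distributions, plus a truth table giving each
#' read's true length, GC fraction (over unambiguous bases) and
#' probability-averaged mean quality computed directly from the sampled
#' integer scores — the oracle for reader tests.
#'
#' @param path output FASTQ file.
#' @param n number of reads (>= 0).
#' @param length_dist [length_lognormal()] or [length_fixed()].
#' @param quality_dist [quality_normal()] or [quality_fixed()].
#' @param gc target GC content of sampled bases (0-1).
#' @param seed integer seed; the same seed reproduces the file byte for
#'   byte.
#' @return invisibly, the truth tibble (`read_id`, `length`,
#'   `gc_fraction`, `mean_quality`).
#' @export
make_fastq <- function(path, n, length_dist = length_lognormal(),
                       quality_dist = quality_normal(), gc = 0.5, seed = 1) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  truth <- local_seed(seed, {
    lens <- sample_lengths(n, length_dist)
    grp <- rep.int(seq_len(n), lens)
    bases <- random_bases(sum(lens), gc)
    seqs <- paste_groups(bases, grp)
    q <- sample_qualities(sum(lens), quality_dist)
    qsplit <- split(q, grp)
    quals <- vapply(qsplit, function(v) intToUtf8(v + 33L), character(1),
                    USE.NAMES = FALSE)
    ids <- sprintf("read%06d", seq_len(n))
    if (n > 0) {
      writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
    } else {
      writeLines(character(0), path)
    }
    gc_true <- vapply(split(bases %in% c("G", "C"), grp), mean, numeric(1),
                      USE.NAMES = FALSE)
    tibble::tibble(
      read_id = ids,
      length = lens,
      gc_fraction = if (n > 0) gc_true else numeric(0),
      mean_quality = vapply(qsplit, function(v) {
        -10 * log10(mean(10^(-v / 10)))
      }, numeric(1), USE.NAMES = FALSE)
    )
  })
  readr::write_tsv(truth, paste0(path, ".truth.tsv"), progress = FALSE)
  invisible(truth)
}

#' Generate a synthetic sequencing-summary TSV with a truth table
#'
#' Emulates the basecaller's per-read summary: start times uniform over
#' the run, channels uniform over the flow cell, and mean qscores drawn as
#' `base_quality - quality_drift * hours + noise`, which reproduces the
#' quality decay seen late in a run when `quality_drift > 0`.
#'
#' @param path output TSV (albacore-style column names).
#' @param n number of reads.
#' @param channels number of flow-cell channels (>= 1).
#' @param run_hours run duration; start times are uniform on `[0, run_hours]`.
#' @param quality_drift linear quality decay in Phred units per hour.
#' @param base_quality mean qscore at time zero.
#' @param noise_sd qscore noise standard deviation.
#' @param barcodes optional character vector; when given, each read gets a
#'   uniformly sampled `barcode_arrangement` label.
#' @param length_dist read-length distribution.
#' @param seed integer seed.
#' @return invisibly, the truth tibble including the generating parameters
#'   as attributes `base_quality` and `quality_drift`.
#' @export
make_summary <- function(path, n, channels = 512, run_hours = 48,
                         quality_drift = 0, base_quality = 12,
                         noise_sd = 0.5, barcodes = NULL,
                         length_dist = length_lognormal(), seed = 1) {
  stopifnot(channels >= 1, run_hours > 0, n >= 0)
  truth <- local_seed(seed, {
    hours <- stats::runif(n, 0, run_hours)
    qscore <- pmax(1, base_quality - quality_drift * hours +
                        stats::rnorm(n, 0, noise_sd))
    df <- tibble::tibble(
      read_id = sprintf("read%06d", seq_len(n)),
      channel = sample.int(channels, n, replace = TRUE),
      start_time = round(hours * 3600, 3),
      sequence_length_template = sample_lengths(n, length_dist),
      mean_qscore_template = round(qscore, 3)
    )
    if (!is.null(barcodes)) {
      df$barcode_arrangement <- sample(barcodes, n, replace = TRUE)
    }
    df
  })
  readr::write_tsv(truth, path, progress = FALSE)
  attr(truth, "base_quality") <- base_quality
  attr(truth, "quality_drift") <- quality_drift
  invisible(truth)
}

#' Generate a synthetic SAM file with exact alignment bookkeeping
#'
#' Builds a random reference, samples reads from it, introduces point
#' substitutions at per-base rate `1 - identity`, and optionally soft-clips
#' a fraction of reads at both ends with random (unaligned) sequence. The
#' SAM `NM` tag and CIGAR are exact by construction, and the truth table
#' records per read the introduced edit count, aligned length, full length
#' and resulting percent identity.
#'
#' @param path output SAM file.
#' @param n number of reads.
#' @param reference_length length of the generated reference in bases.
#' @param identity per-base match probability of aligned bases (0-1).
#' @param partial_fraction fraction of reads given soft-clipped ends.
#' @param read_length_range aligned-segment length bounds (uniform).
#' @param base_quality constant Phred score written for every base.
#' @param seed integer seed.
#' @return invisibly, the truth tibble (`read_id`, `length`,
#'   `aligned_length`, `edits`, `columns`, `percent_identity`, `cigar`).
#' @export
make_alignments <- function(path, n, reference_length = 50000,
                            identity = 0.9, partial_fraction = 0,
                            read_length_range = c(300, 2000),
                            base_quality = 12, seed = 1) {
  stopifnot(identity >= 0, identity <= 1,
            partial_fraction >= 0, partial_fraction <= 1,
            read_length_range[1] >= 1,
            read_length_range[2] <= reference_length)
  truth <- local_seed(seed, {
    ref <- paste(random_bases(reference_length), collapse = "")
    mlen <- as.integer(round(stats::runif(n, read_length_range[1],
                                          read_length_range[2])))
    pos <- vapply(mlen, function(l) {
      sample.int(reference_length - l + 1L, 1L)
    }, integer(1))
    partial <- stats::runif(n) < partial_fraction
    clip5 <- ifelse(partial, as.integer(round(stats::runif(n, 0.05, 0.3) * mlen)), 0L)
    clip3 <- ifelse(partial, as.integer(round(stats::runif(n, 0.05, 0.3) * mlen)), 0L)
    ids <- sprintf("aln%06d", seq_len(n))
    records <- character(n)
    edits <- integer(n)
    seq_out <- character(n)
    for (i in seq_len(n)) {
      core <- strsplit(substr(ref, pos[i], pos[i] + mlen[i] - 1L), "")[[1]]
      mut <- which(stats::runif(mlen[i]) < 1 - identity)
      if (length(mut)) {
        core[mut] <- vapply(core[mut], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      edits[i] <- length(mut)
      seq_i <- paste0(
        paste(random_bases(clip5[i]), collapse = ""),
        paste(core, collapse = ""),
        paste(random_bases(clip3[i]), collapse = "")
      )
      seq_out[i] <- seq_i
      cig <- paste0(
        if (clip5[i] > 0) paste0(clip5[i], "S") else "",
        mlen[i], "M",
        if (clip3[i] > 0) paste0(clip3[i], "S") else ""
      )
      records[i] <- paste(
        ids[i], 0L, "ref", pos[i], 60L, cig, "*", 0L, 0L, seq_i,
        strrep(intToUtf8(base_quality + 33L), nchar(seq_i)),
        paste0("NM:i:", edits[i]),
        sep = "\t"
      )
    }
    writeLines(c(
      "@HD\tVN:1.6\tSO:unsorted",
      paste0("@SQ\tSN:ref\tLN:", reference_length),
      records
    ), path)
    tibble::tibble(
      read_id = ids,
      length = clip5 + mlen + clip3,
      aligned_length = mlen,
      edits = edits,
      columns = mlen,
      percent_identity = 100 * (1 - edits / mlen),
      cigar = vapply(seq_len(n), function(i) paste0(
        if (clip5[i] > 0) paste0(clip5[i], "S") else "",
        mlen[i], "M",
        if (clip3[i] > 0) paste0(clip3[i], "S") else ""), character(1))
    )
  })
  readr::write_tsv(truth, paste0(path, ".truth.tsv"), progress = FALSE)
  invisible(truth)
}

#' Generate a contaminated read set with a synthetic contaminant genome
#'
#' Emulates a run spiked with control DNA: contaminant reads are
#' substrings of a generated 10 kb stand-in genome (with optional
#' substitution errors), clean reads are exact substrings of an
#' independent random genome regenerated until its forward k-mers share
#' nothing with the contaminant genome on either strand. k-mer
#' disjointness guarantees the built-in seed screen has zero false
#' positives on the clean reads.
#'
#' @param dir output directory; writes `reads.fastq`, `contaminant.fa`
#'   (the synthetic stand-in genome) and `reads.truth.tsv`.
#' @param n_clean,n_contaminant read counts of each class.
#' @param error_rate substitution rate applied to contaminant reads.
#' @param genome_length length of each genome.
#' @param read_length_range uniform read-length bounds.
#' @param k k-mer size used for the disjointness guarantee.
#' @param seed integer seed.
#' @return invisibly, a list with `fastq`, `reference` paths and the
#'   `truth` tibble (`read_id`, `is_contaminant`).
#' @export
make_contaminated_set <- function(dir, n_clean, n_contaminant,
                                  error_rate = 0.05, genome_length = 10000,
                                  read_length_range = c(400, 2000), k = 15,
                                  seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fastq <- file.path(dir, "reads.fastq")
  fasta <- file.path(dir, "contaminant.fa")
  truth <- local_seed(seed, {
    contam <- paste(random_bases(genome_length), collapse = "")
    contam_kmers <- unique(c(seq_kmers(contam, k),
                             seq_kmers(revcomp(contam), k)))
    repeat {
      clean <- paste(random_bases(genome_length), collapse = "")
      if (!any(seq_kmers(clean, k) %in% contam_kmers)) break
    }
    writeLines(c(">synthetic_contaminant", contam), fasta)
    sample_reads <- function(genome, n, mutate_rate) {
      lens <- as.integer(round(stats::runif(n, read_length_range[1],
                                            read_length_range[2])))
      lens <- pmin(lens, nchar(genome))
      starts <- vapply(lens, function(l) {
        sample.int(nchar(genome) - l + 1L, 1L)
      }, integer(1))
      vapply(seq_len(n), function(i) {
        s <- strsplit(substr(genome, starts[i], starts[i] + lens[i] - 1L),
                      "")[[1]]
        if (mutate_rate > 0) {
          mut <- which(stats::runif(lens[i]) < mutate_rate)
          if (length(mut)) {
            s[mut] <- vapply(s[mut], function(b) {
              sample(setdiff(c("A", "C", "G", "T"), b), 1)
            }, character(1))
          }
        }
        paste(s, collapse = "")
      }, character(1))
    }
    seqs <- c(sample_reads(contam, n_contaminant, error_rate),
              sample_reads(clean, n_clean, 0))
    is_contam <- c(rep(TRUE, n_contaminant), rep(FALSE, n_clean))
    ord <- sample.int(length(seqs))
    seqs <- seqs[ord]
    is_contam <- is_contam[ord]
    ids <- sprintf("mix%06d", seq_along(seqs))
    if (length(seqs)) {
      writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                                 vapply(nchar(seqs), function(l) {
                                   strrep("I", l)
                                 }, character(1)))), fastq)
    } else {
      writeLines(character(0), fastq)
    }
    tibble::tibble(read_id = ids, is_contaminant = is_contam)
  })
  readr::write_tsv(truth, file.path(dir, "reads.truth.tsv"), progress = FALSE)
  invisible(list(fastq = fastq, reference = fasta, truth = truth))
}
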