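#' Filtering and trimming parameters for a read stream
#'
#' Bundles the predicate and trim settings applied to each FASTQ record by
#' [filter_fastq()]: fixed-length trimming from the 5' (`headcrop`) and 3'
#' (`tailcrop`) ends, then bounds on the trimmed read's length, mean
#' quality (probability-space average) and GC fraction.
#'
#' @param min_quality minimum mean Phred quality of the trimmed read.
#' @param min_length,max_length bounds on trimmed read length in bases.
#' @param min_gc,max_gc bounds on GC fraction (0-1) of the trimmed read.
#' @param headcrop,tailcrop bases removed from the read start / end.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(min_quality = NULL, min_length = NULL,
                        max_length = NULL, min_gc = NULL, max_gc = NULL,
                        headcrop = 0, tailcrop = 0) {
  if (headcrop < 0 || tailcrop < 0) {
    stop("headcrop and tailcrop must be >= 0", call. = FALSE)
  }
  if (!is.null(min_length) && !is.null(max_length) && min_length > max_length) {
    stop("min_length exceeds max_length", call. = FALSE)
  }
  if (!is.null(min_gc) && !is.null(max_gc) && min_gc > max_gc) {
    stop("min_gc exceeds max_gc", call. = FALSE)
  }
  structure(list(min_quality = min_quality, min_length = min_length,
                 max_length = max_length, min_gc = min_gc, max_gc = max_gc,
                 headcrop = as.integer(headcrop),
                 tailcrop = as.integer(tailcrop)),
            class = "filter_spec")
}

#' Trim fixed lengths from both ends of a read
#'
#' Sequence and quality string are cropped identically. A read shorter than
#' `headcrop + tailcrop + 1` cannot survive trimming and is dropped.
#'
#' @param seq,qual sequence and quality strings of equal length.
#' @param headcrop,tailcrop bases to remove from the 5' / 3' end.
#' @return a list with `seq` and `qual`, or `NULL` when the read is
#'   consumed by trimming.
#' @export
trim_read <- function(seq, qual, headcrop = 0, tailcrop = 0) {
  n <- nchar(seq)
  if (headcrop + tailcrop >= n) return(NULL)
  list(seq = substr(seq, headcrop + 1L, n - tailcrop),
       qual = substr(qual, headcrop + 1L, n - tailcrop))
}

#' Stream-filter a FASTQ file
#'
#' Reads FASTQ from a file, gzip file, connection or `"-"` (stdin), trims
#' and tests each record, and writes the survivors — header line preserved
#' verbatim — to the output in input order. Records are processed in
#' bounded chunks, so memory use does not grow with stream length and the
#' filter can sit inside a shell pipeline ahead of an aligner.
#'
#' Each read is first trimmed (headcrop, then tailcrop); reads consumed by
#' trimming are dropped as `trim`. The surviving read is then tested, on
#' its trimmed sequence, in the fixed order length, quality, GC; it is
#' counted under the first test it fails, so the report's reason counts
#' add up to the input count. A GC bound expresses intent to screen on
#' composition, so a read with no unambiguous base is rejected under `gc`
#' whenever a GC bound is set.
#'
#' @param input FASTQ source (path, connection or `"-"`).
#' @param output FASTQ sink (path, connection or `"-"` for stdout).
#' @param spec a [filter_spec()].
#' @return a `filter_report`: counts of input, emitted and per-reason
#'   rejected reads (`trim`, `length`, `quality`, `gc`).
#' @export
filter_fastq <- function(input, output, spec = filter_spec()) {
  out <- open_write_connection(output)
  if (!inherits(output, "connection") && !identical(output, "-")) {
    on.exit(close(out))
  }
  counts <- new.env(parent = emptyenv())
  counts$input <- 0L
  counts$emitted <- 0L
  counts$trim <- 0L
  counts$length <- 0L
  counts$quality <- 0L
  counts$gc <- 0L

  fastq_chunk_apply(input, function(chunk, first) {
    n0 <- nchar(chunk$seq)
    counts$input <- counts$input + length(n0)
    keep <- n0 > spec$headcrop + spec$tailcrop
    counts$trim <- counts$trim + sum(!keep)
    idx <- which(keep)
    if (!length(idx)) return(invisible())
    seqs <- substr(chunk$seq[idx], spec$headcrop + 1L, n0[idx] - spec$tailcrop)
    quals <- substr(chunk$qual[idx], spec$headcrop + 1L, n0[idx] - spec$tailcrop)
    n <- nchar(seqs)

    pass_len <- rep(TRUE, length(idx))
    if (!is.null(spec$min_length)) pass_len <- pass_len & n >= spec$min_length
    if (!is.null(spec$max_length)) pass_len <- pass_len & n <= spec$max_length

    pass_q <- rep(TRUE, length(idx))
    if (!is.null(spec$min_quality)) {
      pass_q <- qual_string_mean_quality(quals) >= spec$min_quality
    }

    pass_gc <- rep(TRUE, length(idx))
    if (!is.null(spec$min_gc) || !is.null(spec$max_gc)) {
      gc <- seq_gc_fraction(seqs)$gc_fraction
      pass_gc <- !is.na(gc)
      if (!is.null(spec$min_gc)) pass_gc <- pass_gc & gc >= spec$min_gc
      if (!is.null(spec$max_gc)) pass_gc <- pass_gc & gc <= spec$max_gc
    }

    counts$length <- counts$length + sum(!pass_len)
    counts$quality <- counts$quality + sum(pass_len & !pass_q)
    counts$gc <- counts$gc + sum(pass_len & pass_q & !pass_gc)
    emit <- which(pass_len & pass_q & pass_gc)
    counts$emitted <- counts$emitted + length(emit)
    if (length(emit)) {
      rec <- rbind(chunk$header[idx][emit], seqs[emit],
                   chunk$plus[idx][emit], quals[emit])
      writeLines(as.vector(rec), out)
    }
    invisible()
  })
  structure(list(input = counts$input, emitted = counts$emitted,
                 rejected = c(trim = counts$trim, length = counts$length,
                              quality = counts$quality, gc = counts$gc)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.filter_report <- function(x, ...) {
  c(sprintf("input=%d", x$input),
    sprintf("emitted=%d", x$emitted),
    sprintf("rejected_%s=%d", names(x$rejected), x$rejected))
}
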