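# Streaming FASTQ plumbing shared by the readers, the stream filter and the
# contaminant screen. Records are processed in bounded chunks so memory use
# is independent of stream length.

open_read_connection <- function(path) {
  if (inherits(path, "connection")) return(path)
  if (identical(path, "-")) return(file("stdin", open = "rt"))
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  gzfile(path, open = "rt") # transparently reads plain text too
}

open_write_connection <- function(path) {
  if (inherits(path, "connection")) return(path)
  if (identical(path, "-")) return(stdout())
  file(path, open = "wt")
}

# Applies fun(chunk, first_ordinal) to successive chunks of a 4-line FASTQ
# stream. chunk is a list(header, id, seq, plus, qual) of parallel character
# vectors; ordinals are 1-based record numbers used in error messages.
fastq_chunk_apply <- function(input, fun, chunk_records = 2000L,
                              source_name = NULL) {
  con <- open_read_connection(input)
  opened <- !inherits(input, "connection")
  if (opened) on.exit(close(con))
  src <- source_name %||% (if (is.character(input)) input else "stream")
  ordinal <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_records)
    if (length(lines) == 0) break
    if (length(lines) %% 4L != 0L) {
      stop("truncated FASTQ record at record ", ordinal + length(lines) %/% 4L + 1L,
           " in ", src, call. = FALSE)
    }
    n <- length(lines) %/% 4L
    chunk <- list(
      header = lines[seq(1L, length(lines), 4L)],
      seq = lines[seq(2L, length(lines), 4L)],
      plus = lines[seq(3L, length(lines), 4L)],
      qual = lines[seq(4L, length(lines), 4L)]
    )
    chunk$id <- sub("^@", "", sub("[ \t].*$", "", chunk$header))
    bad <- which(!startsWith(chunk$header, "@") | !startsWith(chunk$plus, "+"))
    if (length(bad)) {
      stop("malformed FASTQ record ", ordinal + bad[1], " in ", src,
           " (header or separator line)", call. = FALSE)
    }
    bad <- which(nchar(chunk$seq) != nchar(chunk$qual))
    if (length(bad)) {
      stop("malformed FASTQ record for read '", chunk$id[bad[1]], "' in ", src,
           ": sequence and quality strings differ in length", call. = FALSE)
    }
    fun(chunk, ordinal + 1L)
    ordinal <- ordinal + n
  }
  invisible(ordinal)
}

# Probability-space mean quality per read, vectorized over quality strings
# (Phred+33 encoding).
qual_string_mean_quality <- function(quals) {
  n <- nchar(quals)
  out <- rep(NA_real_, length(quals))
  nz <- n > 0
  if (!any(nz)) return(out)
  codes <- utf8ToInt(paste(quals[nz], collapse = ""))
  if (any(codes < 33)) stop("quality character below Phred+33 range", call. = FALSE)
  p <- 10^(-(codes - 33) / 10)
  grp <- rep.int(seq_len(sum(nz)), n[nz])
  out[nz] <- -10 * log10(rowsum(p, grp)[, 1] / n[nz])
  out
}

# GC fraction over unambiguous bases only: ambiguous IUPAC codes are
# excluded from numerator and denominator; a read with no unambiguous base
# gets NA. Returns a warning count of reads containing non-IUPAC characters.
seq_gc_fraction <- function(seqs) {
  gc <- nchar(gsub("[^GCgc]", "", seqs))
  acgt <- nchar(gsub("[^ACGTacgt]", "", seqs))
  iupac <- nchar(gsub("[^ACGTRYSWKMBDHVNUacgtryswkmbdhvnu]", "", seqs))
  non_iupac <- sum(iupac != nchar(seqs))
  frac <- ifelse(acgt > 0, gc / acgt, NA_real_)
  list(gc_fraction = frac, n_non_iupac = non_iupac)
}
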