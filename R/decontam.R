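#' Aligners for contaminant screening
#'
#' [screen_fastq()] drops any read that maps to a contaminant reference
#' (typically the lambda phage control DNA spiked into nanopore runs).
#' The mapping step is a small port with two implementations:
#'
#' * `seed_aligner()` — built-in exact-seed screen: the reference's k-mers
#'   (both strands) are indexed once, and a read is called mapped when at
#'   least `min_seeds` of its k-mers hit the index within a window of
#'   `window` bases. Deterministic, dependency-free, and strand-aware.
#' * `minimap2_aligner()` — shells out to a `minimap2` executable when one
#'   is on the `PATH`, using the map-ont preset; reads named in the PAF
#'   output are called mapped.
#'
#' @param reference path to the contaminant reference FASTA.
#' @param k seed length in bases.
#' @param min_seeds minimum co-located seed hits to call a read mapped.
#' @param window span in bases within which the seed hits must fall.
#' @return an aligner object usable as the `aligner` argument of
#'   [screen_fastq()]; its `map_reads(sequences)` element returns a logical
#'   vector, `TRUE` where the read maps to the reference.
#' @export
seed_aligner <- function(reference, k = 15, min_seeds = 3, window = 500) {
  seqs <- read_reference(reference)
  kmers <- unique(unlist(lapply(c(seqs, revcomp(seqs)), seq_kmers, k = k)))
  if (length(kmers) == 0) {
    stop("reference yields no ", k, "-mers; is it empty or too short?",
         call. = FALSE)
  }
  map_reads <- function(sequences) {
    vapply(toupper(sequences), function(s) {
      km <- seq_kmers(s, k)
      if (length(km) < min_seeds) return(FALSE)
      pos <- which(km %in% kmers)
      if (length(pos) < min_seeds) return(FALSE)
      span <- pos[min_seeds:length(pos)] - pos[1:(length(pos) - min_seeds + 1)]
      any(span <= window)
    }, logical(1), USE.NAMES = FALSE)
  }
  structure(list(kind = "seed", k = k, min_seeds = min_seeds,
                 window = window, n_kmers = length(kmers),
                 map_reads = map_reads),
            class = "contaminant_aligner")
}

#' @rdname seed_aligner
#' @param executable name or path of the minimap2 binary.
#' @export
minimap2_aligner <- function(reference, executable = "minimap2") {
  if (Sys.which(executable) == "") {
    stop("minimap2 executable not found on PATH; use seed_aligner()",
         call. = FALSE)
  }
  read_reference(reference) # validates the file up front
  map_reads <- function(sequences) {
    fq <- tempfile(fileext = ".fa")
    on.exit(unlink(fq))
    ids <- paste0("q", seq_along(sequences))
    writeLines(as.vector(rbind(paste0(">", ids), sequences)), fq)
    paf <- suppressWarnings(
      system2(executable, c("-x", "map-ont", "--secondary=no",
                            shQuote(reference), shQuote(fq)),
              stdout = TRUE, stderr = FALSE)
    )
    mapped <- unique(vapply(strsplit(paf, "\t"), `[[`, character(1), 1))
    ids %in% mapped
  }
  structure(list(kind = "minimap2", map_reads = map_reads),
            class = "contaminant_aligner")
}

read_reference <- function(reference) {
  if (!file.exists(reference)) {
    stop("contaminant reference not found: ", reference, call. = FALSE)
  }
  seqs <- toupper(as.character(Biostrings::readBStringSet(reference)))
  if (length(seqs) == 0 || sum(nchar(seqs)) == 0) {
    stop("contaminant reference ", reference, " is empty", call. = FALSE)
  }
  unname(seqs)
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Remove contaminant reads from a FASTQ stream
#'
#' Streams FASTQ records through a contaminant aligner and drops every
#' read with at least one mapping to the reference; surviving reads are
#' written unchanged, in order. No identity or length threshold gates the
#' removal by default — any mapping removes the read — which errs on the
#' side of decontamination at the cost of possibly discarding genuine
#' reads from regions highly similar to the contaminant.
#'
#' @param input FASTQ source (path, connection or `"-"` for stdin).
#' @param output FASTQ sink (path, connection or `"-"` for stdout).
#' @param reference contaminant reference FASTA; ignored when `aligner` is
#'   given.
#' @param aligner a [seed_aligner()] or [minimap2_aligner()]; defaults to
#'   the built-in seed screen over `reference`.
#' @return a `screen_report` with `input`, `kept` and `removed` counts.
#' @export
screen_fastq <- function(input, output, reference = NULL, aligner = NULL) {
  if (is.null(aligner)) {
    if (is.null(reference)) {
      stop("supply a contaminant reference FASTA or an aligner", call. = FALSE)
    }
    aligner <- seed_aligner(reference)
  }
  out <- open_write_connection(output)
  if (!inherits(output, "connection") && !identical(output, "-")) {
    on.exit(close(out))
  }
  counts <- new.env(parent = emptyenv())
  counts$input <- 0L
  counts$kept <- 0L
  fastq_chunk_apply(input, function(chunk, first) {
    counts$input <- counts$input + length(chunk$seq)
    mapped <- aligner$map_reads(chunk$seq)
    keep <- which(!mapped)
    counts$kept <- counts$kept + length(keep)
    if (length(keep)) {
      rec <- rbind(chunk$header[keep], chunk$seq[keep],
                   chunk$plus[keep], chunk$qual[keep])
      writeLines(as.vector(rec), out)
    }
    invisible()
  })
  structure(list(input = counts$input, kept = counts$kept,
                 removed = counts$input - counts$kept),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.screen_report <- function(x, ...) {
  c(sprintf("input=%d", x$input), sprintf("kept=%d", x$kept),
    sprintf("removed=%d", x$removed))
}
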