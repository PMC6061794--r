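#' Build a read table from FASTQ files
#'
#' Reads one or more 4-line FASTQ files (plain or gzip-compressed; gzip is
#' auto-detected) and computes, per read: length, GC fraction over
#' unambiguous bases, and the probability-averaged Phred quality from the
#' quality string (Phred+33). Records from multiple files are concatenated
#' in path order.
#'
#' @param paths one or more FASTQ file paths.
#' @param label dataset name for the resulting table.
#' @return a [read_tbl()] with `source_kind = "fastq"`.
#' @export
read_fastq <- function(paths, label = "reads") {
  if (length(paths) == 0) stop("no input files given", call. = FALSE)
  acc <- new.env(parent = emptyenv())
  acc$parts <- list()
  for (path in paths) {
    fastq_chunk_apply(path, function(chunk, first) {
      acc$parts[[length(acc$parts) + 1L]] <- tibble::tibble(
        read_id = chunk$id,
        length = nchar(chunk$seq),
        mean_quality = qual_string_mean_quality(chunk$qual),
        gc_fraction = seq_gc_fraction(chunk$seq)$gc_fraction
      )
    })
  }
  df <- if (length(acc$parts)) dplyr::bind_rows(acc$parts) else
    tibble::tibble(read_id = character(), length = integer())
  read_tbl(df, label = label, source_kind = "fastq")
}

#' Build a read table from FASTA files
#'
#' Sequences may span multiple lines and files may be gzip-compressed.
#' FASTA carries no base qualities, so `mean_quality` is absent. Sequences
#' containing characters outside the IUPAC nucleotide codes raise a
#' warning; every character counts toward the read length, but only
#' unambiguous A/C/G/T bases enter the GC fraction.
#'
#' @inheritParams read_fastq
#' @return a [read_tbl()] with `source_kind = "fasta"`.
#' @export
read_fasta <- function(paths, label = "reads") {
  if (length(paths) == 0) stop("no input files given", call. = FALSE)
  parts <- lapply(paths, function(path) {
    if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    txt <- as.character(seqs)
    gc <- seq_gc_fraction(txt)
    if (gc$n_non_iupac > 0) {
      warning(gc$n_non_iupac, " sequence(s) in ", path,
              " contain non-IUPAC characters; they count toward length only",
              call. = FALSE)
    }
    tibble::tibble(
      read_id = sub("[ \t].*$", "", names(seqs)),
      length = nchar(txt),
      gc_fraction = gc$gc_fraction
    )
  })
  read_tbl(dplyr::bind_rows(parts), label = label, source_kind = "fasta")
}

#' Build a read table from a SAM/BAM alignment file
#'
#' Emits exactly one record per primary alignment line: secondary (flag
#' 0x100) and supplementary (flag 0x800) records are skipped. Mapped reads
#' get `length` (query length including soft clips), `aligned_length`
#' (CIGAR M/I/=/X on the query), `percent_identity` (from the NM tag, see
#' [percent_identity()]), `mapping_quality`, plus mean quality and GC
#' computed from the stored sequence when present. Unmapped reads
#' contribute length-only records. A `.sam` input is converted to BAM
#' internally.
#'
#' @param path a SAM or BAM file.
#' @param label dataset name.
#' @return a [read_tbl()] with `source_kind = "bam"`.
#' @export
read_alignments <- function(path, label = "reads") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "cigar", "seq", "qual"),
    tag = "NM"
  ))[[1]]
  flag <- res$flag
  if (is.null(res$tag$NM)) res$tag$NM <- rep(NA_integer_, length(flag))
  primary <- bitwAnd(flag, bitwOr(256L, 2048L)) == 0L
  qname <- res$qname[primary]
  flag <- flag[primary]
  cigar <- res$cigar[primary]
  mapq <- res$mapq[primary]
  nm <- res$tag$NM[primary]
  seqs <- as.character(res$seq)[primary]
  quals <- as.character(res$qual)[primary]
  unmapped <- bitwAnd(flag, 4L) == 4L

  len <- nchar(seqs)
  meanq <- rep(NA_real_, length(qname))
  has_qual <- quals != "*" & nchar(quals) == len
  meanq[has_qual] <- qual_string_mean_quality(quals[has_qual])
  gc <- seq_gc_fraction(seqs)$gc_fraction

  aligned <- rep(NA_integer_, length(qname))
  pid <- rep(NA_real_, length(qname))
  mq <- rep(NA_integer_, length(qname))
  mapped <- which(!unmapped)
  if (length(mapped)) {
    no_cigar <- is.na(cigar[mapped]) | cigar[mapped] == "*"
    if (any(no_cigar)) {
      stop("mapped read without a CIGAR string: ",
           qname[mapped][which(no_cigar)[1]], call. = FALSE)
    }
    aligned[mapped] <- as.integer(aligned_query_length(cigar[mapped]))
    mq[mapped] <- mapq[mapped]
    has_nm <- !is.na(nm[mapped])
    if (any(!has_nm)) {
      warning(sum(!has_nm), " mapped read(s) in ", path,
              " lack an NM tag; percent identity left absent", call. = FALSE)
    }
    idx <- mapped[has_nm]
    pid[idx] <- percent_identity(cigar[idx], nm[idx])
  }
  read_tbl(tibble::tibble(
    read_id = qname, length = len, mean_quality = meanq,
    aligned_length = aligned, percent_identity = pid,
    mapping_quality = mq, gc_fraction = gc
  ), label = label, source_kind = "bam")
}

# Column aliases across basecaller dialects; first match wins.
summary_column_aliases <- list(
  read_id = c("read_id", "read_name", "id"),
  channel = c("channel", "ch"),
  start_time = c("start_time", "template_start"),
  length = c("sequence_length_template", "sequence_length", "seqlen"),
  mean_quality = c("mean_qscore_template", "mean_qscore", "qscore"),
  barcode = c("barcode_arrangement", "barcode", "barcode_id")
)

#' Build a read table from basecaller sequencing-summary files
#'
#' Parses the per-read TSV emitted by the basecaller (plain or
#' gzip-compressed), which allows QC without touching the reads
#' themselves. Column names are matched against an alias list covering
#' basecaller dialects (the albacore names are the defaults). Mean quality
#' is taken verbatim from the qscore column — no per-base qualities exist
#' in this format — and start times are normalized to seconds since the
#' earliest read across all input files.
#'
#' @param paths one or more summary TSV files.
#' @param barcoded if `TRUE`, require and carry the barcode column.
#' @param label dataset name.
#' @return a [read_tbl()] with `source_kind = "summary"`.
#' @export
read_summary <- function(paths, barcoded = FALSE, label = "reads") {
  if (length(paths) == 0) stop("no input files given", call. = FALSE)
  parts <- lapply(paths, function(path) {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    found <- names(df)
    pick <- function(key) {
      hit <- intersect(summary_column_aliases[[key]], found)
      if (length(hit)) hit[1] else NA_character_
    }
    required <- c("read_id", "channel", "start_time", "length", "mean_quality")
    if (barcoded) required <- c(required, "barcode")
    cols <- vapply(required, pick, character(1))
    if (anyNA(cols)) {
      missing <- required[is.na(cols)]
      stop("summary file ", path, " lacks required column(s) ",
           paste(missing, collapse = ", "),
           " (accepted names: ",
           paste(unlist(summary_column_aliases[missing]), collapse = ", "),
           "); found: ", paste(found, collapse = ", "), call. = FALSE)
    }
    numeric_cols <- c("channel", "start_time", "length", "mean_quality")
    for (key in numeric_cols) {
      v <- df[[cols[[key]]]]
      if (!is.numeric(v)) {
        parsed <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(parsed) & !is.na(v))
        if (length(bad)) {
          stop("non-numeric value in column '", cols[[key]], "' of ", path,
               " at line ", bad[1] + 1L, call. = FALSE)
        }
        df[[cols[[key]]]] <- parsed
      }
    }
    out <- tibble::tibble(
      read_id = as.character(df[[cols[["read_id"]]]]),
      length = df[[cols[["length"]]]],
      mean_quality = df[[cols[["mean_quality"]]]],
      start_time = df[[cols[["start_time"]]]],
      channel = df[[cols[["channel"]]]]
    )
    bc <- pick("barcode")
    if (!is.na(bc)) out$barcode <- as.character(df[[bc]])
    out
  })
  df <- dplyr::bind_rows(parts)
  df$start_time <- df$start_time - min(df$start_time)
  read_tbl(df, label = label, source_kind = "summary")
}

#' Split a barcoded read table into one table per barcode
#'
#' Partitions records by barcode label (unlabelled reads are grouped under
#' `"unclassified"`), preserving record order within each group, so plots
#' and statistics can be produced per barcode.
#'
#' @param table a `read_tbl` with a populated `barcode` field.
#' @return a named list of `read_tbl`, one per barcode.
#' @export
split_by_barcode <- function(table) {
  if (all(is.na(table$barcode))) {
    stop("read table has no barcode labels; was the input barcoded?",
         call. = FALSE)
  }
  bc <- table$barcode
  bc[is.na(bc) | bc == ""] <- "unclassified"
  out <- lapply(split(seq_len(nrow(table)), bc), function(idx) {
    part <- keep_rows(table, idx)
    read_label(part) <- paste0(read_label(table), ":", bc[idx[1]])
    part
  })
  out
}
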