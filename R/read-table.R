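#' Per-read feature tables
#'
#' A `read_tbl` is a tibble with one row per sequenced read and a fixed
#' column schema, plus two attributes: `label` (dataset name) and
#' `source_kind` (one of `"fastq"`, `"fasta"`, `"bam"`, `"summary"`).
#' Optional per-read features that a source cannot provide (e.g. quality
#' for FASTA input) are `NA`, never sentinel numbers; statistics downstream
#' skip `NA`s and report the number of reads actually used.
#'
#' Columns:
#' \describe{
#'   \item{read_id}{character read identifier (duplicates permitted)}
#'   \item{length}{read length in bases (>= 0)}
#'   \item{mean_quality}{probability-averaged Phred quality of the read}
#'   \item{start_time}{seconds since the first read of the dataset started}
#'   \item{channel}{integer flow-cell channel id}
#'   \item{barcode}{barcode label for multiplexed runs}
#'   \item{aligned_length}{query bases placed in the alignment
#'     (CIGAR M/I/=/X); always <= length}
#'   \item{percent_identity}{100 * (1 - NM / alignment columns), in [0, 100]}
#'   \item{mapping_quality}{integer Phred-scaled mapping quality}
#'   \item{gc_fraction}{G+C over unambiguous A/C/G/T bases, in [0, 1]}
#' }
#'
#' @param df data frame with at least a `read_id` and `length` column;
#'   missing schema columns are filled with `NA`.
#' @param label dataset name.
#' @param source_kind provenance of the records.
#' @return a `read_tbl` tibble.
#' @export
#' @examples
#' read_tbl(data.frame(read_id = c("a", "b"), length = c(10L, 20L)),
#'          label = "demo", source_kind = "fastq")
read_tbl <- function(df, label = "reads",
                     source_kind = c("fastq", "fasta", "bam", "summary")) {
  source_kind <- match.arg(source_kind)
  df <- tibble::as_tibble(df)
  for (col in setdiff(names(read_tbl_schema), names(df))) {
    df[[col]] <- read_tbl_schema[[col]](nrow(df))
  }
  df <- df[names(read_tbl_schema)]
  df$read_id <- as.character(df$read_id)
  df$length <- as.integer(df$length)
  df$channel <- as.integer(df$channel)
  df$aligned_length <- as.integer(df$aligned_length)
  df$mapping_quality <- as.integer(df$mapping_quality)
  df$barcode <- as.character(df$barcode)
  for (col in c("mean_quality", "start_time", "percent_identity", "gc_fraction")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  out <- validate_read_tbl(new_read_tbl(df, label, source_kind))
  out
}

read_tbl_schema <- list(
  read_id = function(n) character(n),
  length = function(n) integer(n),
  mean_quality = function(n) rep(NA_real_, n),
  start_time = function(n) rep(NA_real_, n),
  channel = function(n) rep(NA_integer_, n),
  barcode = function(n) rep(NA_character_, n),
  aligned_length = function(n) rep(NA_integer_, n),
  percent_identity = function(n) rep(NA_real_, n),
  mapping_quality = function(n) rep(NA_integer_, n),
  gc_fraction = function(n) rep(NA_real_, n)
)

new_read_tbl <- function(df, label, source_kind) {
  structure(df,
    class = c("read_tbl", class(tibble::tibble())),
    label = label, source_kind = source_kind
  )
}

validate_read_tbl <- function(x) {
  stopifnot(is.data.frame(x))
  bad <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      ids <- utils::head(x$read_id[which(cond)], 3)
      stop(msg, " (e.g. read ", paste(ids, collapse = ", "), ")", call. = FALSE)
    }
  }
  bad(x$length < 0, "read length must be >= 0")
  bad(x$aligned_length < 0, "aligned_length must be >= 0")
  bad(x$aligned_length > x$length, "aligned_length must not exceed read length")
  bad(x$percent_identity < 0 | x$percent_identity > 100,
      "percent_identity must lie in [0, 100]")
  bad(x$gc_fraction < 0 | x$gc_fraction > 1, "gc_fraction must lie in [0, 1]")
  bad(x$start_time < 0, "start_time must be >= 0")
  x
}

#' @export
print.read_tbl <- function(x, ...) {
  cat(sprintf("# read_tbl '%s' (%s): %d reads, fields: %s\n",
              read_label(x), source_kind(x), nrow(x),
              paste(populated_fields(x), collapse = ", ")))
  NextMethod()
}

#' Dataset label and provenance of a read table
#'
#' @param x a `read_tbl`.
#' @return `read_label()`: the dataset name; `source_kind()`: the input
#'   format the table was built from.
#' @export
read_label <- function(x) attr(x, "label", exact = TRUE) %||% "reads"

#' @rdname read_label
#' @export
source_kind <- function(x) attr(x, "source_kind", exact = TRUE) %||% "fastq"

#' @rdname read_label
#' @param value new label.
#' @export
`read_label<-` <- function(x, value) {
  attr(x, "label") <- value
  x
}

#' Which per-read fields carry data
#'
#' A field is populated when at least one record has a non-missing value.
#'
#' @param x a `read_tbl`.
#' @return character vector of populated column names.
#' @export
populated_fields <- function(x) {
  names(x)[vapply(x, function(col) any(!is.na(col)), logical(1))]
}

# Subsetting keeps the class and attributes (dplyr verbs strip custom
# attributes; these restore them for the operations the package uses).
#' @export
`[.read_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(read_tbl_schema))) {
    out <- new_read_tbl(tibble::as_tibble(out), read_label(x), source_kind(x))
  }
  out
}

keep_rows <- function(x, idx) {
  new_read_tbl(tibble::as_tibble(x)[idx, , drop = FALSE],
               read_label(x), source_kind(x))
}

#' Write / read the per-read TSV serialization
#'
#' One row per read, columns as in [read_tbl()], missing values as empty
#' cells. The dataset label and source kind are stored in `#`-prefixed
#' header comment lines so a table round-trips without loss.
#'
#' @param x a `read_tbl`.
#' @param path output file.
#' @return `write_read_tsv()` returns `path` invisibly; `read_read_tsv()`
#'   returns the reconstructed `read_tbl`.
#' @export
write_read_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label=%s", read_label(x)),
               sprintf("# source_kind=%s", source_kind(x))), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_read_tsv
#' @export
read_read_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- sub("^# *", "", hdr[startsWith(hdr, "#")])
  kv <- strsplit(meta, "=", fixed = TRUE)
  meta <- stats::setNames(
    vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          na.strings = "", colClasses = c(read_id = "character",
                          barcode = "character"), stringsAsFactors = FALSE)
  read_tbl(df, label = meta[["label"]] %||% "reads",
           source_kind = meta[["source_kind"]] %||% "fastq")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
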