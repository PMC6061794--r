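#' Probability-averaged Phred quality of a read
#'
#' Phred scores are log-scaled error probabilities, so the mean quality of a
#' read is computed in probability space: each per-base score q is converted
#' to its error probability 10^(-q/10), the probabilities are averaged, and
#' the mean is converted back, i.e. -10*log10(mean(10^(-q/10))). The
#' arithmetic mean of Phred values would systematically overstate accuracy.
#'
#' @param phred_scores numeric vector of per-base Phred scores (>= 0).
#' @return the read's mean quality in Phred units; always within
#'   `[min(phred_scores), max(phred_scores)]`.
#' @export
#' @examples
#' mean_read_quality(c(10, 10, 10)) # 10
#' mean_read_quality(c(10, 20))     # 12.596..., not 15
mean_read_quality <- function(phred_scores) {
  if (length(phred_scores) == 0) stop("read has no bases", call. = FALSE)
  if (any(phred_scores < 0)) stop("Phred scores must be >= 0", call. = FALSE)
  -10 * log10(mean(10^(-phred_scores / 10)))
}

#' N50 of a set of read lengths
#'
#' The largest length L such that reads of length >= L together contain at
#' least half of all sequenced bases. The returned value is always one of
#' the input lengths.
#'
#' @param lengths positive integer read lengths.
#' @return the N50 in bases.
#' @export
#' @examples
#' read_n50(c(8, 8, 4, 3, 3, 2, 2, 2)) # 8
read_n50 <- function(lengths) {
  if (length(lengths) == 0) stop("cannot compute N50 of zero reads", call. = FALSE)
  if (any(lengths <= 0) || anyNA(lengths)) {
    stop("lengths must be positive and non-missing", call. = FALSE)
  }
  sorted <- sort(lengths, decreasing = TRUE)
  sorted[which(cumsum(as.numeric(sorted)) >= sum(as.numeric(sorted)) / 2)[1]]
}

# CIGAR helpers ---------------------------------------------------------

cigar_ops <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  purrr::map2(lens, ops, function(l, o) stats::setNames(as.numeric(l), o))
}

sum_ops <- function(cigar, which_ops) {
  vapply(cigar_ops(cigar), function(x) sum(x[names(x) %in% which_ops]),
         numeric(1))
}

#' Query bases consumed by the aligned part of a CIGAR string
#'
#' Sums the lengths of M/I/=/X operations (soft clips excluded), i.e. the
#' bases of the read actually placed in the alignment. Because it is
#' measured on the query, it never exceeds the read length, so aligned and
#' effective length can be compared on one axis.
#'
#' @param cigar character vector of CIGAR strings.
#' @return numeric vector of aligned query lengths.
#' @export
aligned_query_length <- function(cigar) {
  sum_ops(cigar, c("M", "I", "=", "X"))
}

#' Percent identity from CIGAR and edit distance
#'
#' `100 * (1 - NM / columns)` where `columns` is the number of alignment
#' columns, i.e. the summed lengths of M/=/X/I/D operations. Including
#' indel columns in the denominator counts every error the aligner reports
#' (in NM) exactly once. The result is clipped to `[0, 100]`.
#'
#' @param cigar character vector of CIGAR strings of mapped alignments.
#' @param edit_distance integer vector, the NM tag values (>= 0).
#' @return percent identity values in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("100M", 10)       # 90
#' percent_identity("50M10I40M", 12)  # 88: 100 columns
percent_identity <- function(cigar, edit_distance) {
  if (length(cigar) != length(edit_distance)) {
    stop("cigar and edit_distance must have equal length", call. = FALSE)
  }
  if (any(edit_distance < 0, na.rm = TRUE)) {
    stop("edit distance (NM) must be >= 0", call. = FALSE)
  }
  columns <- sum_ops(cigar, c("M", "=", "X", "I", "D"))
  if (any(columns == 0 & !is.na(edit_distance))) {
    stop("alignment with zero aligned columns", call. = FALSE)
  }
  pmin(100, pmax(0, 100 * (1 - edit_distance / columns)))
}

# Summary statistics ----------------------------------------------------

#' Summary statistics for a read table
#'
#' Aggregates a [read_tbl()] into the block of numbers a run-QC report
#' prints: read count, yield, length mean/median and N50, quality mean and
#' median, counts of reads at or above each quality tier, and the top-k
#' longest reads. Statistics over a field that the input source does not
#' populate are `NA`, and `n_with_quality` records how many reads entered
#' the quality statistics.
#'
#' @param table a `read_tbl` with at least one read.
#' @param quality_tiers Phred thresholds for the cumulative
#'   reads-above-quality counts.
#' @param top_n how many longest reads to report.
#' @return an object of class `read_summary`; see [tidy.read_summary()].
#' @export
summarize_reads <- function(table, quality_tiers = c(5, 7, 10, 12, 15),
                            top_n = 5) {
  if (nrow(table) == 0) stop("cannot summarize an empty read table", call. = FALSE)
  q <- table$mean_quality[!is.na(table$mean_quality)]
  tiers <- stats::setNames(
    vapply(quality_tiers, function(t) sum(q >= t), integer(1)),
    paste0("Q", quality_tiers)
  )
  ord <- order(table$length, decreasing = TRUE)
  top <- utils::head(ord, top_n)
  structure(list(
    label = read_label(table),
    source_kind = source_kind(table),
    n_reads = nrow(table),
    total_bases = sum(as.numeric(table$length)),
    mean_length = mean(table$length),
    median_length = stats::median(table$length),
    n50 = read_n50(table$length[table$length > 0]),
    mean_quality = if (length(q)) mean(q) else NA_real_,
    median_quality = if (length(q)) stats::median(q) else NA_real_,
    n_with_quality = length(q),
    mean_percent_identity = if (any(!is.na(table$percent_identity))) {
      mean(table$percent_identity, na.rm = TRUE)
    } else NA_real_,
    reads_over_quality = tiers,
    longest_reads = tibble::tibble(read_id = table$read_id[top],
                                   length = table$length[top])
  ), class = "read_summary")
}

#' @export
print.read_summary <- function(x, ...) {
  cat(sprintf("Summary of dataset '%s' (%s input)\n", x$label, x$source_kind))
  fmt <- function(v) format(v, big.mark = ",", digits = 6)
  cat(sprintf("  reads:           %s\n", fmt(x$n_reads)))
  cat(sprintf("  total bases:     %s\n", fmt(x$total_bases)))
  cat(sprintf("  mean length:     %s\n", fmt(x$mean_length)))
  cat(sprintf("  median length:   %s\n", fmt(x$median_length)))
  cat(sprintf("  length N50:      %s\n", fmt(x$n50)))
  if (!is.na(x$mean_quality)) {
    cat(sprintf("  mean quality:    %.2f (over %d reads)\n",
                x$mean_quality, x$n_with_quality))
    cat(sprintf("  median quality:  %.2f\n", x$median_quality))
    for (nm in names(x$reads_over_quality)) {
      cat(sprintf("  reads >= %-5s   %d\n", paste0(nm, ":"),
                  x$reads_over_quality[[nm]]))
    }
  }
  if (!is.na(x$mean_percent_identity)) {
    cat(sprintf("  mean identity:   %.2f%%\n", x$mean_percent_identity))
  }
  cat("  longest reads:\n")
  for (i in seq_len(nrow(x$longest_reads))) {
    cat(sprintf("    %s (%d bases)\n", x$longest_reads$read_id[i],
                x$longest_reads$length[i]))
  }
  invisible(x)
}

#' Tidy a read summary into a statistic/value tibble
#'
#' @param x a `read_summary` from [summarize_reads()].
#' @param ... unused.
#' @return `tidy()`: a two-column tibble (`statistic`, `value`), one row per
#'   scalar statistic including the per-tier counts. `glance()`: a one-row
#'   tibble of the headline statistics.
#' @export
tidy.read_summary <- function(x, ...) {
  scalars <- c(
    n_reads = x$n_reads, total_bases = x$total_bases,
    mean_length = x$mean_length, median_length = x$median_length,
    n50 = x$n50, mean_quality = x$mean_quality,
    median_quality = x$median_quality, n_with_quality = x$n_with_quality,
    mean_percent_identity = x$mean_percent_identity
  )
  tiers <- stats::setNames(as.numeric(x$reads_over_quality),
                           paste0("reads_over_", names(x$reads_over_quality)))
  tibble::tibble(statistic = c(names(scalars), names(tiers)),
                 value = c(unname(scalars), unname(tiers)))
}

#' @rdname tidy.read_summary
#' @export
glance.read_summary <- function(x, ...) {
  tibble::tibble(label = x$label, n_reads = x$n_reads,
                 total_bases = x$total_bases, n50 = x$n50,
                 mean_length = x$mean_length, median_length = x$median_length,
                 mean_quality = x$mean_quality,
                 median_quality = x$median_quality)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

# Time-resolved views ---------------------------------------------------

#' Cumulative sequencing yield over time
#'
#' Orders reads by start time and accumulates bases, giving the yield curve
#' whose flattening shows a flow cell wearing out.
#'
#' @param table a `read_tbl` whose records carry `start_time`.
#' @return a `plot_data` object of kind `cumulative_yield` whose payload is
#'   a tibble with `hours` and `cumulative_bases`, both monotone
#'   non-decreasing; the final value equals the dataset's total bases.
#' @export
cumulative_yield <- function(table) {
  if (all(is.na(table$start_time))) {
    stop("cumulative yield needs reads with start times", call. = FALSE)
  }
  ok <- !is.na(table$start_time)
  ord <- order(table$start_time[ok])
  hours <- table$start_time[ok][ord] / 3600
  series <- tibble::tibble(
    hours = hours,
    cumulative_bases = cumsum(as.numeric(table$length[ok][ord]))
  )
  plot_data("cumulative_yield", payload = list(series = series),
            annotations = list(label = read_label(table),
                               excluded_no_time = sum(!ok)))
}

#' Bin reads into fixed time intervals
#'
#' Partitions reads into contiguous half-open bins `[0, w)`, `[w, 2w)`, ...
#' of `interval_hours` width (6 h by default) by start time, collecting the
#' requested per-read value in each bin. Used for violin plots of quality
#' or length over the run.
#'
#' @param table a `read_tbl` with `start_time` and the requested field.
#' @param field which per-read value to collect.
#' @param interval_hours bin width in hours (> 0).
#' @return a tibble with one row per bin: `bin`, `start_hours`, `end_hours`,
#'   `n`, `mean`, and a `values` list-column of the raw per-read values.
#' @export
bin_by_time <- function(table, field = c("mean_quality", "length"),
                        interval_hours = 6) {
  field <- match.arg(field)
  if (interval_hours <= 0) stop("interval_hours must be > 0", call. = FALSE)
  ok <- !is.na(table$start_time) & !is.na(table[[field]])
  if (!any(ok)) stop("no reads with both start_time and ", field, call. = FALSE)
  hours <- table$start_time[ok] / 3600
  values <- as.numeric(table[[field]][ok])
  idx <- floor(hours / interval_hours)
  bins <- 0:max(idx)
  tibble::tibble(
    bin = bins,
    start_hours = bins * interval_hours,
    end_hours = (bins + 1) * interval_hours,
    n = vapply(bins, function(b) sum(idx == b), integer(1)),
    mean = vapply(bins, function(b) {
      v <- values[idx == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    values = lapply(bins, function(b) values[idx == b])
  )
}

#' Randomly downsample a read table
#'
#' Uniform sampling without replacement; the kept records preserve their
#' input order. The same seed always selects the same reads.
#'
#' @param table a `read_tbl`.
#' @param n number of reads to keep; `n >=` table size returns the table
#'   unchanged.
#' @param seed integer seed for the sampler.
#' @return a `read_tbl` with `min(n, nrow(table))` rows.
#' @export
downsample_reads <- function(table, n, seed = 1) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n >= nrow(table)) return(table)
  keep <- local_seed(seed, sort(sample.int(nrow(table), n)))
  keep_rows(table, keep)
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Drop extreme reads before plotting
#'
#' Keeps reads with `length <= max_length` and `mean_quality >=
#' min_quality`; either bound may be omitted, in which case its test is
#' skipped. Reads without a quality value pass the quality test only when
#' no quality bound is set.
#'
#' @param table a `read_tbl`.
#' @param max_length keep reads of at most this length (optional).
#' @param min_quality keep reads of at least this mean quality (optional).
#' @return the filtered `read_tbl`.
#' @export
apply_plot_cutoffs <- function(table, max_length = NULL, min_quality = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(max_length)) keep <- keep & table$length <= max_length
  if (!is.null(min_quality)) {
    keep <- keep & !is.na(table$mean_quality) & table$mean_quality >= min_quality
  }
  keep_rows(table, keep)
}
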