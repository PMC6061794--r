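# Small in-code fixtures shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A FASTQ file written verbatim from (id, seq, qual) triplets.
write_fastq_tmp <- function(ids, seqs, quals, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  close(con)
  path
}

# gzip-compress an existing text file.
gzip_copy <- function(path) {
  out <- paste0(path, ".gz")
  con <- gzfile(out, "wt")
  writeLines(readLines(path), con)
  close(con)
  out
}

# A minimal SAM file over a 1000-base reference named "ref".
write_sam_tmp <- function(records) {
  write_lines_tmp(c("@HD\tVN:1.6\tSO:unsorted",
                    "@SQ\tSN:ref\tLN:1000", records), ext = ".sam")
}

sam_record <- function(qname, flag, cigar, seq, mapq = 60, nm = NULL,
                       pos = 1) {
  fields <- c(qname, flag, if (bitwAnd(flag, 4L) == 4L) "*" else "ref",
              pos, mapq, cigar, "*", 0, 0, seq,
              strrep("I", nchar(seq)))
  if (!is.null(nm)) fields <- c(fields, paste0("NM:i:", nm))
  paste(fields, collapse = "\t")
}

# Direct probability-space arithmetic, independent of the implementation.
oracle_mean_quality <- function(q) -10 * log10(sum(10^(-q / 10)) / length(q))

# Sort/cumulative-sum N50 oracle.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))
  s[which(cs >= sum(as.numeric(s)) / 2)[1]]
}

random_cigar <- function() {
  n_ops <- sample(1:5, 1)
  ops <- sample(c("M", "I", "D", "=", "X"), n_ops, replace = TRUE)
  if (!any(ops %in% c("M", "=", "X"))) ops[1] <- "M"
  lens <- sample(1:200, n_ops, replace = TRUE)
  core <- paste0(lens, ops, collapse = "")
  pre <- if (stats::runif(1) < 0.3) paste0(sample(1:50, 1), "S") else ""
  post <- if (stats::runif(1) < 0.3) paste0(sample(1:50, 1), "S") else ""
  paste0(pre, core, post)
}

trapezoid_2d <- function(x, y, z) {
  col_int <- apply(z, 2, function(col) {
    sum(diff(x) * (col[-1] + col[-length(col)]) / 2)
  })
  sum(diff(y) * (col_int[-1] + col_int[-length(col_int)]) / 2)
}
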