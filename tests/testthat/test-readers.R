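test_that("read_fastq computes length, quality and GC per record", {
  path <- write_fastq_tmp("r1", "ACGT", "IIII") # 'I' = Phred 40
  t <- read_fastq(path)
  expect_identical(t$length, 4L)
  expect_equal(t$mean_quality, 40)
  expect_equal(t$gc_fraction, 0.5)
  expect_identical(source_kind(t), "fastq")
})

test_that("read_fastq concatenates multiple files in path order", {
  f1 <- write_fastq_tmp(paste0("a", 1:3), rep("ACGT", 3), rep("IIII", 3))
  f2 <- write_fastq_tmp(paste0("b", 1:2), rep("GGCC", 2), rep("$$$$", 2))
  t <- read_fastq(c(f1, f2))
  expect_identical(t$read_id, c("a1", "a2", "a3", "b1", "b2"))
})

test_that("read_fastq reports malformed records by id and tolerates empty files", {
  bad <- write_fastq_tmp(c("ok", "broken"), c("ACGT", "ACGT"),
                         c("IIII", "III"))
  expect_error(read_fastq(bad), "broken")
  empty <- write_lines_tmp(character(0), ext = ".fastq")
  t <- read_fastq(empty)
  expect_identical(nrow(t), 0L)
  trunc <- write_lines_tmp(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"),
                           ext = ".fastq")
  expect_error(read_fastq(trunc), "record 2")
  expect_error(read_fastq(character(0)), "no input")
})

test_that("gzip-compressed FASTQ gives an identical table", {
  truth <- make_fastq(fq <- tempfile(fileext = ".fastq"), 200,
                      length_dist = length_lognormal(5, 0.7), seed = 11)
  plain <- read_fastq(fq)
  zipped <- read_fastq(gzip_copy(fq))
  expect_equal(as.data.frame(plain), as.data.frame(zipped))
  expect_identical(nrow(plain), 200L)
})

test_that("read_fasta handles wrapped records and ambiguity codes", {
  fa <- write_lines_tmp(c(">r1 some description", "AC", "GT",
                          ">r2", "NNNN",
                          ">r3", "ACGN"), ext = ".fa")
  t <- read_fasta(fa)
  expect_identical(t$read_id, c("r1", "r2", "r3"))
  expect_identical(t$length, c(4L, 4L, 4L))
  expect_equal(t$gc_fraction, c(0.5, NA, 2 / 3)) # r3 "ACGN": C,G of A,C,G
  expect_true(all(is.na(t$mean_quality)))
  expect_identical(source_kind(t), "fasta")
  expect_error(read_fasta(character(0)), "no input")
})

test_that("read_fasta warns on non-IUPAC characters but counts their length", {
  fa <- write_lines_tmp(c(">odd", "ACGT!!"), ext = ".fa")
  expect_warning(t <- read_fasta(fa), "non-IUPAC")
  expect_identical(t$length, 6L)
  expect_equal(t$gc_fraction, 0.5)
})

test_that("read_alignments keeps one record per primary alignment", {
  sam <- write_sam_tmp(c(
    sam_record("perfect", 0, "100M", strrep("A", 100), nm = 0),
    sam_record("multi", 0, "50M", strrep("C", 50), nm = 5),
    sam_record("multi", 2048, "10M40S", strrep("C", 50), nm = 0),
    sam_record("multi", 256, "50M", strrep("C", 50), nm = 1),
    sam_record("lost", 4, "*", strrep("G", 500))
  ))
  t <- read_alignments(sam)
  expect_identical(nrow(t), 3L)
  p <- t[t$read_id == "perfect", ]
  expect_identical(p$aligned_length, 100L)
  expect_equal(p$percent_identity, 100)
  expect_identical(p$mapping_quality, 60L)
  expect_identical(sum(t$read_id == "multi"), 1L)
  u <- t[t$read_id == "lost", ]
  expect_identical(u$length, 500L)
  expect_true(is.na(u$aligned_length) && is.na(u$percent_identity) &&
              is.na(u$mapping_quality))
})

test_that("read_alignments soft clips count toward length, not aligned length", {
  sam <- write_sam_tmp(sam_record("clipped", 0, "20S60M20S",
                                  strrep("A", 100), nm = 6))
  t <- read_alignments(sam)
  expect_identical(t$length, 100L)
  expect_identical(t$aligned_length, 60L)
  expect_equal(t$percent_identity, 90)
})

test_that("read_alignments warns when NM is missing and errors without CIGAR", {
  sam <- write_sam_tmp(sam_record("untagged", 0, "80M", strrep("A", 80)))
  expect_warning(t <- read_alignments(sam), "NM")
  expect_true(is.na(t$percent_identity))
  expect_identical(t$aligned_length, 80L)
  # a mapped record lacking a CIGAR is demoted to unmapped by htslib on
  # conversion; it must come back as a length-only record, never with
  # alignment fields silently guessed
  bad <- write_sam_tmp(sam_record("nocigar", 0, "*", strrep("A", 80), nm = 0))
  t2 <- suppressWarnings(read_alignments(bad))
  expect_identical(t2$length, 80L)
  expect_true(is.na(t2$aligned_length) && is.na(t2$percent_identity))
})

test_that("read_summary takes qscore verbatim and normalizes start times", {
  tsv <- write_lines_tmp(c(
    "read_id\tchannel\tstart_time\tsequence_length_template\tmean_qscore_template",
    "read1\t5\t100\t4000\t11.5",
    "read2\t300\t40\t2000\t8.25"
  ), ext = ".tsv")
  t <- read_summary(tsv)
  expect_equal(t$mean_quality, c(11.5, 8.25))
  expect_equal(t$start_time, c(60, 0))
  expect_identical(t$channel, c(5L, 300L))
  expect_identical(t$length, c(4000L, 2000L))
  expect_identical(source_kind(t), "summary")
})

test_that("read_summary errors list missing columns and bad cells", {
  tsv <- write_lines_tmp(c("read_id\tchannel\tstart_time",
                           "r\t1\t0"), ext = ".tsv")
  expect_error(read_summary(tsv), "sequence_length_template")
  bad <- write_lines_tmp(c(
    "read_id\tchannel\tstart_time\tsequence_length_template\tmean_qscore_template",
    "r1\t1\t0\t100\t10",
    "r2\t1\toops\t100\t10"
  ), ext = ".tsv")
  expect_error(read_summary(bad), "line 3")
})

test_that("read_summary carries barcodes and split_by_barcode partitions", {
  tsv <- write_lines_tmp(c(
    "read_id\tchannel\tstart_time\tsequence_length_template\tmean_qscore_template\tbarcode_arrangement",
    sprintf("r%d\t1\t%d\t100\t10\t%s", 1:8,
            seq(0, 70, 10), c(rep("bc01", 5), rep("bc02", 3)))
  ), ext = ".tsv")
  t <- read_summary(tsv, barcoded = TRUE)
  parts <- split_by_barcode(t)
  expect_setequal(names(parts), c("bc01", "bc02"))
  expect_identical(nrow(parts$bc01), 5L)
  expect_identical(nrow(parts$bc02), 3L)

  one <- split_by_barcode(parts$bc01)
  expect_identical(length(one), 1L)

  expect_error(split_by_barcode(read_fastq(
    write_fastq_tmp("x", "ACGT", "IIII"))), "barcode")
})

test_that("barcode partition sizes always sum to the input size", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    bcs <- sample(c("bc01", "bc02", "bc03", "unclassified"), n, replace = TRUE)
    t <- read_tbl(tibble::tibble(read_id = paste0("r", 1:n),
                                 length = sample(100:1000, n, replace = TRUE),
                                 barcode = bcs))
    parts <- split_by_barcode(t)
    expect_identical(sum(vapply(parts, nrow, integer(1))), n)
    expect_setequal(names(parts), unique(bcs))
  }
})
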