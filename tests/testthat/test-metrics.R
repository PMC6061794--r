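test_that("mean read quality averages in probability space", {
  expect_equal(mean_read_quality(c(10, 10, 10)), 10)
  expect_equal(mean_read_quality(c(10, 20)), -10 * log10((0.1 + 0.01) / 2))
  expect_error(mean_read_quality(numeric(0)), "no bases")
  expect_error(mean_read_quality(c(10, -1)), ">= 0")
})

test_that("mean quality is bounded by the extreme per-base scores", {
  set.seed(101)
  for (i in 1:50) {
    q <- sample(0:45, sample(1:300, 1), replace = TRUE)
    m <- mean_read_quality(q)
    expect_gte(m, min(q))
    expect_lte(m, max(q))
    expect_equal(m, oracle_mean_quality(q))
  }
})

test_that("N50 follows the cumulative-half convention and is an input element", {
  expect_identical(read_n50(c(8, 8, 4, 3, 3, 2, 2, 2)), 8)
  expect_identical(read_n50(5), 5)
  expect_identical(read_n50(c(1, 1, 1, 1)), 1)
  expect_error(read_n50(numeric(0)), "zero reads")
  expect_error(read_n50(c(5, 0)), "positive")
})

test_that("N50 matches the sort/cumsum oracle and ignores input order", {
  set.seed(7)
  for (i in 1:50) {
    lens <- sample(1:50000, sample(1:500, 1), replace = TRUE)
    v <- read_n50(lens)
    expect_identical(v, oracle_n50(lens))
    expect_identical(read_n50(sample(lens)), v)
    expect_true(v %in% lens)
  }
})

test_that("percent identity divides NM by all aligned columns", {
  expect_equal(percent_identity("100M", 0), 100)
  expect_equal(percent_identity("100M", 10), 90)
  expect_equal(percent_identity("50M10I40M", 12), 88)
  # soft clips are not alignment columns; deletions are
  expect_equal(percent_identity("10S40M10D50M", 10), 90)
  expect_error(percent_identity("10S", 0), "zero aligned columns")
  expect_error(percent_identity("100M", -1), ">= 0")
})

test_that("percent identity is monotone non-increasing in edit distance", {
  set.seed(13)
  for (i in 1:20) {
    cig <- random_cigar()
    vals <- percent_identity(rep(cig, 21), 0:20)
    expect_true(all(diff(vals) <= 0))
    expect_true(all(vals >= 0 & vals <= 100))
  }
})

test_that("summarize_reads aggregates lengths, qualities and tiers", {
  t <- read_tbl(tibble::tibble(read_id = c("a", "b", "c"),
                               length = c(100L, 200L, 300L),
                               mean_quality = c(6, 12, NA)))
  s <- summarize_reads(t, quality_tiers = c(5, 10))
  expect_identical(s$n_reads, 3L)
  expect_equal(s$total_bases, 600)
  expect_equal(s$mean_length, 200)
  expect_equal(s$median_length, 200)
  expect_identical(s$reads_over_quality, c(Q5 = 2L, Q10 = 1L))
  expect_identical(s$n_with_quality, 2L)
  expect_identical(s$longest_reads$read_id[1], "c")
  expect_error(summarize_reads(t[0, ]), "empty")
})

test_that("tier counts are non-increasing and N50 cross-checks", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    t <- read_tbl(tibble::tibble(
      read_id = paste0("r", 1:n),
      length = sample(1:20000, n, replace = TRUE),
      mean_quality = stats::runif(n, 2, 20)
    ))
    s <- summarize_reads(t)
    expect_true(all(diff(s$reads_over_quality) <= 0))
    expect_identical(s$n50, oracle_n50(t$length))
    expect_equal(s$total_bases, sum(t$length))
  }
})

test_that("tidy and glance expose the summary as tibbles", {
  t <- read_tbl(tibble::tibble(read_id = c("a", "b"), length = c(10L, 30L),
                               mean_quality = c(8, 12)))
  s <- summarize_reads(t)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_identical(names(td), c("statistic", "value"))
  expect_equal(td$value[td$statistic == "total_bases"], 40)
  g <- glance(s)
  expect_identical(nrow(g), 1L)
  expect_equal(g$n50, 30)
})

test_that("cumulative yield is a running sum, order-invariant, ending at total bases", {
  t <- read_tbl(tibble::tibble(read_id = c("a", "b", "c"),
                               length = c(100L, 200L, 300L),
                               start_time = c(0, 3600, 7200)))
  y <- cumulative_yield(t)
  expect_equal(y$payload$series$cumulative_bases, c(100, 300, 600))
  expect_equal(y$payload$series$hours, c(0, 1, 2))
  shuffled <- keep_rows(t, c(3, 1, 2))
  expect_equal(cumulative_yield(shuffled)$payload$series, y$payload$series)
  one <- cumulative_yield(t[1, ])
  expect_equal(one$payload$series$cumulative_bases, 100)
  expect_error(cumulative_yield(read_tbl(tibble::tibble(read_id = "a",
                                                        length = 1L))),
               "start time")
})

test_that("time bins are half-open, contiguous, and partition the reads", {
  t <- read_tbl(tibble::tibble(
    read_id = paste0("r", 1:3),
    length = c(10L, 20L, 30L),
    mean_quality = c(9, 9, 9),
    start_time = c(0, 5.9, 6.1) * 3600
  ))
  b <- bin_by_time(t, "mean_quality")
  expect_identical(b$n, c(2L, 1L))
  expect_equal(b$start_hours, c(0, 6))
  expect_true(all(b$end_hours - b$start_hours == 6))
  expect_identical(sum(b$n), 3L)
  expect_true(all(abs(b$mean - 9) < 1e-12))
  expect_error(bin_by_time(t, "mean_quality", interval_hours = 0), "> 0")
})

test_that("time bin partition holds on random runs", {
  truth <- make_summary(tsv <- tempfile(fileext = ".tsv"), 500,
                        run_hours = 30, seed = 19)
  t <- read_summary(tsv)
  b <- bin_by_time(t, "length", interval_hours = 4)
  expect_identical(sum(b$n), 500L)
  expect_identical(sum(lengths(b$values)), 500L)
})

test_that("downsampling is uniform, order-preserving and seed-deterministic", {
  t <- read_tbl(tibble::tibble(read_id = paste0("r", 1:100),
                               length = rep(10L, 100)))
  expect_identical(nrow(downsample_reads(t, 100)), 100L)
  expect_identical(nrow(downsample_reads(t, 500)), 100L)
  empty <- downsample_reads(t, 0)
  expect_identical(nrow(empty), 0L)
  expect_identical(read_label(empty), read_label(t))
  a <- downsample_reads(t, 20, seed = 42)
  b <- downsample_reads(t, 20, seed = 42)
  expect_identical(a$read_id, b$read_id)
  # order preserved: kept ids appear in input order
  expect_identical(a$read_id, t$read_id[t$read_id %in% a$read_id])
  expect_error(downsample_reads(t, -1), ">= 0")
})

test_that("plot cutoffs match brute-force enumeration", {
  set.seed(31)
  n <- 500L
  t <- read_tbl(tibble::tibble(
    read_id = paste0("r", 1:n),
    length = sample(1:5000, n, replace = TRUE),
    mean_quality = ifelse(stats::runif(n) < 0.1, NA, stats::runif(n, 2, 20))
  ))
  expect_identical(nrow(apply_plot_cutoffs(t)), n)
  kept <- apply_plot_cutoffs(t, max_length = 2000, min_quality = 8)
  brute <- t$length <= 2000 & !is.na(t$mean_quality) & t$mean_quality >= 8
  expect_identical(kept$read_id, t$read_id[brute])
  # reads without quality pass when no quality bound is set
  only_len <- apply_plot_cutoffs(t, max_length = 2000)
  expect_identical(only_len$read_id, t$read_id[t$length <= 2000])
})

test_that("example cutoff keeps two of three reads", {
  t <- read_tbl(tibble::tibble(read_id = c("a", "b", "c"),
                               length = c(10L, 20L, 30L)))
  expect_identical(nrow(apply_plot_cutoffs(t, max_length = 20)), 2L)
})
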