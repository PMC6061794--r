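demo_table <- function(n = 200, seed = 55) {
  set.seed(seed)
  read_tbl(tibble::tibble(
    read_id = paste0("r", 1:n),
    length = sample(50:20000, n, replace = TRUE),
    mean_quality = stats::runif(n, 3, 18),
    aligned_length = NA_integer_,
    percent_identity = NA_real_
  ), label = "demo")
}

test_that("length histogram bins linearly and conserves counts", {
  t <- read_tbl(tibble::tibble(read_id = c("a", "b", "c"),
                               length = c(10L, 10L, 1000L)))
  h <- length_histogram(t, bins = 2)
  expect_equal(h$payload$counts, c(2, 1))
  expect_identical(length(h$payload$breaks), 3L)
  expect_error(length_histogram(t, bins = 0), ">= 1")

  big <- demo_table()
  hb <- length_histogram(big, bins = 40, mark_n50 = TRUE)
  expect_equal(sum(hb$payload$counts), nrow(big))
  expect_identical(hb$annotations$n50_marker, oracle_n50(big$length))
})

test_that("log-scale bin assignment matches the per-read floor formula", {
  t <- demo_table(300, seed = 9)
  bins <- 25
  h <- length_histogram(t, bins = bins, log_scale = TRUE)
  expect_equal(sum(h$payload$counts), nrow(t))
  lx <- log10(t$length)
  width <- (max(lx) - min(lx)) / bins
  idx <- pmin(floor((lx - min(lx)) / width), bins - 1)
  expect_equal(h$payload$counts, as.vector(table(factor(idx, 0:(bins - 1)))))
})

test_that("hexbin payload conserves reads and collapses identical points", {
  t10 <- read_tbl(tibble::tibble(read_id = paste0("r", 1:10),
                                 length = rep(500L, 10),
                                 mean_quality = rep(10, 10)))
  hx <- bivariate(t10, style = "hexbin")
  expect_identical(nrow(hx$payload$cells), 1L)
  expect_equal(hx$payload$cells$count, 10)

  t <- demo_table()
  hx2 <- bivariate(t, style = "hexbin", log_x = TRUE)
  expect_equal(sum(hx2$payload$cells$count), nrow(t))
  expect_equal(sum(hx2$payload$marginal_x$counts), nrow(t))
})

test_that("reads missing a field are excluded and tallied", {
  t <- demo_table(100)
  t$mean_quality[1:7] <- NA
  hx <- bivariate(t, style = "hexbin")
  expect_equal(sum(hx$payload$cells$count), 93)
  expect_identical(hx$annotations$excluded_missing, 7L)
  tiny <- demo_table(5)
  tiny$mean_quality <- NA_real_
  expect_error(bivariate(tiny), "at least 2")
  expect_error(bivariate(t, x_field = "nope"), "unknown field")
})

test_that("KDE density integrates to one on its grid", {
  t <- demo_table(400, seed = 3)
  kd <- bivariate(t, style = "kde", log_x = TRUE)
  z <- kd$payload$density
  integral <- trapezoid_2d(kd$payload$grid_x, kd$payload$grid_y, z)
  expect_gt(integral, 0.99)
  expect_lt(integral, 1.01)
  expect_true(kd$annotations$bandwidth_x > 0)
})

test_that("aligned-vs-effective points never exceed the diagonal", {
  make_alignments(sam <- tempfile(fileext = ".sam"), 150,
                  partial_fraction = 0.5, seed = 21)
  t <- read_alignments(sam)
  p <- aligned_vs_effective(t)
  pts <- p$payload$points
  expect_true(all(pts$aligned_length <= pts$length))
  expect_true(any(pts$aligned_length < pts$length)) # partial alignments exist
  fully <- make_alignments(sam2 <- tempfile(fileext = ".sam"), 30,
                           identity = 1, partial_fraction = 0, seed = 22)
  t2 <- read_alignments(sam2)
  p2 <- aligned_vs_effective(t2)
  expect_true(all(p2$payload$points$aligned_length ==
                  p2$payload$points$length))
  expect_error(aligned_vs_effective(demo_table(5)), "no aligned reads")
})

test_that("comparisons group per label and cross-check N50", {
  a <- demo_table(150, seed = 1)
  b <- demo_table(90, seed = 2)
  read_label(b) <- "other"
  cmp <- compare_reads(list(a, b))
  counts <- table(cmp$groups$label[cmp$groups$metric == "length"])
  expect_identical(as.integer(counts[c("demo", "other")]), c(150L, 90L))
  expect_identical(cmp$summary$n50,
                   c(oracle_n50(a$length), oracle_n50(b$length)))
  expect_error(compare_reads(list(a)), "at least 2")
  expect_error(compare_reads(list(a, a)), "duplicate")
})

test_that("identical datasets under two labels summarize identically", {
  a <- demo_table(80, seed = 12)
  b <- a
  read_label(b) <- "twin"
  cmp <- compare_reads(list(a, b))
  s <- cmp$summary
  expect_equal(s[1, -1], s[2, -1], ignore_attr = TRUE)
  pd <- comparison_plot_data(cmp, "quality")
  expect_identical(lengths(pd$payload$groups), c(demo = 80L, twin = 80L))
})

test_that("a dataset without a field is flagged absent, not an error", {
  a <- demo_table(50, seed = 31)
  b <- read_tbl(tibble::tibble(read_id = paste0("f", 1:20),
                               length = sample(100:900, 20)),
                label = "fasta-only", source_kind = "fasta")
  cmp <- compare_reads(list(a, b))
  expect_true(any(cmp$absent$label == "fasta-only" &
                  cmp$absent$metric == "quality"))
  expect_error(comparison_plot_data(cmp, "identity"), "no dataset")
})

test_that("render writes one deterministic file per plot and format", {
  t <- demo_table(60, seed = 41)
  plots <- list(length_histogram(t, bins = 10),
                bivariate(t, style = "hexbin"))
  dir <- tempfile("plots")
  files <- render_plots(plots, dir = dir, formats = c("png", "pdf"))
  expect_identical(length(files), 4L)
  expect_true(all(file.exists(files)))
  expect_setequal(basename(files),
                  c("demo_length_histogram.png", "demo_length_histogram.pdf",
                    "demo_bivariate_hexbin.png", "demo_bivariate_hexbin.pdf"))
  # re-rendering leaves exactly the same file set
  before <- sort(list.files(dir))
  render_plots(plots, dir = dir, formats = c("png", "pdf"))
  expect_identical(sort(list.files(dir)), before)
  expect_error(render_plots(plots, dir = dir, formats = "bmp"), "unknown format")
  expect_error(render_plots(plots, dir = dir, formats = character(0)),
               "no output formats")
  expect_error(render_plots(list(), dir = dir), "no plots")
})

test_that("rendering does not mutate the plot data", {
  t <- demo_table(40, seed = 43)
  p <- length_histogram(t, bins = 8)
  snapshot <- unserialize(serialize(p, NULL))
  render_plots(list(p), dir = tempfile("p"), formats = "png")
  expect_identical(p, snapshot)
})

test_that("every autoplot method returns a ggplot", {
  make_summary(tsv <- tempfile(fileext = ".tsv"), 120, channels = 512,
               quality_drift = 0.05, seed = 6)
  st <- read_summary(tsv)
  t <- demo_table(120, seed = 44)
  plots <- list(
    length_histogram(t, log_scale = TRUE, mark_n50 = TRUE),
    cumulative_yield(st),
    activity_matrix(st),
    time_violin(st, "mean_quality"),
    bivariate(t, style = "hexbin"),
    bivariate(t, style = "kde")
  )
  for (p in plots) expect_s3_class(ggplot2::autoplot(p), "ggplot")
})

test_that("the HTML report embeds stats, plots and the per-read TSV", {
  t <- demo_table(50, seed = 45)
  s <- summarize_reads(t)
  plots <- list(length_histogram(t, bins = 10),
                bivariate(t, style = "hexbin"))
  path <- file.path(tempfile("report"), "report.html")
  dir.create(dirname(path))
  html_report(s, plots, path = path, table = t)
  html <- paste(readLines(path), collapse = "\n")
  expect_match(html, "length_histogram")
  expect_match(html, "bivariate_hexbin")
  expect_match(html, "data:image/png;base64")
  for (stat in tidy(s)$statistic) expect_match(html, stat, fixed = TRUE)
  tsv <- sub("\\.html$", "_reads.tsv", path)
  expect_true(file.exists(tsv))
  expect_identical(nrow(read_read_tsv(tsv)), nrow(t))
  # stats only, no plots, is still a valid report
  p2 <- file.path(dirname(path), "stats_only.html")
  html_report(s, list(), path = p2)
  expect_match(paste(readLines(p2), collapse = "\n"), "<table class='stats'>")
})
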