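#' Numeric plot content, independent of rendering
#'
#' Every figure the package draws is computed first as a `plot_data`
#' object: the bins, grids, series or groups that the figure shows, plus
#' annotations (dataset label, N50 marker, bandwidths, excluded-read
#' tallies). Rendering ([ggplot2::autoplot()] methods, [render_plots()])
#' consumes these objects without modifying them, so correctness is tested
#' on numbers, not pixels.
#'
#' @param kind plot kind identifier.
#' @param payload named list of numeric content specific to the kind.
#' @param annotations named list of scalar annotations.
#' @return a `plot_data` object.
#' @keywords internal
#' @export
plot_data <- function(kind, payload, annotations = list()) {
  structure(list(kind = kind, payload = payload, annotations = annotations),
            class = c(paste0("plot_data_", kind), "plot_data"))
}

#' @export
print.plot_data <- function(x, ...) {
  cat(sprintf("<plot_data: %s> payload: %s\n", x$kind,
              paste(names(x$payload), collapse = ", ")))
  if (length(x$annotations)) {
    ann <- vapply(x$annotations, function(a) paste(format(a), collapse = ","),
                  character(1))
    cat("  ", paste(names(ann), ann, sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Read-length histogram
#'
#' Uniform bins over the observed length range, optionally in log10 space
#' (zero-length reads cannot be log-transformed; they are excluded and
#' tallied). The dataset N50 can be attached as a marker annotation.
#'
#' @param table a non-empty `read_tbl`.
#' @param bins number of bins (>= 1).
#' @param log_scale bin uniformly in log10(length) instead of length.
#' @param mark_n50 annotate with the dataset N50.
#' @return a `plot_data` of kind `length_histogram` (or
#'   `log_length_histogram`): payload has `breaks` (bin edges, length
#'   `bins + 1`) and `counts` summing to the contributing reads.
#' @export
length_histogram <- function(table, bins = 50, log_scale = FALSE,
                             mark_n50 = FALSE) {
  if (bins < 1) stop("bins must be >= 1", call. = FALSE)
  if (nrow(table) == 0) stop("empty read table", call. = FALSE)
  x <- as.numeric(table$length)
  excluded_zero <- 0L
  if (log_scale) {
    excluded_zero <- sum(x <= 0)
    x <- log10(x[x > 0])
  }
  h <- bin_uniform(x, bins)
  ann <- list(label = read_label(table), log10 = log_scale,
              excluded_zero_length = excluded_zero)
  if (mark_n50) ann$n50_marker <- read_n50(table$length[table$length > 0])
  plot_data(if (log_scale) "log_length_histogram" else "length_histogram",
            payload = list(breaks = h$breaks, counts = h$counts),
            annotations = ann)
}

# Uniform binning with half-open bins, last bin closed; counts sum to
# length(x).
bin_uniform <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- pmin(findInterval(x, breaks), bins)
  list(breaks = breaks, counts = tabulate(idx, nbins = bins))
}

#' Bivariate view of two per-read features
#'
#' Relates two per-read metrics (e.g. log-length vs mean quality, quality
#' vs percent identity) either as hexagonal-bin counts or a 2D kernel
#' density estimate, each with the matching marginal summaries. Reads
#' missing either field are excluded and tallied in the annotations.
#'
#' @param table a `read_tbl`.
#' @param x_field,y_field column names among the per-read features.
#' @param style `"hexbin"` (per-cell counts + marginal histograms) or
#'   `"kde"` (density grid integrating to 1 +/- 1% + marginal densities).
#' @param log_x log10-transform the x field (zero/negative excluded and
#'   tallied).
#' @param nbins hexagon columns across the x extent, and marginal
#'   histogram bin count.
#' @return a `plot_data` of kind `bivariate_hexbin` or `bivariate_kde`.
#' @export
bivariate <- function(table, x_field = "length", y_field = "mean_quality",
                      style = c("hexbin", "kde"), log_x = FALSE, nbins = 35) {
  style <- match.arg(style)
  for (f in c(x_field, y_field)) {
    if (!f %in% names(table)) stop("unknown field '", f, "'", call. = FALSE)
  }
  x <- as.numeric(table[[x_field]])
  y <- as.numeric(table[[y_field]])
  usable <- !is.na(x) & !is.na(y)
  excluded_log <- 0L
  if (log_x) {
    excluded_log <- sum(usable & x <= 0)
    usable <- usable & x > 0
  }
  if (sum(usable) < 2) {
    stop("need at least 2 reads with both ", x_field, " and ", y_field,
         call. = FALSE)
  }
  x <- x[usable]
  y <- y[usable]
  if (log_x) x <- log10(x)
  ann <- list(label = read_label(table), x_field = x_field,
              y_field = y_field, log10_x = log_x,
              excluded_missing = sum(!usable) - excluded_log,
              excluded_nonpositive = excluded_log)
  if (style == "hexbin") {
    hx <- hex_bin(x, y, nbins)
    plot_data("bivariate_hexbin",
              payload = list(cells = hx,
                             marginal_x = bin_uniform(x, nbins),
                             marginal_y = bin_uniform(y, nbins)),
              annotations = ann)
  } else {
    bw_x <- MASS::bandwidth.nrd(x)
    bw_y <- MASS::bandwidth.nrd(y)
    if (bw_x == 0) bw_x <- 4 * 1.06 * max(stats::sd(x), 1e-3)
    if (bw_y == 0) bw_y <- 4 * 1.06 * max(stats::sd(y), 1e-3)
    # grid extended by the full bandwidth (4 kernel sds) so essentially all
    # density mass lies inside the grid and the trapezoid integral is ~1
    lims <- c(range(x) + c(-1, 1) * bw_x, range(y) + c(-1, 1) * bw_y)
    kd <- MASS::kde2d(x, y, h = c(bw_x, bw_y), n = 101, lims = lims)
    ann$bandwidth_x <- bw_x
    ann$bandwidth_y <- bw_y
    plot_data("bivariate_kde",
              payload = list(grid_x = kd$x, grid_y = kd$y, density = kd$z,
                             marginal_x = marginal_density(x),
                             marginal_y = marginal_density(y)),
              annotations = ann)
  }
}

marginal_density <- function(v) {
  d <- stats::density(v, bw = "nrd") # Scott's rule, matching the 2D kernel
  list(x = d$x, y = d$y, bw = d$bw)
}

# Hexagonal binning on a pointy-top lattice: hexagon centers form two
# interleaved rectangular grids; each point is assigned to the nearer of
# its two candidate centers, so every point lands in exactly one cell.
hex_bin <- function(x, y, nbins = 35) {
  xr <- range(x)
  yr <- range(y)
  dx <- (xr[2] - xr[1]) / nbins
  if (dx == 0) dx <- 1
  dy <- (yr[2] - yr[1]) / nbins * sqrt(3)
  if (dy == 0) dy <- 1
  # candidate A: even lattice; candidate B: odd lattice offset by half a cell
  ax_i <- round((x - xr[1]) / dx)
  ay_i <- round((y - yr[1]) / dy)
  bx_i <- round((x - xr[1]) / dx - 0.5)
  by_i <- round((y - yr[1]) / dy - 0.5)
  ax <- xr[1] + ax_i * dx
  ay <- yr[1] + ay_i * dy
  bx <- xr[1] + (bx_i + 0.5) * dx
  by <- yr[1] + (by_i + 0.5) * dy
  use_a <- ((x - ax) / dx)^2 + ((y - ay) / dy)^2 <=
           ((x - bx) / dx)^2 + ((y - by) / dy)^2
  cx <- ifelse(use_a, ax, bx)
  cy <- ifelse(use_a, ay, by)
  key <- paste(signif(cx, 12), signif(cy, 12))
  agg <- rowsum(rep(1L, length(key)), key)
  first <- !duplicated(key)
  centers <- tibble::tibble(x = cx[first], y = cy[first], key = key[first])
  centers$count <- unname(agg[match(centers$key, rownames(agg)), 1])
  centers$key <- NULL
  centers
}

#' Aligned versus effective read length
#'
#' Scatter payload of full read length against the aligned query length,
#' with the identity diagonal as annotation. Points below the diagonal are
#' reads only partially placed in the alignment; points can never lie
#' above it because aligned length is measured on the query.
#'
#' @param table a `read_tbl` from alignment input.
#' @return a `plot_data` of kind `aligned_vs_effective` whose payload
#'   tibble has `length` and `aligned_length`.
#' @export
aligned_vs_effective <- function(table) {
  ok <- !is.na(table$aligned_length)
  if (!any(ok)) stop("no aligned reads in table", call. = FALSE)
  plot_data("aligned_vs_effective",
            payload = list(points = tibble::tibble(
              length = table$length[ok],
              aligned_length = table$aligned_length[ok])),
            annotations = list(label = read_label(table),
                               diagonal = "aligned = effective",
                               excluded_unaligned = sum(!ok)))
}

#' Time-resolved violin payload
#'
#' Raw per-bin values of quality or length over the run (default 6 h
#' bins), for violin plots showing e.g. quality decay as the flow cell
#' ages. The payload keeps the raw values per bin; rendering computes the
#' violin shapes.
#'
#' @inheritParams bin_by_time
#' @return a `plot_data` of kind `time_violin` wrapping the [bin_by_time()]
#'   tibble.
#' @export
time_violin <- function(table, field = c("mean_quality", "length"),
                        interval_hours = 6) {
  field <- match.arg(field)
  bins <- bin_by_time(table, field, interval_hours)
  plot_data("time_violin",
            payload = list(bins = bins),
            annotations = list(label = read_label(table), field = field,
                               interval_hours = interval_hours))
}

#' Compare several datasets or barcodes
#'
#' Groups per-read length (optionally log10), quality and percent identity
#' across two or more labelled read tables and tabulates per-dataset
#' summary statistics (reads, yield, N50, mean/median length and quality).
#' A field absent from one dataset flags that dataset as absent for that
#' comparison rather than failing.
#'
#' @param tables list of two or more `read_tbl`s with distinct labels.
#' @param log_length also provide log10 lengths per group.
#' @return a `read_comparison`: list with `groups` (long tibble of
#'   `label`, `metric`, `value`), `summary` (one row per dataset via
#'   [glance.read_summary()]), and `absent` (label/metric pairs without
#'   data); has [tidy()] and [ggplot2::autoplot()] methods.
#' @export
compare_reads <- function(tables, log_length = TRUE) {
  if (length(tables) < 2) stop("need at least 2 datasets to compare", call. = FALSE)
  labels <- vapply(tables, read_label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate dataset labels: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  metrics <- c(length = "length", quality = "mean_quality",
               identity = "percent_identity")
  groups <- purrr::map_dfr(seq_along(tables), function(i) {
    purrr::map_dfr(names(metrics), function(m) {
      v <- tables[[i]][[metrics[[m]]]]
      v <- as.numeric(v[!is.na(v)])
      if (!length(v)) return(tibble::tibble())
      tibble::tibble(label = labels[i], metric = m, value = v)
    })
  })
  if (log_length) {
    len <- dplyr::filter(groups, .data$metric == "length", .data$value > 0)
    groups <- dplyr::bind_rows(
      groups,
      dplyr::mutate(len, metric = "log10_length", value = log10(.data$value))
    )
  }
  present <- unique(groups[c("label", "metric")])
  all_pairs <- tidyr::expand_grid(label = labels, metric = names(metrics))
  absent <- dplyr::anti_join(all_pairs, present, by = c("label", "metric"))
  summary <- purrr::map_dfr(tables, function(t) glance(summarize_reads(t)))
  structure(list(groups = groups, summary = summary, absent = absent),
            class = "read_comparison")
}

#' @export
print.read_comparison <- function(x, ...) {
  cat("Comparison of", nrow(x$summary), "datasets\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.read_comparison <- function(x, ...) x$summary

#' Grouped plot payload from a comparison
#'
#' @param comparison a [compare_reads()] result.
#' @param metric which grouped metric to extract.
#' @return a `plot_data` of kind `comparison` with one value vector per
#'   dataset label.
#' @export
comparison_plot_data <- function(comparison,
                                 metric = c("log10_length", "length",
                                            "quality", "identity")) {
  metric <- match.arg(metric)
  g <- dplyr::filter(comparison$groups, .data$metric == !!metric)
  if (nrow(g) == 0) stop("no dataset provides metric '", metric, "'", call. = FALSE)
  plot_data("comparison",
            payload = list(groups = split(g$value, g$label)),
            annotations = list(metric = metric,
                               label = "comparison"))
}
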