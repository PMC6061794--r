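#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Render plot data as ggplot2 figures
#'
#' Each `plot_data` kind has an `autoplot()` method turning the numeric
#' payload into a figure; rendering never alters the payload.
#'
#' @param object a `plot_data` object.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot.plot_data
NULL

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_length_histogram <- function(object, ...) {
  p <- object$payload
  mids <- (p$breaks[-1] + p$breaks[-length(p$breaks)]) / 2
  df <- tibble::tibble(mid = mids, count = p$counts,
                       width = diff(p$breaks))
  log10_x <- isTRUE(object$annotations$log10)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = df$width, fill = "#4878A8", colour = "grey30",
                      linewidth = 0.1) +
    ggplot2::labs(
      x = if (log10_x) "log10 read length (bases)" else "Read length (bases)",
      y = "Reads",
      title = paste0("Read length histogram: ", object$annotations$label)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$annotations$n50_marker)) {
    n50 <- object$annotations$n50_marker
    gg <- gg + ggplot2::geom_vline(
      xintercept = if (log10_x) log10(n50) else n50,
      linetype = "dashed", colour = "firebrick"
    ) + ggplot2::annotate("text", x = if (log10_x) log10(n50) else n50,
                          y = max(df$count), hjust = -0.1, vjust = 1,
                          label = paste0("N50 = ", n50), colour = "firebrick")
  }
  gg
}

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_log_length_histogram <-
  autoplot.plot_data_length_histogram

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_cumulative_yield <- function(object, ...) {
  ggplot2::ggplot(object$payload$series,
                  ggplot2::aes(x = .data$hours, y = .data$cumulative_bases)) +
    ggplot2::geom_step(colour = "#4878A8") +
    ggplot2::labs(x = "Run time (hours)", y = "Cumulative yield (bases)",
                  title = paste0("Cumulative yield: ",
                                 object$annotations$label)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_flowcell_heatmap <- function(object, ...) {
  m <- object$payload$matrix
  df <- tibble::tibble(
    row = as.vector(row(m)), col = as.vector(col(m)), value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = object$annotations$statistic) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row",
                  title = paste0("Flow-cell activity: ",
                                 object$annotations$label)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_time_violin <- function(object, ...) {
  bins <- object$payload$bins
  df <- tidyr::unnest(bins[c("start_hours", "values")], "values")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$start_hours),
                                   y = .data$values)) +
    ggplot2::geom_violin(fill = "#4878A8", alpha = 0.7, scale = "width") +
    ggplot2::labs(x = sprintf("Interval start (h, %g h bins)",
                              object$annotations$interval_hours),
                  y = object$annotations$field,
                  title = paste0(object$annotations$field, " over time: ",
                                 object$annotations$label)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_bivariate_hexbin <- function(object, ...) {
  cells <- object$payload$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = bivariate_axis(object, "x"),
                  y = bivariate_axis(object, "y"),
                  title = paste0("Bivariate (hex): ",
                                 object$annotations$label)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_bivariate_kde <- function(object, ...) {
  p <- object$payload
  df <- tidyr::expand_grid(xi = seq_along(p$grid_x), yi = seq_along(p$grid_y))
  df$x <- p$grid_x[df$xi]
  df$y <- p$grid_y[df$yi]
  df$density <- p$density[cbind(df$xi, df$yi)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   z = .data$density)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = bivariate_axis(object, "x"),
                  y = bivariate_axis(object, "y"),
                  title = paste0("Bivariate (KDE): ",
                                 object$annotations$label)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

bivariate_axis <- function(object, which) {
  f <- object$annotations[[paste0(which, "_field")]]
  if (which == "x" && isTRUE(object$annotations$log10_x)) {
    f <- paste0("log10 ", f)
  }
  f
}

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_aligned_vs_effective <- function(object, ...) {
  ggplot2::ggplot(object$payload$points,
                  ggplot2::aes(x = .data$length, y = .data$aligned_length)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6, colour = "#4878A8") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Effective read length (bases)",
                  y = "Aligned read length (bases)",
                  title = paste0("Aligned vs effective length: ",
                                 object$annotations$label)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.plot_data_comparison <- function(object, ...) {
  groups <- object$payload$groups
  df <- tibble::tibble(
    label = rep(names(groups), lengths(groups)),
    value = unlist(groups, use.names = FALSE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$label)) +
    ggplot2::geom_violin(alpha = 0.7, scale = "width") +
    ggplot2::labs(x = NULL, y = object$annotations$metric,
                  title = paste0("Comparison: ", object$annotations$metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname autoplot.plot_data
#' @exportS3Method ggplot2::autoplot
autoplot.read_comparison <- function(object, ...) {
  autoplot(comparison_plot_data(object))
}

#' Write figures for a set of plots
#'
#' Renders each `plot_data` in every requested image format, using the
#' deterministic naming scheme `<label>_<kind>.<ext>`. Re-running
#' overwrites, leaving exactly the same file set.
#'
#' @param plots list of `plot_data` objects.
#' @param dir output directory (created if needed).
#' @param formats subset of `png`, `jpg`, `pdf`, `svg`.
#' @param width,height,dpi figure geometry passed to [ggplot2::ggsave()].
#' @return invisibly, the vector of files written.
#' @export
render_plots <- function(plots, dir = ".", formats = "png",
                         width = 7, height = 5, dpi = 120) {
  if (length(plots) == 0) stop("no plots to render", call. = FALSE)
  known <- c("png", "jpg", "pdf", "svg")
  if (length(formats) == 0) stop("no output formats requested", call. = FALSE)
  bad <- setdiff(formats, known)
  if (length(bad)) {
    stop("unknown format(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(known, collapse = ", "), ")", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (p in plots) {
    stem <- paste0(sanitize_filename(p$annotations$label %||% "dataset"),
                   "_", p$kind)
    gg <- autoplot(p)
    for (fmt in formats) {
      f <- file.path(dir, paste0(stem, ".", fmt))
      suppressMessages(ggplot2::ggsave(f, gg, width = width, height = height,
                                       dpi = dpi, device = ggsave_device(fmt)))
      files <- c(files, f)
    }
  }
  invisible(files)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "-", x)

ggsave_device <- function(fmt) {
  switch(fmt,
    jpg = grDevices::jpeg,
    svg = grDevices::svg,
    png = grDevices::png,
    pdf = grDevices::pdf
  )
}

#' Assemble the combined HTML report
#'
#' Writes a single self-contained HTML file holding the full statistics
#' block (or per-dataset comparison table) and every plot, with images
#' embedded as base64 PNG. A machine-readable per-read TSV (and a summary
#' TSV) is written alongside when the read table is supplied.
#'
#' @param stats a `read_summary` or `read_comparison`.
#' @param plots list of `plot_data` objects (may be empty).
#' @param path output HTML file.
#' @param table optional `read_tbl`; when given, `<stem>_reads.tsv.` and
#'   `<stem>_summary.tsv` are written next to the report.
#' @return invisibly, `path`.
#' @export
html_report <- function(stats, plots = list(), path = "report.html",
                        table = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  stats_html <- if (inherits(stats, "read_summary")) {
    td <- tidy(stats)
    rows <- sprintf("<tr><td>%s</td><td>%s</td></tr>", esc(td$statistic),
                    format(td$value, digits = 6, big.mark = ","))
    c(sprintf("<h2>Summary: %s</h2>", esc(stats$label)),
      "<table class='stats'><tr><th>Statistic</th><th>Value</th></tr>",
      rows, "</table>")
  } else if (inherits(stats, "read_comparison")) {
    s <- stats$summary
    hdr <- paste0("<tr>", paste0("<th>", esc(names(s)), "</th>",
                                 collapse = ""), "</tr>")
    rows <- vapply(seq_len(nrow(s)), function(i) {
      paste0("<tr>", paste0("<td>",
        vapply(s[i, ], function(v) format(v, digits = 6), character(1)),
        "</td>", collapse = ""), "</tr>")
    }, character(1))
    c("<h2>Dataset comparison</h2>",
      "<table class='stats'>", hdr, rows, "</table>")
  } else {
    stop("stats must be a read_summary or read_comparison", call. = FALSE)
  }

  plot_html <- character(0)
  if (length(plots)) {
    tmp <- tempfile("plots")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    for (p in plots) {
      f <- render_plots(list(p), dir = tmp, formats = "png")
      b64 <- jsonlite::base64_enc(readBin(f[1], "raw", file.size(f[1])))
      plot_html <- c(plot_html,
        sprintf("<div class='plot' id='%s'><h3>%s</h3>", esc(p$kind),
                esc(p$kind)),
        sprintf("<img alt='%s' src='data:image/png;base64,%s'/></div>",
                esc(p$kind), gsub("\n", "", b64)))
    }
  }

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'/>",
    "<title>Long-read sequencing QC report</title>",
    "<style>body{font-family:sans-serif;max-width:70em;margin:auto}",
    "table.stats{border-collapse:collapse}",
    "table.stats td,table.stats th{border:1px solid #ccc;padding:0.3em 0.8em}",
    "img{max-width:100%}</style></head><body>",
    "<h1>Long-read sequencing QC report</h1>",
    stats_html, plot_html,
    "</body></html>"
  )
  writeLines(html, path)

  if (!is.null(table)) {
    stem <- sub("\\.html?$", "", path)
    write_read_tsv(table, paste0(stem, "_reads.tsv"))
    if (inherits(stats, "read_summary")) {
      utils::write.table(tidy(stats), paste0(stem, "_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
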