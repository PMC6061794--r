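#' Flow-cell channel layouts
#'
#' Maps channel identifiers to physical grid coordinates so per-channel
#' activity can be drawn as a heat map of the flow cell. The vendor wiring
#' is treated as data, not code: a packaged default covers the 512-channel
#' MinION grid (16 rows x 32 columns, arranged in four column-major blocks
#' of 128 channels), and any custom wiring can be supplied as a TSV with
#' columns `channel`, `row`, `col` forming a bijection onto the grid.
#'
#' @param name packaged layout name, or a path to a layout TSV.
#' @return a `flowcell_layout`: list with `name`, `rows`, `cols` and a
#'   `map` tibble (`channel`, `row`, `col`).
#' @export
flowcell_layout <- function(name = "minion_r9") {
  path <- if (file.exists(name)) name else {
    p <- system.file("extdata", paste0(name, "_layout.tsv"),
                     package = "longreadqc")
    if (p == "") stop("unknown flow-cell layout '", name, "'", call. = FALSE)
    p
  }
  map <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("channel", "row", "col") %in% names(map))) {
    stop("layout TSV needs columns channel, row, col", call. = FALSE)
  }
  rows <- max(map$row)
  cols <- max(map$col)
  n <- rows * cols
  if (nrow(map) != n ||
      !setequal(map$channel, seq_len(n)) ||
      anyDuplicated(map[c("row", "col")]) > 0) {
    stop("layout is not a bijection from channels 1..", n,
         " onto the ", rows, "x", cols, " grid", call. = FALSE)
  }
  structure(list(name = if (file.exists(name)) basename(name) else name,
                 rows = rows, cols = cols,
                 map = tibble::as_tibble(map)),
            class = "flowcell_layout")
}

#' @export
print.flowcell_layout <- function(x, ...) {
  cat(sprintf("Flow-cell layout '%s': %d channels on a %dx%d grid\n",
              x$name, nrow(x$map), x$rows, x$cols))
  invisible(x)
}

#' Physical grid position of a channel
#'
#' @param layout a [flowcell_layout()].
#' @param channel integer channel id(s), within `1..rows*cols`.
#' @return a tibble with `channel`, `row`, `col`.
#' @export
channel_to_cell <- function(layout, channel) {
  n <- nrow(layout$map)
  bad <- channel < 1 | channel > n | is.na(channel)
  if (any(bad)) {
    stop("channel(s) ", paste(utils::head(channel[bad], 5), collapse = ", "),
         " outside layout '", layout$name, "' (", n, " channels)",
         call. = FALSE)
  }
  idx <- match(channel, layout$map$channel)
  tibble::tibble(channel = channel,
                 row = layout$map$row[idx],
                 col = layout$map$col[idx])
}

#' Per-channel activity matrix for the flow-cell heat map
#'
#' Aggregates reads per channel and places the chosen statistic at each
#' channel's physical grid cell; channels without reads are 0. Productive
#' and silent regions of the flow cell then show up spatially, e.g. an air
#' bubble introduced at loading.
#'
#' @param table a `read_tbl` whose records carry channel ids.
#' @param layout a [flowcell_layout()]; if the maximum channel id exceeds
#'   it, the error suggests using a larger layout rather than silently
#'   truncating.
#' @param statistic aggregate per channel: number of reads or total bases.
#' @return a `plot_data` object of kind `flowcell_heatmap` whose payload
#'   holds the rows x cols matrix.
#' @export
activity_matrix <- function(table, layout = flowcell_layout(),
                            statistic = c("read_count", "total_bases")) {
  statistic <- match.arg(statistic)
  ok <- !is.na(table$channel)
  ch <- table$channel[ok]
  n <- nrow(layout$map)
  if (any(ch > n)) {
    stop("channel(s) ", paste(utils::head(sort(unique(ch[ch > n])), 5),
                              collapse = ", "),
         " exceed layout '", layout$name, "' (", n,
         " channels); supply a larger layout TSV", call. = FALSE)
  }
  if (any(ch < 1)) stop("channel ids must be >= 1", call. = FALSE)
  mat <- matrix(0, nrow = layout$rows, ncol = layout$cols)
  if (length(ch)) {
    value <- switch(statistic,
      read_count = rep(1, length(ch)),
      total_bases = as.numeric(table$length[ok])
    )
    per_channel <- rowsum(value, ch)
    cells <- channel_to_cell(layout, as.integer(rownames(per_channel)))
    mat[cbind(cells$row, cells$col)] <- per_channel[, 1]
  }
  plot_data("flowcell_heatmap",
            payload = list(matrix = mat),
            annotations = list(label = read_label(table),
                               statistic = statistic,
                               layout = layout$name,
                               excluded_no_channel = sum(!ok)))
}
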