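# Self-contained HTML heatmap of joint features across samples, with a
# red-to-green scale (low to high abundance).

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a feature table as an HTML heatmap
#'
#' One table cell per (feature, sample); the background colour is linearly
#' interpolated between `color_low` (table minimum) and `color_high` (table
#' maximum) after the transform. Abundances are right-skewed, so the default
#' transform is `log1p`. The output is a single self-contained HTML document
#' with no external assets.
#'
#' @param table numeric feature matrix (rows = features, cols = samples).
#' @param features optional subset of feature keys (row order of the plot).
#' @param samples optional subset/order of sample ids.
#' @param color_low,color_high hex colours anchoring the scale (defaults:
#'   red `#d73027` for low, green `#1a9850` for high abundance).
#' @param transform `"log1p"` (default) or `"linear"`.
#' @param title document title.
#' @return the HTML document as a single character string.
#' @export
render_heatmap <- function(table, features = NULL, samples = NULL,
                           color_low = "#d73027", color_high = "#1a9850",
                           transform = c("log1p", "linear"),
                           title = "Joint feature heatmap") {
  transform <- match.arg(transform)
  stopifnot(is.matrix(table), nzchar(color_low), nzchar(color_high))
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(table))
    if (length(missing)) stop("unknown feature(s): ",
                              paste(missing, collapse = ", "))
    table <- table[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(table))
    if (length(missing)) stop("unknown sample(s): ",
                              paste(missing, collapse = ", "))
    table <- table[, samples, drop = FALSE]
  }
  vals <- if (transform == "log1p") log1p(table) else table
  rng <- if (length(vals)) range(vals) else c(0, 1)
  t01 <- if (length(vals) == 0L) vals
         else if (rng[2L] > rng[1L]) (vals - rng[1L]) / (rng[2L] - rng[1L])
         else array(0.5, dim = dim(vals))
  ramp <- grDevices::colorRamp(c(color_low, color_high))
  cell_color <- function(t) grDevices::rgb(ramp(t), maxColorValue = 255)

  head_row <- paste0("<tr><th></th>",
                     paste0("<th>", html_escape(colnames(table)), "</th>",
                            collapse = ""),
                     "</tr>")
  body_rows <- vapply(seq_len(nrow(table)), function(i) {
    cells <- vapply(seq_len(ncol(table)), function(j) {
      sprintf('<td style="background-color:%s">%s</td>',
              cell_color(t01[i, j]), format(signif(table[i, j], 4)))
    }, character(1))
    paste0("<tr><th>", html_escape(rownames(table)[i]), "</th>",
           paste0(cells, collapse = ""), "</tr>")
  }, character(1))
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>", html_escape(title), "</title>\n",
    "<style>table{border-collapse:collapse;font-family:sans-serif;",
    "font-size:12px}th,td{border:1px solid #ccc;padding:2px 6px;",
    "text-align:right}th{text-align:left}</style>\n</head>\n<body>\n",
    "<table>\n<thead>\n", head_row, "\n</thead>\n<tbody>\n",
    paste0(body_rows, collapse = "\n"),
    if (length(body_rows)) "\n" else "",
    "</tbody>\n</table>\n</body>\n</html>\n")
}

#' Write an HTML heatmap to a file
#'
#' @inheritParams render_heatmap
#' @param path output path.
#' @param ... passed to [render_heatmap()].
#' @export
write_heatmap <- function(table, path, ...) {
  writeLines(render_heatmap(table, ...), path)
  invisible(path)
}
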