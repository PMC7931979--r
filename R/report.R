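#' Write a table to TSV with stable formatting
#'
#' All tabular exports go through this writer: tab-separated, no quoting,
#' no row names, numbers at 15 significant digits. Identical inputs always
#' produce byte-identical files, which is what makes settings-replay
#' reproducibility checkable.
#'
#' @param x a data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x))
    if (is.double(x[[j]]))
      x[[j]] <- ifelse(is.na(x[[j]]), "NA",
                       formatC(x[[j]], digits = 15, format = "g"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Export a figure to PNG and SVG
#'
#' @param plot_fun a function of no arguments that draws the figure.
#' @param path_base path without extension; `<path_base>.png` and
#'   `<path_base>.svg` are written.
#' @param width,height device size in inches.
#' @return character vector of the two file paths, invisibly.
#' @export
export_figure <- function(plot_fun, path_base, width = 7, height = 5) {
  png_path <- paste0(path_base, ".png")
  svg_path <- paste0(path_base, ".svg")
  grDevices::png(png_path, width = width, height = height, units = "in",
                 res = 150)
  tryCatch(plot_fun(), finally = grDevices::dev.off())
  grDevices::svg(svg_path, width = width, height = height)
  tryCatch(plot_fun(), finally = grDevices::dev.off())
  invisible(c(png = png_path, svg = svg_path))
}

#' @export
plot.pca_result <- function(x, components = c(1, 2), groups = NULL, ...) {
  s <- x$scores
  i <- components[1]; j <- components[2]
  col <- if (is.null(groups)) "black" else as.integer(factor(groups)) + 1L
  graphics::plot(s[, i], s[, j], col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", i,
                                100 * x$variance_explained[i]),
                 ylab = sprintf("PC%d (%.1f%%)", j,
                                100 * x$variance_explained[j]),
                 main = "PCA of samples", ...)
  graphics::text(s[, i], s[, j], rownames(s), pos = 3, cex = 0.7)
  invisible(x)
}

#' @export
plot.tree_result <- function(x, ...) {
  graphics::plot(x$hclust, main = "Sample dendrogram (average linkage)",
                 xlab = "", sub = "", ...)
  invisible(x)
}

#' @export
plot.sample_summary <- function(x, ...) {
  if (length(x$density_grid) == 0) {
    graphics::plot.new()
    graphics::title("No plottable samples")
    return(invisible(x))
  }
  d <- x$densities
  graphics::matplot(x$density_grid, d, type = "l", lty = 1,
                    xlab = "value", ylab = "density",
                    main = "Per-sample densities", ...)
  graphics::legend("topright", legend = colnames(d), lty = 1,
                   col = seq_len(ncol(d)), cex = 0.6)
  invisible(x)
}

#' @export
plot.feature_profile <- function(x, ...) {
  pts <- x$points[!is.na(x$points$value), ]
  if (nrow(pts) == 0) {
    graphics::plot.new(); graphics::title("All values missing")
    return(invisible(x))
  }
  grp <- factor(pts$group)
  graphics::boxplot(value ~ grp, data = pts,
                    main = sprintf("Feature %s by %s", x$feature_id,
                                   x$group_column),
                    xlab = x$group_column, ylab = "value", ...)
  graphics::points(jitter(as.integer(grp), 0.2), pts$value, pch = 19,
                   col = grDevices::adjustcolor("steelblue", 0.7))
  invisible(x)
}

#' Draw a volcano plot coloured by cross-comparison category
#'
#' @param tab a [volcano_table()] result.
#' @param classification optional [classify_features()] table; points are
#'   coloured by category.
#' @param highlight optional feature ID vector drawn emphasised.
#' @param main plot title.
#' @export
plot_volcano <- function(tab, classification = NULL, highlight = NULL,
                         main = "Volcano") {
  col <- rep("grey50", nrow(tab))
  if (!is.null(classification)) {
    pal <- c(both_same = "firebrick", both_contra = "forestgreen",
             a_only = "royalblue", b_only = "orange", neither = "grey70")
    cat_by_id <- stats::setNames(classification$category, classification$id)
    hit <- tab$id %in% names(cat_by_id)
    col[hit] <- pal[cat_by_id[tab$id[hit]]]
  }
  graphics::plot(tab$x, tab$y, col = col, pch = 19, cex = 0.5,
                 xlab = "log2 fold change", ylab = "-log10(p)", main = main)
  if (!is.null(highlight)) {
    sel <- tab$id %in% highlight
    graphics::points(tab$x[sel], tab$y[sel], pch = 1, cex = 1.2,
                     col = "black", lwd = 2)
  }
  invisible(tab)
}

#' Draw exclusive-intersection counts as an UpSet-style bar chart
#'
#' @param ic an [exclusive_intersections()] result.
#' @param max_bars show at most this many intersections (largest first).
#' @export
plot_upset <- function(ic, max_bars = 20) {
  ic <- utils::head(ic, max_bars)
  if (nrow(ic) == 0) {
    graphics::plot.new(); graphics::title("No intersections")
    return(invisible(ic))
  }
  op <- graphics::par(mar = c(10, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(ic$count, names.arg = ic$key, las = 2, cex.names = 0.7,
                    ylab = "features", main = "Exclusive intersections")
  invisible(ic)
}

#' Draw the direction-concordance profile
#'
#' @param cp a [concordance_profile()] result.
#' @export
plot_concordance <- function(cp) {
  mid <- (cp$bin_lo + cp$bin_hi) / 2
  graphics::plot(mid, cp$fraction_same, type = "b", pch = 19,
                 ylim = c(0, 1), xlab = "p-value bin midpoint",
                 ylab = "fraction same direction",
                 main = "Direction concordance by p-value")
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  graphics::text(mid, cp$fraction_same, cp$n_features, pos = 1, cex = 0.7)
  invisible(cp)
}

#' @export
plot.correlation_summary <- function(x, method = "pearson", ...) {
  s <- x[[method]]
  if (s$empty) {
    graphics::plot.new(); graphics::title("No correlations")
    return(invisible(x))
  }
  h <- s$histogram
  graphics::barplot(h$count, names.arg = sprintf("%.2f", h$bin_lo),
                    las = 2, cex.names = 0.5, ylab = "features",
                    main = sprintf("%s correlation distribution (median %.2f)",
                                   method, s$median), ...)
  invisible(x)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a static HTML report
#'
#' Assembles an HTML index over previously exported figures and tables:
#' one section per analysis, each embedding its figures (relative links
#' within the output directory) and linking its tables, plus an appendix
#' with the exact settings used so the run can be replayed. Every
#' referenced file must exist under `out_dir`.
#'
#' @param sections non-empty list; each element a list with `title`,
#'   optional `text`, optional `figures` (paths of PNG/SVG files inside
#'   `out_dir`) and optional `tables` (paths of TSV files inside
#'   `out_dir`).
#' @param out_dir output directory; the report is written as
#'   `<out_dir>/report.html`.
#' @param settings settings list included as an appendix and saved next to
#'   the report as `settings.json`.
#' @param title report title.
#' @return path of the HTML file, invisibly.
#' @export
generate_report <- function(sections, out_dir, settings = list(),
                            title = "omicomp report") {
  if (!is.list(sections) || length(sections) == 0L)
    stop("at least one section is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rel <- function(p) {
    p <- normalizePath(p, mustWork = TRUE)
    root <- normalizePath(out_dir, mustWork = TRUE)
    if (!startsWith(p, root))
      stop(sprintf("referenced file is outside the report directory: %s", p),
           call. = FALSE)
    sub("^/", "", substring(p, nchar(root) + 1L))
  }
  body <- character(0)
  for (sec in sections) {
    if (is.null(sec$title)) stop("every section needs a title", call. = FALSE)
    body <- c(body, sprintf("<h2>%s</h2>", .html_escape(sec$title)))
    if (!is.null(sec$text))
      body <- c(body, sprintf("<p>%s</p>", .html_escape(sec$text)))
    for (f in sec$figures)
      body <- c(body, sprintf("<img src=\"%s\" style=\"max-width:45em\"/>",
                              rel(f)))
    for (tb in sec$tables)
      body <- c(body, sprintf("<p><a href=\"%s\">%s</a></p>", rel(tb),
                              .html_escape(basename(tb))))
  }
  settings_path <- file.path(out_dir, "settings.json")
  save_settings(settings, settings_path)
  appendix <- sprintf("<h2>Settings</h2><pre>%s</pre>",
                      .html_escape(paste(readLines(settings_path),
                                         collapse = "\n")))
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
            sprintf("<title>%s</title>", .html_escape(title)),
            "<style>body{font-family:sans-serif;max-width:60em;margin:auto}",
            "pre{background:#f6f6f6;padding:1em}</style></head><body>",
            sprintf("<h1>%s</h1>", .html_escape(title)), body, appendix,
            "</body></html>")
  path <- file.path(out_dir, "report.html")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

#' One structured log line per operation
#'
#' Headless substitute for the visible state of an interactive session:
#' each analysis step logs its name, parameters and row counts on one line.
#'
#' @param op operation name.
#' @param ... named scalar parameters / counts to record.
#' @param file connection or path to append to (default stderr).
#' @export
log_step <- function(op, ..., file = stderr()) {
  kv <- list(...)
  msg <- paste0("[omicomp] ", op,
                if (length(kv)) paste0(" ", paste(names(kv),
                                                  vapply(kv, format, ""),
                                                  sep = "=",
                                                  collapse = " ")) else "")
  if (inherits(file, "connection")) writeLines(msg, file)
  else cat(msg, "\n", sep = "", file = file, append = TRUE)
  invisible(msg)
}
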