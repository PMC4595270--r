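# Figures and the scrapbook. Every figure-producing operation returns a
# machine-readable sidecar (summary table or layout) so tests assert on data
# rather than pixels, and optionally writes PNG + SVG files. The single
# current grouping dictates order and colour in every view, which keeps the
# violin, both heatmaps and the embedding scatter mutually coherent.

# draw by calling `fun` twice, once per device, so PNG and SVG stay identical
render_to <- function(file, fun, width = 7, height = 5) {
  if (is.null(file)) { fun(); return(invisible(NULL)) }
  png_file <- paste0(file, ".png"); svg_file <- paste0(file, ".svg")
  grDevices::png(png_file, width = width * 100, height = height * 100, res = 100)
  tryCatch(fun(), finally = grDevices::dev.off())
  grDevices::svg(svg_file, width = width, height = height)
  tryCatch(fun(), finally = grDevices::dev.off())
  c(png = png_file, svg = svg_file)
}

violin_shape <- function(v) {
  if (length(v) < 2L || stats::sd(v) == 0) return(NULL)
  d <- stats::density(v, bw = "nrd0")
  keep <- d$x >= min(v) & d$x <= max(v)
  list(x = d$x[keep], y = d$y[keep] / max(d$y) * 0.4)
}

#' Violin plot of one gene across groups
#'
#' One violin per non-empty group, drawn in grouping order with group
#' colours; singleton groups render as a point. The per-group summary table
#' is returned alongside the figure for testing.
#'
#' @param exp an `scx_experiment`.
#' @param gene gene on the panel.
#' @param grouping an `scx_grouping`; defaults to the experiment's current one.
#' @param file base path for `<file>.png` + `<file>.svg`, or `NULL` to skip
#'   file output.
#' @return list of class `scx_figure`: `summary` (data.frame with `group`,
#'   `n`, `median`, `q1`, `q3`), `files`, `type`.
#' @export
violin_figure <- function(exp, gene, grouping = exp$grouping, file = NULL) {
  if (!gene %in% exp$genes) stop("unknown gene: ", gene, call. = FALSE)
  if (is.null(grouping)) stop("no grouping available", call. = FALSE)
  validate_grouping(exp, grouping)
  vals <- lapply(grouping$members, function(m) exp$matrix[m, gene])
  summary <- do.call(rbind, lapply(seq_along(vals), function(i) {
    v <- vals[[i]][!is.na(vals[[i]])]
    q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(group = grouping$labels[i], n = length(v),
               median = q[2], q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
  }))
  draw <- function() {
    k <- length(vals)
    all_v <- unlist(vals); all_v <- all_v[!is.na(all_v)]
    graphics::plot(NA, xlim = c(0.5, k + 0.5),
                   ylim = range(all_v, na.rm = TRUE) + c(-0.5, 0.5),
                   xaxt = "n", xlab = "", ylab = paste(gene, "expression"),
                   main = gene)
    graphics::axis(1, at = seq_len(k), labels = grouping$labels, las = 2,
                   cex.axis = 0.8)
    for (i in seq_len(k)) {
      v <- vals[[i]][!is.na(vals[[i]])]
      sh <- violin_shape(v)
      if (!is.null(sh)) {
        graphics::polygon(c(i - sh$y, rev(i + sh$y)), c(sh$x, rev(sh$x)),
                          col = grouping$colors[i], border = NA)
      }
      graphics::points(rep(i, length(v)), v, pch = 16, cex = 0.4,
                       col = "#00000066")
      if (length(v)) graphics::segments(i - 0.2, stats::median(v),
                                        i + 0.2, stats::median(v), lwd = 2)
    }
  }
  files <- render_to(file, draw)
  structure(list(summary = summary, files = files, type = "violin",
                 gene = gene, group_order = grouping$labels),
            class = "scx_figure")
}

heat_colors <- function(stage) {
  if (stage == "z_transformed")
    grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  else grDevices::colorRampPalette(c("#FFF5EB", "#D94801", "#7F2704"))(101)
}

draw_heatmap <- function(mat, cell_colors, stage, main, missing_color = "#BBBBBB") {
  # cells as columns, genes/markers as rows; colour bar above the matrix
  cols <- heat_colors(stage)
  rng <- range(mat, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (stage == "z_transformed") rng <- c(-1, 1) * max(abs(rng), 1e-9)
  z <- t(mat)                               # image: x = cells, y = genes
  graphics::layout(matrix(c(1, 2), nrow = 2), heights = c(1.5, 8.5))
  op <- graphics::par(mar = c(0.1, 4, 1.1, 0.5))
  graphics::image(seq_len(nrow(z)), 1, matrix(seq_len(nrow(z))), col = cell_colors,
                  axes = FALSE, xlab = "", ylab = "", main = main,
                  cex.main = 0.9)
  graphics::par(mar = c(2, 4, 0.1, 0.5))
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)),
                  pmin(pmax(z, rng[1]), rng[2]),
                  zlim = rng, col = cols, axes = FALSE, xlab = "cells", ylab = "")
  if (anyNA(z)) {
    na_idx <- which(is.na(z), arr.ind = TRUE)
    graphics::rect(na_idx[, 1] - 0.5, na_idx[, 2] - 0.5,
                   na_idx[, 1] + 0.5, na_idx[, 2] + 0.5,
                   col = missing_color, border = NA)
  }
  if (ncol(z) <= 60)
    graphics::axis(2, at = seq_len(ncol(z)), labels = colnames(z), las = 2,
                   cex.axis = 0.5, tick = FALSE)
  graphics::par(op)
  graphics::layout(1)
}

#' Expression heatmap with group colour bar
#'
#' Cells are ordered by group (in grouping order); within each group either
#' by hierarchical leaf order (correlation distance, complete linkage) or by
#' input order. Genes are optionally clustered too (default on). The layout
#' (cell order, gene order, per-cell colour bar) is returned and can be fed
#' to [index_heatmap()] so both heatmaps share one cell order.
#'
#' @param exp an `scx_experiment`.
#' @param grouping an `scx_grouping`; defaults to the experiment's current one.
#' @param within_group_order `"cluster"` (default) or `"none"`.
#' @param cluster_genes reorder genes by hierarchical leaf order? Default `TRUE`.
#' @param file base path for image output, or `NULL`.
#' @return list of class `scx_figure` with `layout` (`cell_order`,
#'   `gene_order`, `colour_bar`, `group_blocks`) and `files`.
#' @export
expression_heatmap <- function(exp, grouping = exp$grouping,
                               within_group_order = c("cluster", "none"),
                               cluster_genes = TRUE, file = NULL) {
  within_group_order <- match.arg(within_group_order)
  if (is.null(grouping)) stop("no grouping available", call. = FALSE)
  validate_grouping(exp, grouping)
  order_within <- function(members) {
    if (within_group_order == "none" || length(members) < 3L) return(members)
    m <- exp$matrix[members, , drop = FALSE]
    ok <- apply(m, 1, stats::sd) > 0
    if (sum(ok) < 3L) return(members)
    d <- correlation_distance(m[ok, , drop = FALSE])
    ord <- hcluster(d, "complete")$hclust$order
    c(members[ok][ord], members[!ok])
  }
  cell_order <- unlist(lapply(grouping$members, order_within), use.names = FALSE)
  gene_order <- exp$genes
  if (isTRUE(cluster_genes) && length(exp$genes) >= 3L) {
    gm <- t(exp$matrix)
    ok <- apply(gm, 1, stats::sd) > 0
    if (sum(ok) >= 3L) {
      d <- correlation_distance(gm[ok, , drop = FALSE])
      ord <- hcluster(d, "complete")$hclust$order
      gene_order <- c(exp$genes[ok][ord], exp$genes[!ok])
    }
  }
  colour_bar <- group_of(grouping, cell_order)$color
  layout <- list(cell_order = cell_order, gene_order = gene_order,
                 colour_bar = colour_bar,
                 group_blocks = stats::setNames(lengths(grouping$members),
                                                grouping$labels))
  mat <- exp$matrix[cell_order, gene_order, drop = FALSE]
  files <- render_to(file, function()
    draw_heatmap(mat, colour_bar, exp$stage, "expression"), width = 8, height = 6)
  structure(list(layout = layout, files = files, type = "expression_heatmap"),
            class = "scx_figure")
}

#' Index-marker heatmap sharing an expression heatmap's layout
#'
#' Uses the identical cell order and colour bar as the supplied layout, so
#' the immunophenotype view lines up column-for-column with the expression
#' view. Missing marker values are rendered in a dedicated missing colour,
#' never dropped.
#'
#' @param exp an `scx_experiment` with index data joined.
#' @param layout the `layout` of an [expression_heatmap()] result (the
#'   `scx_figure` itself is also accepted).
#' @param file base path for image output, or `NULL`.
#' @return list of class `scx_figure` with the (shared) `layout` and `files`.
#' @export
index_heatmap <- function(exp, layout, file = NULL) {
  if (inherits(layout, "scx_figure")) layout <- layout$layout
  if (is.null(exp$index))
    stop("no index data joined; run join_index() first", call. = FALSE)
  if (!setequal(layout$cell_order, exp$cells))
    stop("layout cell order does not match the experiment", call. = FALSE)
  mat <- exp$index$matrix[layout$cell_order, , drop = FALSE]
  # markers on their own scales: column-standardise for display only
  disp <- apply(mat, 2, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) v * 0 else (v - mean(v, na.rm = TRUE)) / s
  })
  rownames(disp) <- rownames(mat)
  files <- render_to(file, function()
    draw_heatmap(disp, layout$colour_bar, "z_transformed", "index markers"),
    width = 8, height = 3.5)
  out_layout <- layout
  out_layout$marker_order <- exp$index$markers
  structure(list(layout = out_layout, files = files, type = "index_heatmap"),
            class = "scx_figure")
}

#' Scatter plot of an embedding, coloured by group
#'
#' Components 1-2 for `dims = 2`, or a static orthographic projection of
#' components 1-3 for `dims = 3`.
#'
#' @param embedding an `scx_embedding`.
#' @param grouping an `scx_grouping` covering the embedded cells.
#' @param dims 2 or 3.
#' @param file base path for image output, or `NULL`.
#' @return list of class `scx_figure` with `points` (data.frame of plotted
#'   coordinates, group and colour per cell) and `files`.
#' @export
embedding_scatter <- function(embedding, grouping, dims = 2, file = NULL) {
  stopifnot(inherits(embedding, "scx_embedding"))
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3", call. = FALSE)
  if (ncol(embedding$coords) < dims)
    stop("embedding has only ", ncol(embedding$coords),
         " component(s); dims = ", dims, " requested", call. = FALSE)
  cells <- rownames(embedding$coords)
  ginfo <- group_of(grouping, cells)
  if (anyNA(ginfo$group))
    stop("grouping does not cover all embedded cells", call. = FALSE)
  co <- embedding$coords
  if (dims == 2) {
    px <- co[, 1]; py <- co[, 2]
    labs <- c(paste0(toupper(embedding$method), " 1"),
              paste0(toupper(embedding$method), " 2"))
  } else {
    # fixed-angle orthographic projection of components 1-3
    theta <- pi / 6; phi <- pi / 8
    px <- co[, 1] * cos(theta) + co[, 2] * sin(theta)
    py <- -co[, 1] * sin(theta) * sin(phi) + co[, 2] * cos(theta) * sin(phi) +
      co[, 3] * cos(phi)
    labs <- c("projection x", "projection y")
  }
  pts <- data.frame(cell = cells, x = px, y = py, group = ginfo$group,
                    color = ginfo$color, stringsAsFactors = FALSE)
  files <- render_to(file, function() {
    graphics::plot(pts$x, pts$y, col = pts$color, pch = 16,
                   xlab = labs[1], ylab = labs[2],
                   main = paste0(embedding$method, " (", dims, "D)"))
    graphics::legend("topright", legend = grouping$labels,
                     col = grouping$colors, pch = 16, cex = 0.7, bty = "n")
  })
  structure(list(points = pts, files = files, type = "embedding_scatter",
                 group_order = grouping$labels),
            class = "scx_figure")
}

# ---- scrapbook -------------------------------------------------------------

new_scrapbook <- function() structure(list(entries = list()), class = "scx_scrapbook")

#' Add a figure to the scrapbook
#'
#' Entries carry strictly increasing sequence numbers; the number of entries
#' is unlimited. Timestamps are injectable so report rendering can be
#' byte-deterministic in tests.
#'
#' @param scrapbook an `scx_scrapbook` (created internally by sessions).
#' @param figure an `scx_figure` (or a figure file path).
#' @param annotation free-text annotation; may be empty.
#' @param timestamp optional timestamp string; defaults to the current time.
#' @return the scrapbook with the entry appended.
#' @export
scrapbook_add <- function(scrapbook, figure, annotation = "",
                          timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")) {
  stopifnot(inherits(scrapbook, "scx_scrapbook"))
  fig_file <- if (inherits(figure, "scx_figure")) {
    if (length(figure$files)) unname(figure$files[["png"]]) else NA_character_
  } else as.character(figure)
  seq_no <- length(scrapbook$entries) + 1L
  scrapbook$entries[[seq_no]] <- list(seq = seq_no, figure = fig_file,
                                      annotation = annotation,
                                      timestamp = timestamp)
  scrapbook
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the session report
#'
#' An HTML page listing every scrapbook entry in sequence order with its
#' annotation, followed by the full analysis log. Rendering is pure given the
#' session state and the injected timestamp.
#'
#' @param state a session state (see [run_pipeline()]) or a list with
#'   `experiment` and `scrapbook`.
#' @param path output HTML file path.
#' @param timestamp report timestamp string; injectable for deterministic
#'   output.
#' @return `path`, invisibly.
#' @export
render_report <- function(state, path,
                          timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")) {
  exp <- state$experiment; sb <- state$scrapbook
  lines <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
             "<title>single-cell qPCR session report</title></head><body>",
             "<h1>Session report</h1>",
             paste0("<p>Generated: ", html_escape(timestamp), "</p>"),
             paste0("<p>", length(exp$cells), " cells x ", length(exp$genes),
                    " genes; stage: ", exp$stage, "</p>"),
             "<h2>Scrapbook</h2>")
  for (e in sb$entries) {
    lines <- c(lines,
               paste0("<div class='entry'><h3>Entry ", e$seq, "</h3>"),
               if (!is.na(e$figure))
                 paste0("<img src='", html_escape(basename(e$figure)),
                        "' style='max-width:100%'>"),
               paste0("<p>", html_escape(e$annotation), "</p></div>"))
  }
  lines <- c(lines, "<h2>Analysis log</h2>", "<ol>")
  for (entry in exp$log) {
    par_txt <- paste(names(entry$params),
                     vapply(entry$params, function(p)
                       paste(format(unlist(p)), collapse = ","), ""),
                     sep = "=", collapse = "; ")
    cnt_txt <- paste(names(entry$counts), unlist(entry$counts),
                     sep = "=", collapse = "; ")
    lines <- c(lines, paste0("<li><b>", html_escape(entry$op), "</b> ",
                             html_escape(par_txt),
                             if (nzchar(cnt_txt)) paste0(" [", html_escape(cnt_txt), "]"),
                             "</li>"))
  }
  lines <- c(lines, "</ol>", "</body></html>")
  writeLines(lines, path)
  invisible(path)
}
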