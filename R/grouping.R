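# Cell groupings: ordered, coloured partitions of the current cell set.
# Heatmaps, violin plots and embedding scatters all draw their order and
# colours from the single current grouping, which is what keeps the paired
# expression / index-marker views coherent.

# colour-blind-safe 12-colour palette (Okabe-Ito extended with darker tones);
# cycled with shade variation beyond 12 groups
SCX_PALETTE <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
                 "#D55E00", "#CC79A7", "#999999", "#8C510A", "#01665E",
                 "#762A83", "#1B7837")

#' Default group colours
#'
#' @param n number of colours required.
#' @return character vector of `n` unique hex colours.
#' @export
scx_palette <- function(n) {
  if (n <= length(SCX_PALETTE)) return(SCX_PALETTE[seq_len(n)])
  reps <- ceiling(n / length(SCX_PALETTE))
  out <- character(0)
  for (r in seq_len(reps)) {
    shade <- 1 - (r - 1) * 0.25           # darken each successive cycle
    rgb <- grDevices::col2rgb(SCX_PALETTE) * shade
    out <- c(out, grDevices::rgb(rgb[1, ], rgb[2, ], rgb[3, ], maxColorValue = 255))
  }
  out[seq_len(n)]
}

new_grouping <- function(labels, colors, members, source) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate group labels", call. = FALSE)
  if (anyDuplicated(colors)) stop("group colours must be unique", call. = FALSE)
  all_members <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("groups must be pairwise disjoint", call. = FALSE)
  structure(list(labels = labels, colors = as.character(colors),
                 members = lapply(members, as.character), source = source),
            class = "scx_grouping")
}

#' @export
print.scx_grouping <- function(x, ...) {
  cat("scx_grouping (", x$source, "): ", length(x$labels), " groups, ",
      length(unlist(x$members)), " cells\n", sep = "")
  for (i in seq_along(x$labels))
    cat("  ", x$labels[i], " [", x$colors[i], "]: ",
        length(x$members[[i]]), " cells\n", sep = "")
  invisible(x)
}

# partition check against the current cell set
validate_grouping <- function(exp, grouping) {
  all_members <- unlist(grouping$members, use.names = FALSE)
  if (!setequal(all_members, exp$cells) || length(all_members) != length(exp$cells))
    stop("grouping does not partition the current cell set", call. = FALSE)
  invisible(grouping)
}

#' Per-cell group labels and colours
#'
#' @param grouping an `scx_grouping`.
#' @param cells cell IDs to look up (defaults to all grouped cells in order).
#' @return data.frame with columns `cell`, `group`, `color`.
#' @export
group_of <- function(grouping, cells = unlist(grouping$members)) {
  lab <- rep(grouping$labels, lengths(grouping$members))
  col <- rep(grouping$colors, lengths(grouping$members))
  names(lab) <- names(col) <- unlist(grouping$members, use.names = FALSE)
  data.frame(cell = cells, group = unname(lab[cells]),
             color = unname(col[cells]), stringsAsFactors = FALSE)
}

#' Initial grouping by plate of origin
#'
#' @param exp an `scx_experiment`.
#' @return an `scx_grouping` with one group per plate, in plate input order.
#' @export
groups_from_plates <- function(exp) {
  ids <- unique(exp$plates)
  members <- lapply(ids, function(p) exp$cells[exp$plates == p])
  new_grouping(ids, scx_palette(length(ids)), members, "plates")
}

#' Grouping from a cluster assignment
#'
#' @param exp an `scx_experiment`.
#' @param assignment named integer vector (cell -> cluster index 1..k), as
#'   returned by [cut_tree()] or [kmeans_cluster()].
#' @return an `scx_grouping` with groups `"cluster 1"..k` in ascending index.
#' @export
groups_from_assignment <- function(exp, assignment) {
  if (is.null(names(assignment)) ||
      !setequal(names(assignment), exp$cells) ||
      length(assignment) != length(exp$cells))
    stop("assignment must cover exactly the current cells", call. = FALSE)
  ks <- sort(unique(assignment))
  members <- lapply(ks, function(k) names(assignment)[assignment == k])
  new_grouping(paste("cluster", ks), scx_palette(length(ks)), members, "cluster")
}

#' 1-D grouping: bin cells by one gene's expression
#'
#' Bins are half-open, `(-Inf, c1), [c1, c2), ..., [ck, Inf)`: a value exactly
#' at a cutoff lands in the upper bin. Binning operates on the experiment's
#' current stage matrix (not-detected raw Ct counts as the floor). Empty bins
#' are dropped; bins are ordered low to high.
#'
#' @param exp an `scx_experiment`.
#' @param gene gene to bin on.
#' @param cutoffs numeric cutoffs (sorted internally, with a warning if the
#'   input was unsorted).
#' @return an `scx_grouping`.
#' @export
groups_1d <- function(exp, gene, cutoffs) {
  if (!gene %in% exp$genes) stop("unknown gene: ", gene, call. = FALSE)
  if (length(cutoffs) < 1L) stop("need at least one cutoff", call. = FALSE)
  if (is.unsorted(cutoffs)) {
    warning("cutoffs were not ascending; sorting them", call. = FALSE)
    cutoffs <- sort(cutoffs)
  }
  v <- exp$matrix[, gene]
  v[is.na(v)] <- if (exp$stage == "raw_ct") exp$lod else min(v, na.rm = TRUE)
  bin <- findInterval(v, cutoffs, left.open = FALSE) + 1L   # value==cutoff -> upper
  edges <- c(-Inf, cutoffs, Inf)
  labels <- sprintf("%s [%s, %s)", gene,
                    formatC(edges[-length(edges)]), formatC(edges[-1]))
  keep <- sort(unique(bin))
  members <- lapply(keep, function(b) exp$cells[bin == b])
  new_grouping(labels[keep], scx_palette(length(keep)), members, "1d")
}

#' Describe a rectangular two-gene gate
#'
#' Bounds are inclusive, mirroring cytometry gating conventions.
#'
#' @param gene_x,gene_y gene names for the x and y axes.
#' @param x_min,x_max,y_min,y_max expression bounds.
#' @param label optional group label.
#' @return a list of class `scx_gate`.
#' @export
gate2d <- function(gene_x, gene_y, x_min = -Inf, x_max = Inf,
                   y_min = -Inf, y_max = Inf, label = NULL) {
  if (x_min > x_max || y_min > y_max)
    stop("gate bounds must satisfy min <= max", call. = FALSE)
  structure(list(gene_x = gene_x, gene_y = gene_y, x_min = x_min,
                 x_max = x_max, y_min = y_min, y_max = y_max, label = label),
            class = "scx_gate")
}

#' 2-D grouping: rectangular gates on a two-gene plane
#'
#' Cells are tested against the gates in order; the first gate containing a
#' cell wins, so overlapping gates still yield disjoint groups. Cells caught
#' by no gate form a final `"rest"` group.
#'
#' @param exp an `scx_experiment`.
#' @param gates an [gate2d()] or ordered list of them.
#' @return an `scx_grouping`.
#' @export
groups_2d <- function(exp, gates) {
  if (inherits(gates, "scx_gate")) gates <- list(gates)
  if (length(gates) < 1L) stop("need at least one gate", call. = FALSE)
  for (g in gates)
    for (gn in c(g$gene_x, g$gene_y))
      if (!gn %in% exp$genes) stop("unknown gene: ", gn, call. = FALSE)
  assigned <- rep(NA_integer_, length(exp$cells))
  for (i in seq_along(gates)) {
    g <- gates[[i]]
    x <- exp$matrix[, g$gene_x]; y <- exp$matrix[, g$gene_y]
    inside <- !is.na(x) & !is.na(y) &
      x >= g$x_min & x <= g$x_max & y >= g$y_min & y <= g$y_max
    assigned[is.na(assigned) & inside] <- i
  }
  labels <- vapply(seq_along(gates), function(i) {
    if (!is.null(gates[[i]]$label)) gates[[i]]$label else paste0("gate ", i)
  }, "")
  members <- lapply(seq_along(gates), function(i) exp$cells[which(assigned == i)])
  keep <- lengths(members) > 0L
  labels <- labels[keep]; members <- members[keep]
  rest <- exp$cells[is.na(assigned)]
  if (length(rest) > 0L) {
    labels <- c(labels, "rest")
    members <- c(members, list(rest))
  }
  new_grouping(labels, scx_palette(length(labels)), members, "2d")
}

#' Merge groups
#'
#' The merged group takes the position of the earliest merged member and the
#' colour of that member; total cell count is preserved.
#'
#' @param grouping an `scx_grouping`.
#' @param labels_to_merge two or more existing labels.
#' @param new_label label of the merged group.
#' @return an `scx_grouping`.
#' @export
merge_groups <- function(grouping, labels_to_merge, new_label) {
  idx <- match(labels_to_merge, grouping$labels)
  if (anyNA(idx))
    stop("unknown group label: ",
         paste(labels_to_merge[is.na(idx)], collapse = ", "), call. = FALSE)
  if (length(idx) < 2L) stop("need at least two labels to merge", call. = FALSE)
  first <- min(idx)
  merged <- unlist(grouping$members[idx], use.names = FALSE)
  keep <- setdiff(seq_along(grouping$labels), setdiff(idx, first))
  labels <- grouping$labels[keep]; colors <- grouping$colors[keep]
  members <- grouping$members[keep]
  pos <- match(first, keep)
  labels[pos] <- new_label
  members[[pos]] <- merged
  new_grouping(labels, colors, members, "merged")
}

#' Reorder groups
#'
#' @param grouping an `scx_grouping`.
#' @param new_order a permutation of the current labels; colours travel with
#'   their groups.
#' @return an `scx_grouping`.
#' @export
reorder_groups <- function(grouping, new_order) {
  if (!setequal(new_order, grouping$labels) ||
      length(new_order) != length(grouping$labels))
    stop("new_order must be a permutation of the current labels", call. = FALSE)
  idx <- match(new_order, grouping$labels)
  new_grouping(grouping$labels[idx], grouping$colors[idx],
               grouping$members[idx], "reordered")
}
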