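# The central container: a concatenated multi-plate experiment with an
# expression matrix, detection mask, optional index-sorting markers, a
# grouping and an append-only analysis log. The `stage` field drives a small
# state machine (raw_ct -> inverted -> hk_normalised -> z_transformed) so
# transformations can only compose in the documented order.

STAGES <- c("raw_ct", "inverted", "hk_normalised", "z_transformed")

new_experiment <- function(cells, plates, wells, genes, matrix, detected,
                           stage, lod, index = NULL, grouping = NULL,
                           log = list(), flags = character()) {
  if (anyDuplicated(cells)) stop("duplicate cell IDs", call. = FALSE)
  dimnames(matrix) <- dimnames(detected) <- list(cells, genes)
  structure(list(cells = cells, plates = plates, wells = wells, genes = genes,
                 matrix = matrix, detected = detected, stage = stage,
                 lod = lod, index = index, grouping = grouping, log = log,
                 flags = flags),
            class = "scx_experiment")
}

#' @export
print.scx_experiment <- function(x, ...) {
  cat("scx_experiment: ", length(x$cells), " cells x ", length(x$genes),
      " genes (stage: ", x$stage, ", LOD ", x$lod, ")\n", sep = "")
  cat("  plates: ", paste(unique(x$plates), collapse = ", "), "\n", sep = "")
  if (!is.null(x$index))
    cat("  index markers: ", paste(x$index$markers, collapse = ", "), "\n", sep = "")
  if (!is.null(x$grouping))
    cat("  grouping: ", length(x$grouping$labels), " groups (",
        x$grouping$source, ")\n", sep = "")
  cat("  log: ", length(x$log), " entries\n", sep = "")
  invisible(x)
}

#' @export
dim.scx_experiment <- function(x) c(length(x$cells), length(x$genes))

assert_stage <- function(exp, allowed, op) {
  if (!exp$stage %in% allowed)
    stop(op, " requires stage ", paste(allowed, collapse = " or "),
         " but experiment is at stage '", exp$stage, "'", call. = FALSE)
  invisible(exp)
}

# every state-changing operation appends exactly one entry
log_append <- function(exp, op, params = list(), counts = list()) {
  seq_no <- length(exp$log) + 1L
  exp$log[[seq_no]] <- list(seq = seq_no, op = op, params = params,
                            counts = counts)
  exp
}

#' Concatenate plates into a single experiment
#'
#' All plates must share the same gene panel (any column order) and the same
#' LOD; a mismatch is an error rather than a silent intersection, since mixed
#' chip designs usually indicate an array mix-up. Cell IDs are
#' plate-qualified (`"<plate_id>:<well>"`).
#'
#' @param plates a list of [scx_plate()] objects (or a single one).
#' @return an `scx_experiment` at stage `raw_ct`.
#' @export
concatenate_plates <- function(plates) {
  if (inherits(plates, "scx_plate")) plates <- list(plates)
  if (length(plates) < 1L) stop("need at least one plate", call. = FALSE)
  ids <- vapply(plates, function(p) p$plate_id, "")
  if (anyDuplicated(ids))
    stop("duplicate plate_id: ", ids[duplicated(ids)][1], call. = FALSE)
  panel <- sort(plates[[1]]$genes)
  for (p in plates[-1]) {
    if (!identical(sort(p$genes), panel)) {
      d <- union(setdiff(p$genes, panel), setdiff(panel, p$genes))
      stop("gene panels differ between plates ('", ids[1], "' vs '",
           p$plate_id, "'): ", paste(d, collapse = ", "), call. = FALSE)
    }
  }
  lods <- vapply(plates, function(p) p$lod, 0)
  if (length(unique(lods)) != 1L)
    stop("LOD differs between plates: ", paste(unique(lods), collapse = ", "),
         call. = FALSE)
  genes <- plates[[1]]$genes
  mats <- lapply(plates, function(p) p$ct[, genes, drop = FALSE])
  dets <- lapply(plates, function(p) p$detected[, genes, drop = FALSE])
  cells <- unlist(lapply(plates, function(p) make_cell_id(p$plate_id, p$wells)),
                  use.names = FALSE)
  exp <- new_experiment(
    cells = cells,
    plates = unlist(lapply(plates, function(p) rep(p$plate_id, length(p$wells))),
                    use.names = FALSE),
    wells = unlist(lapply(plates, function(p) p$wells), use.names = FALSE),
    genes = genes,
    matrix = do.call(rbind, mats),
    detected = do.call(rbind, dets),
    stage = "raw_ct", lod = lods[1])
  log_append(exp, "concatenate_plates",
             params = list(plate_ids = ids),
             counts = list(n_plates = length(plates), n_cells = length(cells),
                           n_genes = length(genes)))
}

#' Join index-sorting intensities onto an experiment
#'
#' Rows are matched by (plate, well). Expression cells without an index row
#' get missing marker values; index rows without a matching expression cell
#' are dropped with a logged warning. The marker set is the union across
#' tables. The expression matrix itself is never altered.
#'
#' @param exp an `scx_experiment`.
#' @param tables a list of `scx_index` tables (or a single one). Tables with
#'   `NA` plate_id are resolvable only in single-plate experiments.
#' @return the experiment with an `index` component aligned to its cells.
#' @export
join_index <- function(exp, tables) {
  stopifnot(inherits(exp, "scx_experiment"))
  if (inherits(tables, "scx_index")) tables <- list(tables)
  plate_ids <- unique(exp$plates)
  markers <- unique(unlist(lapply(tables, function(t) t$markers)))
  im <- matrix(NA_real_, length(exp$cells), length(markers),
               dimnames = list(exp$cells, markers))
  dropped <- character()
  for (tab in tables) {
    pid <- tab$plate_id
    if (is.na(pid)) {
      if (length(plate_ids) != 1L)
        stop("index table without plate_id is ambiguous in a ",
             length(plate_ids), "-plate experiment", call. = FALSE)
      pid <- plate_ids
    } else if (!pid %in% plate_ids) {
      stop("index table plate_id '", pid, "' matches no plate in the experiment",
           call. = FALSE)
    }
    cid <- make_cell_id(pid, tab$wells)
    hit <- cid %in% exp$cells
    if (any(!hit)) dropped <- c(dropped, cid[!hit])
    im[cid[hit], tab$markers] <- tab$intensity[hit, , drop = FALSE]
  }
  if (length(dropped) > 0L)
    warning(length(dropped), " index row(s) had no matching expression cell ",
            "and were dropped: ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  exp$index <- list(markers = markers, matrix = im)
  log_append(exp, "join_index",
             params = list(n_tables = length(tables), markers = markers),
             counts = list(n_matched = sum(!is.na(im[, 1, drop = TRUE])),
                           n_dropped = length(dropped)))
}

# keep only the given cells; grouping and index rows are pruned consistently
subset_cells <- function(exp, keep) {
  exp$matrix <- exp$matrix[keep, , drop = FALSE]
  exp$detected <- exp$detected[keep, , drop = FALSE]
  exp$plates <- exp$plates[match(keep, exp$cells)]
  exp$wells <- exp$wells[match(keep, exp$cells)]
  exp$cells <- keep
  if (!is.null(exp$index))
    exp$index$matrix <- exp$index$matrix[keep, , drop = FALSE]
  if (!is.null(exp$grouping)) {
    g <- exp$grouping
    g$members <- lapply(g$members, intersect, keep)
    nonempty <- lengths(g$members) > 0L
    exp$grouping <- new_grouping(g$labels[nonempty], g$colors[nonempty],
                                 g$members[nonempty], g$source)
  }
  exp
}
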