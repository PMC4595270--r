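# Quality control on raw Ct: per-plate control-gene distributions, and
# removal of cells whose positive controls fail user-defined criteria.
# Filtering always precedes inversion (lower Ct = higher expression, so a
# control "expressed below threshold" means Ct ABOVE the rule's max_ct).

#' A single control-gene filter rule
#'
#' A cell passes the rule iff the gene is detected (when `require_detected`)
#' and its Ct is at most `max_ct`. A not-detected entry passes a rule with
#' `require_detected = FALSE` vacuously (there is no Ct to compare).
#'
#' @param gene control gene name.
#' @param max_ct maximum acceptable Ct in cycles (0 < max_ct <= LOD).
#' @param require_detected must the gene be detected? Default `TRUE`.
#' @return a list of class `scx_filter_rule`.
#' @export
filter_rule <- function(gene, max_ct, require_detected = TRUE) {
  if (!is.numeric(max_ct) || max_ct <= 0)
    stop("max_ct must be a positive number of cycles", call. = FALSE)
  structure(list(gene = gene, max_ct = max_ct,
                 require_detected = isTRUE(require_detected)),
            class = "scx_filter_rule")
}

#' A filter specification: rules plus a combinator
#'
#' @param rules a [filter_rule()] or list of them.
#' @param combinator `"all"` (default; every rule must pass — a positive
#'   control failing in any channel indicates a failed cell) or `"any"`.
#' @return a list of class `scx_filter_spec`.
#' @export
filter_spec <- function(rules, combinator = c("all", "any")) {
  if (inherits(rules, "scx_filter_rule")) rules <- list(rules)
  if (length(rules) < 1L) stop("need at least one rule", call. = FALSE)
  structure(list(rules = rules, combinator = match.arg(combinator)),
            class = "scx_filter_spec")
}

#' Summarise control-gene distributions
#'
#' For each control gene: one histogram pooled over all cells, plus one
#' kernel density per plate (Gaussian kernel, Silverman's rule bandwidth) so
#' outlier chips are visible, and per-plate mean/median Ct. Not-detected
#' values are excluded from the distributions and counted separately.
#'
#' @param exp an `scx_experiment` at stage `raw_ct`.
#' @param control_genes character vector of genes on the panel.
#' @param n_bins number of histogram bins (default 30).
#' @return a list of class `scx_qc_summary`: per gene, `histogram`
#'   (`breaks`, `counts`), `densities` (per plate: `x`, `y`), `per_plate`
#'   (data.frame with `plate`, `n_detected`, `n_missing`, `mean_ct`,
#'   `median_ct`).
#' @export
control_gene_summary <- function(exp, control_genes, n_bins = 30) {
  assert_stage(exp, "raw_ct", "control_gene_summary")
  unknown <- setdiff(control_genes, exp$genes)
  if (length(unknown) > 0L)
    stop("control gene(s) not on panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- lapply(control_genes, function(g) {
    v <- exp$matrix[, g]
    det <- exp$detected[, g]
    pooled <- v[det]
    h <- if (length(pooled) > 0L)
      graphics::hist(pooled, breaks = n_bins, plot = FALSE)
    else list(breaks = numeric(), counts = integer())
    plates <- unique(exp$plates)
    dens <- lapply(plates, function(p) {
      pv <- v[det & exp$plates == p]
      if (length(pv) >= 2L && stats::sd(pv) > 0) {
        d <- stats::density(pv, bw = "nrd0", kernel = "gaussian")
        list(x = d$x, y = d$y)
      } else list(x = pv, y = rep(NA_real_, length(pv)))
    })
    names(dens) <- plates
    pp <- do.call(rbind, lapply(plates, function(p) {
      pv <- v[det & exp$plates == p]
      data.frame(plate = p, n_detected = length(pv),
                 n_missing = sum(exp$plates == p) - length(pv),
                 mean_ct = if (length(pv)) mean(pv) else NA_real_,
                 median_ct = if (length(pv)) stats::median(pv) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    list(gene = g, histogram = list(breaks = h$breaks, counts = h$counts),
         densities = dens, per_plate = pp)
  })
  names(out) <- control_genes
  structure(out, class = "scx_qc_summary")
}

# rule evaluation over all cells; returns logical pass vector
eval_rule <- function(exp, rule) {
  if (!rule$gene %in% exp$genes)
    stop("filter rule names unknown gene: ", rule$gene, call. = FALSE)
  det <- exp$detected[, rule$gene]
  ct <- exp$matrix[, rule$gene]
  pass <- ifelse(det, ct <= rule$max_ct, !rule$require_detected)
  unname(pass)
}

#' Remove cells failing control criteria
#'
#' Cells are kept iff the combinator over the rules holds; each removed cell
#' is reported with the first rule it failed. The grouping and index rows are
#' pruned consistently. An empty result is not an error but is flagged.
#'
#' @param exp an `scx_experiment` at stage `raw_ct`.
#' @param spec a [filter_spec()] (or a single [filter_rule()]).
#' @return list with `experiment` (filtered) and `removed` (data.frame with
#'   columns `cell`, `reason`).
#' @export
apply_cell_filter <- function(exp, spec) {
  assert_stage(exp, "raw_ct", "apply_cell_filter")
  if (inherits(spec, "scx_filter_rule")) spec <- filter_spec(spec)
  if (any(vapply(spec$rules, function(r) r$max_ct > exp$lod, logical(1))))
    stop("rule max_ct exceeds the LOD (", exp$lod, " cycles)", call. = FALSE)
  pass_mat <- vapply(spec$rules, function(r) eval_rule(exp, r),
                     logical(length(exp$cells)))
  pass_mat <- matrix(pass_mat, nrow = length(exp$cells))
  keep <- if (spec$combinator == "all") apply(pass_mat, 1, all)
          else apply(pass_mat, 1, any)
  removed_idx <- which(!keep)
  reason <- vapply(removed_idx, function(i) {
    j <- which(!pass_mat[i, ])[1]
    r <- spec$rules[[j]]
    if (exp$detected[i, r$gene])
      sprintf("%s Ct %.2f > %.2f", r$gene, exp$matrix[i, r$gene], r$max_ct)
    else sprintf("%s not detected", r$gene)
  }, "")
  removed <- data.frame(cell = exp$cells[removed_idx], reason = reason,
                        stringsAsFactors = FALSE)
  out <- subset_cells(exp, exp$cells[keep])
  if (length(out$cells) == 0L)
    out$flags <- c(out$flags, "all cells removed by filtering")
  out <- log_append(out, "apply_cell_filter",
                    params = list(rules = lapply(spec$rules, unclass),
                                  combinator = spec$combinator),
                    counts = list(n_removed = nrow(removed),
                                  n_kept = length(out$cells)))
  list(experiment = out, removed = removed)
}

#' Drop an entire plate
#'
#' @param exp an `scx_experiment`.
#' @param plate_id plate to remove (e.g. a technical-outlier chip).
#' @return the experiment without that plate's cells.
#' @export
drop_plate <- function(exp, plate_id) {
  if (!plate_id %in% exp$plates)
    stop("unknown plate: ", plate_id, call. = FALSE)
  n0 <- length(exp$cells)
  out <- subset_cells(exp, exp$cells[exp$plates != plate_id])
  if (length(out$cells) == 0L)
    out$flags <- c(out$flags, "all cells removed (last plate dropped)")
  log_append(out, "drop_plate", params = list(plate_id = plate_id),
             counts = list(n_removed = n0 - length(out$cells)))
}
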