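# The two-phase workflow as a single config-driven pipeline:
# import -> concatenate -> join index -> QC filter -> invert ->
# (optional housekeeping) -> z-transform -> embed + cluster -> group ->
# figures -> report -> archive. Every step appends one log entry; the config
# snapshot saved in the archive makes `replay()` reproduce the matrices
# exactly. The tool writes only inside the configured output directory.

#' Build a pipeline configuration
#'
#' @param expression_files data.frame (or list coercible to one) with columns
#'   `path`, `format` (`"table"`, `"heatmap"` or `"matrix"`), `plate_id`.
#' @param index_files optional data.frame with columns `path`, `plate_id`.
#' @param lod limit of detection in cycles.
#' @param filters list of [filter_rule()]s (or a [filter_spec()]); `NULL`
#'   skips filtering.
#' @param combinator filter combinator when `filters` is a list of rules.
#' @param hk_genes optional housekeeping genes; `NULL` skips that step.
#' @param z_axis `"per_gene"` or `"per_cell"`.
#' @param embed_method `"pca"`, `"isomap"` or `"lle"`.
#' @param embed_k embedding components.
#' @param n_neighbors neighbourhood size for isomap/lle.
#' @param cluster_method `"hclust"` or `"kmeans"`.
#' @param cluster_k number of groups.
#' @param linkage agglomeration rule for hclust.
#' @param cluster_on `"expression"` or `"index"`.
#' @param seed seed registered for all randomised steps.
#' @param violin_gene gene for the violin figure; default: first gene.
#' @param out_dir output directory for figures, report and archive.
#' @return a list of class `scx_config`.
#' @export
pipeline_config <- function(expression_files, index_files = NULL, lod = 40,
                            filters = NULL, combinator = "all",
                            hk_genes = NULL, z_axis = "per_gene",
                            embed_method = "pca", embed_k = 3,
                            n_neighbors = 10, cluster_method = "hclust",
                            cluster_k = 5, linkage = "complete",
                            cluster_on = "expression", seed = 0,
                            violin_gene = NULL, out_dir = tempfile("scx_out_")) {
  structure(list(expression_files = as.data.frame(expression_files),
                 index_files = if (!is.null(index_files)) as.data.frame(index_files),
                 lod = lod, filters = filters, combinator = combinator,
                 hk_genes = hk_genes, z_axis = z_axis,
                 embed_method = embed_method, embed_k = embed_k,
                 n_neighbors = n_neighbors, cluster_method = cluster_method,
                 cluster_k = cluster_k, linkage = linkage,
                 cluster_on = cluster_on, seed = seed,
                 violin_gene = violin_gene, out_dir = out_dir),
            class = "scx_config")
}

read_plate_any <- function(path, format, plate_id, lod) {
  switch(format,
         table = read_biomark_table(path, plate_id = plate_id, lod = lod),
         heatmap = read_biomark_heatmap(path, plate_id = plate_id, lod = lod),
         matrix = read_ct_matrix(path, plate_id = plate_id, lod = lod),
         stop("unknown expression file format: ", format, call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the documented stage order, logging each step, and writes the
#' figures, `report.html` and `session.zip` into `config$out_dir`.
#'
#' @param config an [pipeline_config()].
#' @return a session state: list with `experiment`, `scrapbook`, `config`,
#'   and `results` (embedding, assignment, figure objects).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "scx_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ef <- config$expression_files
  plates <- lapply(seq_len(nrow(ef)), function(i)
    read_plate_any(ef$path[i], ef$format[i], ef$plate_id[i], config$lod))
  exp <- concatenate_plates(plates)
  exp <- log_append(exp, "import",
                    params = list(files = ef$path, formats = ef$format),
                    counts = list(n_files = nrow(ef)))
  if (!is.null(config$index_files) && nrow(config$index_files) > 0) {
    tabs <- lapply(seq_len(nrow(config$index_files)), function(i)
      read_index_table(config$index_files$path[i],
                       plate_id = config$index_files$plate_id[i]))
    exp <- join_index(exp, tabs)
  } else {
    exp <- log_append(exp, "join_index_skipped",
                      counts = list(note = "no index files supplied"))
  }
  removed <- NULL
  if (!is.null(config$filters)) {
    spec <- if (inherits(config$filters, "scx_filter_spec")) config$filters
            else filter_spec(config$filters, config$combinator)
    fr <- apply_cell_filter(exp, spec)
    exp <- fr$experiment
    removed <- fr$removed
  }
  exp <- invert_ct(exp, config$lod)
  if (!is.null(config$hk_genes))
    exp <- normalize_housekeeping(exp, config$hk_genes)
  exp <- z_transform(exp, axis = config$z_axis)

  emb <- switch(config$embed_method,
                pca = pca_embed(exp$matrix, config$embed_k),
                isomap = isomap_embed(exp$matrix, config$embed_k,
                                      config$n_neighbors),
                lle = lle_embed(exp$matrix, config$embed_k, config$n_neighbors),
                stop("unknown embedding method: ", config$embed_method,
                     call. = FALSE))
  exp <- log_append(exp, "embed",
                    params = list(method = config$embed_method,
                                  k = config$embed_k),
                    counts = list(n_cells = length(exp$cells)))
  cl_mat <- if (config$cluster_on == "index") {
    if (is.null(exp$index)) stop("cluster_on='index' but no index data joined",
                                 call. = FALSE)
    m <- exp$index$matrix
    ok <- stats::complete.cases(m)
    if (any(!ok))
      warning(sum(!ok), " cell(s) with missing index markers excluded from ",
              "index clustering", call. = FALSE)
    m[ok, , drop = FALSE]
  } else exp$matrix
  assignment <- if (config$cluster_method == "kmeans") {
    kmeans_cluster(cl_mat, config$cluster_k, seed = config$seed)
  } else {
    tree <- hcluster(correlation_distance(cl_mat), config$linkage)
    cut_tree(tree, config$cluster_k)
  }
  exp <- log_append(exp, "cluster",
                    params = list(method = config$cluster_method,
                                  k = config$cluster_k,
                                  linkage = if (config$cluster_method == "hclust")
                                    config$linkage,
                                  seed = config$seed),
                    counts = list(n_groups = length(unique(assignment))))
  if (config$cluster_on == "index" && length(assignment) < length(exp$cells)) {
    # grouping must partition all cells: unclustered cells form a rest group
    rest <- setdiff(exp$cells, names(assignment))
    assignment <- c(assignment,
                    stats::setNames(rep(max(assignment) + 1L, length(rest)), rest))
  }
  exp$grouping <- groups_from_assignment(exp, assignment)
  exp <- log_append(exp, "group",
                    params = list(source = "cluster"),
                    counts = list(n_groups = length(exp$grouping$labels)))

  scrapbook <- new_scrapbook()
  gene <- if (!is.null(config$violin_gene)) config$violin_gene else exp$genes[1]
  vfig <- violin_figure(exp, gene, file = file.path(config$out_dir, "violin"))
  scrapbook <- scrapbook_add(scrapbook, vfig, paste("violin of", gene),
                             timestamp = "")
  hfig <- expression_heatmap(exp, file = file.path(config$out_dir, "heatmap_expr"))
  scrapbook <- scrapbook_add(scrapbook, hfig, "expression heatmap", timestamp = "")
  ifig <- NULL
  if (!is.null(exp$index)) {
    ifig <- index_heatmap(exp, hfig$layout,
                          file = file.path(config$out_dir, "heatmap_index"))
    scrapbook <- scrapbook_add(scrapbook, ifig, "index-marker heatmap",
                               timestamp = "")
  } else {
    exp <- log_append(exp, "index_heatmap_skipped",
                      counts = list(note = "no index data"))
  }
  sfig <- embedding_scatter(emb, exp$grouping, dims = min(2, config$embed_k),
                            file = file.path(config$out_dir, "scatter"))
  scrapbook <- scrapbook_add(scrapbook, sfig,
                             paste(config$embed_method, "scatter"),
                             timestamp = "")
  exp <- log_append(exp, "figures",
                    counts = list(n_figures = length(scrapbook$entries)))

  state <- list(experiment = exp, scrapbook = scrapbook,
                config = config_snapshot(config),
                results = list(embedding = emb, assignment = assignment,
                               removed = removed, violin = vfig,
                               heatmap = hfig, index_heatmap = ifig,
                               scatter = sfig))
  render_report(state, file.path(config$out_dir, "report.html"), timestamp = "")
  save_session(state, file.path(config$out_dir, "session.zip"))
  state
}

# serialisable snapshot of the config (rules flattened to plain lists)
config_snapshot <- function(config) {
  snap <- unclass(config)
  if (!is.null(snap$filters)) {
    spec <- if (inherits(snap$filters, "scx_filter_spec")) snap$filters
            else filter_spec(snap$filters, snap$combinator)
    snap$filters <- lapply(spec$rules, unclass)
    snap$combinator <- spec$combinator
  }
  snap
}

config_from_snapshot <- function(snap) {
  filters <- snap$filters
  if (is.data.frame(filters)) {          # JSON round-trip simplifies to a frame
    filters <- lapply(seq_len(nrow(filters)), function(i)
      filter_rule(filters$gene[i], filters$max_ct[i],
                  isTRUE(filters$require_detected[i])))
  } else if (!is.null(filters) && length(filters) > 0) {
    filters <- lapply(filters, function(r)
      filter_rule(r$gene, r$max_ct, isTRUE(r$require_detected)))
  } else filters <- NULL
  pipeline_config(
    expression_files = as.data.frame(snap$expression_files),
    index_files = if (!is.null(snap$index_files))
      as.data.frame(snap$index_files),
    lod = snap$lod, filters = filters,
    combinator = if (!is.null(snap$combinator)) snap$combinator else "all",
    hk_genes = unlist(snap$hk_genes), z_axis = snap$z_axis,
    embed_method = snap$embed_method, embed_k = snap$embed_k,
    n_neighbors = snap$n_neighbors, cluster_method = snap$cluster_method,
    cluster_k = snap$cluster_k, linkage = snap$linkage,
    cluster_on = snap$cluster_on, seed = snap$seed,
    violin_gene = unlist(snap$violin_gene), out_dir = snap$out_dir)
}

#' Resume a saved session
#'
#' @param archive_path a `session.zip` written by [save_session()] /
#'   [run_pipeline()].
#' @return the restored session state, with a `resume` entry appended to the
#'   log.
#' @export
resume <- function(archive_path) {
  state <- load_session(archive_path)
  state$experiment <- log_append(state$experiment, "resume",
                                 params = list(archive = basename(archive_path)))
  state
}

#' Replay a session's pipeline from its raw inputs
#'
#' Re-runs the config snapshot stored in the archive against the original
#' input files and returns the fresh state; because every randomised step
#' flows through the registered seed, the final matrices are reproduced
#' exactly.
#'
#' @param archive_path a session archive.
#' @param out_dir output directory for the replayed run (default: a fresh
#'   temporary directory, so the original outputs are untouched).
#' @return the replayed session state.
#' @export
replay <- function(archive_path, out_dir = tempfile("scx_replay_")) {
  state <- load_session(archive_path)
  if (is.null(state$config))
    stop("archive carries no config snapshot; cannot replay", call. = FALSE)
  config <- config_from_snapshot(state$config)
  config$out_dir <- out_dir
  run_pipeline(config)
}
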