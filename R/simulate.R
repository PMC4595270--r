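# Synthetic fixture generator. Emulates a multi-plate single-cell qRT-PCR
# study with index sorting and known group structure: group-specific marker
# genes shifted down in Ct (up in expression) by `effect_size` cycles,
# logistic dropout in true Ct, bright low-dropout control genes, a small
# fraction of cells with failed controls for QC tests, and log-normal
# index-marker intensities with per-group shifts. Files are written in the
# same dialects the readers parse, so generated data exercises the full
# import path.

#' Configuration for the experiment simulator
#'
#' Defaults emulate a 5-population study probed on a 96-gene chip: 60 cells
#' per group, 8 marker genes per group separated by 6 Ct cycles, baseline
#' Ct 26 +/- 1.5, logistic dropout centred at Ct 33, two bright control
#' genes, 5 index markers with a 1-decade log-intensity shift in the marked
#' group, LOD 40 cycles.
#'
#' @param n_groups number of true cell populations.
#' @param cells_per_group cells per population.
#' @param n_genes genes on the chip (default 96).
#' @param n_marker_genes_per_group group-specific marker genes.
#' @param effect_size Ct cycles by which marker genes are brighter in their
#'   group (lower Ct = higher expression).
#' @param baseline_mu,baseline_sigma baseline true-Ct distribution (cycles).
#' @param dropout_midpoint,dropout_slope logistic dropout in true Ct:
#'   P(missed) = plogis((ct - midpoint) * slope).
#' @param control_genes number of bright control genes (Ct ~ baseline - 10,
#'   near-zero dropout).
#' @param frac_failed_controls fraction of cells whose controls fail (their
#'   control entries become not-detected), for QC-filter tests.
#' @param n_index_markers surface markers in the index table; marker m is
#'   bright in group m.
#' @param index_effect per-group shift in log10 intensity.
#' @param compensation subtracted from intensities after sampling, so some
#'   values go negative (as after sorter compensation).
#' @param lod limit of detection in cycles.
#' @param seed RNG seed.
#' @return a list of class `scx_sim_config`.
#' @export
sim_config <- function(n_groups = 5, cells_per_group = 60, n_genes = 96,
                       n_marker_genes_per_group = 8, effect_size = 6,
                       baseline_mu = 26, baseline_sigma = 1.5,
                       dropout_midpoint = 33, dropout_slope = 1,
                       control_genes = 2, frac_failed_controls = 0.05,
                       n_index_markers = 5, index_effect = 1,
                       compensation = 50, lod = 40, seed = 1) {
  cfg <- list(n_groups = n_groups, cells_per_group = cells_per_group,
              n_genes = n_genes,
              n_marker_genes_per_group = n_marker_genes_per_group,
              effect_size = effect_size, baseline_mu = baseline_mu,
              baseline_sigma = baseline_sigma,
              dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope, control_genes = control_genes,
              frac_failed_controls = frac_failed_controls,
              n_index_markers = n_index_markers, index_effect = index_effect,
              compensation = compensation, lod = lod, seed = seed)
  stopifnot(n_groups >= 1, cells_per_group >= 1, n_genes >= 1,
            effect_size >= 0,
            n_genes >= n_groups * n_marker_genes_per_group + control_genes)
  structure(cfg, class = "scx_sim_config")
}

#' Simulate an experiment and write its input files
#'
#' Writes one expression file per plate (the first plate in the long "table"
#' dialect, remaining plates in the grid "heatmap" dialect, so both readers
#' are exercised), one index TSV per plate, and `truth.json` with the
#' generating parameters and true labels. Deterministic for a fixed seed.
#'
#' @param config an [sim_config()].
#' @param dir output directory (created if needed).
#' @return list of class `scx_sim`: `files` (`expression` data.frame with
#'   `path`, `format`, `plate_id`; `index` data.frame with `path`,
#'   `plate_id`; `truth` path) and `truth` (list with `labels` named by cell
#'   ID, `group_of_gene`, per-group true `mean_ct` and `mean_log_intensity`,
#'   `failed_control_cells`).
#' @export
simulate_experiment <- function(config = sim_config(), dir = tempfile("scx_sim_")) {
  stopifnot(inherits(config, "scx_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, simulate_experiment_impl(config, dir))
}

simulate_experiment_impl <- function(cfg, dir) {
  n_cells <- cfg$n_groups * cfg$cells_per_group
  # gene panel: group markers first, then fillers, controls last
  n_mk <- cfg$n_groups * cfg$n_marker_genes_per_group
  gene_names <- c(sprintf("Gene%03d", seq_len(cfg$n_genes - cfg$control_genes)),
                  sprintf("Ctrl%02d", seq_len(cfg$control_genes)))
  group_of_gene <- rep(NA_integer_, cfg$n_genes)
  group_of_gene[seq_len(n_mk)] <- rep(seq_len(cfg$n_groups),
                                      each = cfg$n_marker_genes_per_group)
  is_control <- seq_len(cfg$n_genes) > cfg$n_genes - cfg$control_genes

  # interleave groups across wells so plates mix populations
  labels <- rep(seq_len(cfg$n_groups), cfg$cells_per_group)
  wells_per_plate <- 96L
  n_plates <- ceiling(n_cells / wells_per_plate)
  plate_ids <- sprintf("P%d", seq_len(n_plates))
  all_wells <- as.vector(outer(sprintf("%02d", 1:12), LETTERS[1:8],
                               function(c, r) paste0(r, c)))
  plate_of_cell <- rep(plate_ids, each = wells_per_plate)[seq_len(n_cells)]
  well_of_cell <- rep(all_wells, n_plates)[seq_len(n_cells)]
  cell_ids <- make_cell_id(plate_of_cell, well_of_cell)

  # true Ct, dropout, observed matrix
  mu <- matrix(cfg$baseline_mu, n_cells, cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    if (!is.na(group_of_gene[g]))
      mu[labels == group_of_gene[g], g] <-
        cfg$baseline_mu - cfg$effect_size
    if (is_control[g]) mu[, g] <- cfg$baseline_mu - 10
  }
  true_ct <- mu + matrix(stats::rnorm(n_cells * cfg$n_genes,
                                      sd = cfg$baseline_sigma),
                         n_cells, cfg$n_genes)
  true_ct <- pmax(true_ct, 1)
  p_drop <- stats::plogis((true_ct - cfg$dropout_midpoint) * cfg$dropout_slope)
  p_drop[, is_control] <- 1e-6
  observed <- matrix(stats::runif(n_cells * cfg$n_genes),
                     n_cells, cfg$n_genes) > p_drop
  # a configurable fraction of cells get failed controls
  n_fail <- round(cfg$frac_failed_controls * n_cells)
  failed_cells <- if (n_fail > 0) sample(n_cells, n_fail) else integer()
  observed[failed_cells, is_control] <- FALSE
  ct_obs <- round(true_ct, 2)
  dimnames(ct_obs) <- list(cell_ids, gene_names)

  # index intensities: log-normal, marker m bright in group m
  n_markers <- cfg$n_index_markers
  marker_names <- sprintf("CD%d", 100 + seq_len(n_markers))
  logi <- matrix(stats::rnorm(n_cells * n_markers, mean = 2, sd = 0.3),
                 n_cells, n_markers)
  for (m in seq_len(min(n_markers, cfg$n_groups)))
    logi[labels == m, m] <- logi[labels == m, m] + cfg$index_effect
  intensity <- round(10^logi - cfg$compensation, 3)
  dimnames(intensity) <- list(cell_ids, marker_names)

  # write per-plate files
  exp_files <- data.frame(path = character(), format = character(),
                          plate_id = character(), stringsAsFactors = FALSE)
  idx_files <- data.frame(path = character(), plate_id = character(),
                          stringsAsFactors = FALSE)
  for (pi in seq_len(n_plates)) {
    pid <- plate_ids[pi]
    sel <- plate_of_cell == pid
    wells <- well_of_cell[sel]
    ct_p <- ct_obs[sel, , drop = FALSE]
    obs_p <- observed[sel, , drop = FALSE]
    fmt <- if (pi == 1L) "table" else "heatmap"
    path <- file.path(dir, paste0(pid, "_expression.", fmt, ".txt"))
    if (fmt == "table") {
      write_biomark_table_file(path, wells, gene_names, ct_p, obs_p)
    } else {
      write_biomark_heatmap_file(path, wells, gene_names, ct_p, obs_p)
    }
    exp_files <- rbind(exp_files,
                       data.frame(path = path, format = fmt, plate_id = pid,
                                  stringsAsFactors = FALSE))
    ipath <- file.path(dir, paste0(pid, "_index.txt"))
    write_index_file(ipath, wells, marker_names,
                     intensity[sel, , drop = FALSE])
    idx_files <- rbind(idx_files,
                       data.frame(path = ipath, plate_id = pid,
                                  stringsAsFactors = FALSE))
  }
  # per-group true mean Ct / log-intensity per gene and marker
  mean_ct <- t(vapply(seq_len(cfg$n_groups), function(k)
    colMeans(mu[labels == k, , drop = FALSE]), numeric(cfg$n_genes)))
  dimnames(mean_ct) <- list(paste0("group", seq_len(cfg$n_groups)), gene_names)
  mean_log_intensity <- t(vapply(seq_len(cfg$n_groups), function(k) {
    out <- rep(2, n_markers)
    if (k <= n_markers) out[k] <- out[k] + cfg$index_effect
    out
  }, numeric(n_markers)))
  dimnames(mean_log_intensity) <- list(rownames(mean_ct), marker_names)
  truth <- list(labels = stats::setNames(labels, cell_ids),
                group_of_gene = stats::setNames(group_of_gene, gene_names),
                mean_ct = mean_ct,
                mean_log_intensity = mean_log_intensity,
                failed_control_cells = cell_ids[sort(failed_cells)],
                config = unclass(cfg))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  structure(list(files = list(expression = exp_files, index = idx_files,
                              truth = truth_path),
                 truth = truth, dir = dir),
            class = "scx_sim")
}

# ---- fixture writers (the paired inverses of the io readers) ---------------

write_biomark_table_file <- function(path, wells, genes, ct, observed) {
  lines <- c("Chip Run Export", "Well\tGene\tCt\tCall")
  for (i in seq_along(wells)) {
    for (j in seq_along(genes)) {
      det <- observed[i, j]
      lines <- c(lines, paste(wells[i], genes[j],
                              if (det) format_num(ct[i, j]) else "999",
                              if (det) "Pass" else "Fail", sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_biomark_heatmap_file <- function(path, wells, genes, ct, observed) {
  vals <- matrix(format_num(ct), nrow(ct))
  vals[!observed] <- "999"
  lines <- c(paste(c("Well", genes), collapse = "\t"),
             vapply(seq_along(wells), function(i)
               paste(c(wells[i], vals[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

write_index_file <- function(path, wells, markers, intensity) {
  lines <- c(paste(c("Well", markers), collapse = "\t"),
             vapply(seq_along(wells), function(i)
               paste(c(wells[i], format_num(intensity[i, ])), collapse = "\t"),
               ""))
  writeLines(lines, path)
  invisible(path)
}

#' A tiny hand-checkable fixture with expected values at every stage
#'
#' Four wells by three genes (one control) plus two index markers. The
#' expected matrices after filtering (the one failing cell removed),
#' inversion and per-gene z-transform are stored as literals, computed by
#' hand / an independent one-off calculation, so every pipeline stage can be
#' checked against fixed numbers.
#'
#' @return a list with `plate` (`scx_plate`), `index` (`scx_index`),
#'   `filter` (the [filter_spec()] that removes exactly cell A04), and
#'   `expected` (matrices `after_filter_ct`, `after_invert`, `after_z`,
#'   plus `removed_cell`).
#' @export
worked_micro_fixture <- function() {
  genes <- c("Actb", "G1", "G2")
  wells <- c("A01", "A02", "A03", "A04")
  ct <- matrix(c(20, 25, NA,
                 21, 24, 30,
                 22, NA, 28,
                 26, 23, 27),
               nrow = 4, byrow = TRUE, dimnames = list(wells, genes))
  plate <- scx_plate("P1", wells, genes, ct, lod = 40)
  index <- structure(list(wells = wells, markers = c("CD55", "CD115"),
                          intensity = matrix(c(520.5, -12.3,
                                               310.0, 45.2,
                                               101.7, 88.8,
                                               250.1, 3.0),
                                             nrow = 4, byrow = TRUE,
                                             dimnames = list(wells,
                                                             c("CD55", "CD115"))),
                          plate_id = "P1"),
                     class = "scx_index")
  spec <- filter_spec(filter_rule("Actb", max_ct = 24, require_detected = TRUE))
  cells <- make_cell_id("P1", wells[1:3])
  after_filter_ct <- matrix(c(20, 25, NA,
                              21, 24, 30,
                              22, NA, 28),
                            nrow = 3, byrow = TRUE,
                            dimnames = list(cells, genes))
  after_invert <- matrix(c(20, 15, 0,
                           19, 16, 10,
                           18, 0, 12),
                         nrow = 3, byrow = TRUE,
                         dimnames = list(cells, genes))
  # per-gene z-scores of after_invert (sample sd), frozen from an
  # independent computation:
  #   Actb: mean 19, sd 1            -> { 1, 0, -1}
  #   G1:   mean 31/3, sd 8.9628864  -> computed below to 10 digits
  #   G2:   mean 22/3, sd 6.4291005
  after_z <- matrix(c(1,  0.5206656023, -1.1406468642,
                      0,  0.6322368028,  0.4147806779,
                     -1, -1.1529024051,  0.7258661863),
                    nrow = 3, byrow = TRUE, dimnames = list(cells, genes))
  list(plate = plate, index = index, filter = spec,
       expected = list(after_filter_ct = after_filter_ct,
                       after_invert = after_invert,
                       after_z = after_z,
                       removed_cell = make_cell_id("P1", "A04")))
}
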