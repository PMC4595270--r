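small_cfg <- function(...) {
  sim_config(n_groups = 3, cells_per_group = 15, n_genes = 24,
             n_marker_genes_per_group = 4, control_genes = 2,
             n_index_markers = 3, seed = 5, ...)
}

test_that("the simulator is byte-deterministic for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_experiment(small_cfg(), dir = d1)
  s2 <- simulate_experiment(small_cfg(), dir = d2)
  for (i in seq_len(nrow(s1$files$expression))) {
    expect_identical(readLines(s1$files$expression$path[i]),
                     readLines(s2$files$expression$path[i]))
  }
  expect_identical(readLines(s1$files$index$path[1]),
                   readLines(s2$files$index$path[1]))
  expect_identical(s1$truth$labels, s2$truth$labels)
})

test_that("generated files round-trip through the readers without discrepancy", {
  sim <- simulate_experiment(small_cfg(), dir = withr::local_tempdir())
  ef <- sim$files$expression
  plates <- lapply(seq_len(nrow(ef)), function(i)
    switch(ef$format[i],
           table = read_biomark_table(ef$path[i], plate_id = ef$plate_id[i]),
           heatmap = read_biomark_heatmap(ef$path[i], plate_id = ef$plate_id[i])))
  exp <- concatenate_plates(plates)
  expect_equal(length(exp$cells), 45L)
  expect_equal(length(exp$genes), 24L)
  expect_setequal(exp$cells, names(sim$truth$labels))
  # failed-control cells really have not-detected controls
  ctrl <- grep("^Ctrl", exp$genes, value = TRUE)
  for (cell in sim$truth$failed_control_cells)
    expect_true(all(!exp$detected[cell, ctrl]))
  # index tables join onto every cell
  tabs <- lapply(seq_len(nrow(sim$files$index)), function(i)
    read_index_table(sim$files$index$path[i],
                     plate_id = sim$files$index$plate_id[i]))
  joined <- join_index(exp, tabs)
  expect_false(anyNA(joined$index$matrix))
})

test_that("dropout is monotone non-decreasing in true Ct", {
  cfg <- sim_config(n_groups = 2, cells_per_group = 60, n_genes = 30,
                    n_marker_genes_per_group = 6, effect_size = 5,
                    baseline_mu = 31, baseline_sigma = 1, control_genes = 2,
                    frac_failed_controls = 0, n_index_markers = 2, seed = 8)
  sim <- simulate_experiment(cfg, dir = withr::local_tempdir())
  ef <- sim$files$expression
  plates <- lapply(seq_len(nrow(ef)), function(i)
    switch(ef$format[i],
           table = read_biomark_table(ef$path[i], plate_id = ef$plate_id[i]),
           heatmap = read_biomark_heatmap(ef$path[i], plate_id = ef$plate_id[i])))
  exp <- concatenate_plates(plates)
  # three true mean-Ct levels per (cell, gene): controls (mu-10), markers in
  # their own group (mu-5), baseline (mu). Empirical dropout must be
  # non-decreasing across those bins.
  truth_mu <- sim$truth$mean_ct[sim$truth$labels[exp$cells], exp$genes]
  det <- exp$detected
  rates <- vapply(sort(unique(as.vector(truth_mu))), function(m)
    1 - mean(det[truth_mu == m]), 0)
  expect_true(!is.unsorted(rates))
  expect_gt(rates[length(rates)], rates[1])
})

test_that("clustering recovery improves with effect size and is absent at 1 group", {
  aris <- vapply(c(0.5, 3, 6), function(es) {
    cfg <- sim_config(n_groups = 3, cells_per_group = 20, n_genes = 24,
                      n_marker_genes_per_group = 4, effect_size = es,
                      control_genes = 2, frac_failed_controls = 0, seed = 13)
    sim <- simulate_experiment(cfg, dir = withr::local_tempdir())
    ef <- sim$files$expression
    plates <- lapply(seq_len(nrow(ef)), function(i)
      switch(ef$format[i],
             table = read_biomark_table(ef$path[i], plate_id = ef$plate_id[i]),
             heatmap = read_biomark_heatmap(ef$path[i], plate_id = ef$plate_id[i])))
    exp <- suppressWarnings(z_transform(invert_ct(concatenate_plates(plates))))
    cl <- cut_tree(hcluster(correlation_distance(exp$matrix)), 3)
    adjusted_rand_index(cl, sim$truth$labels[exp$cells])
  }, 0)
  expect_true(!is.unsorted(aris))
  expect_gt(aris[3], 0.9)

  # single population: k-means at k=3 agrees with random labels at ARI ~ 0
  cfg1 <- sim_config(n_groups = 1, cells_per_group = 60, n_genes = 24,
                     n_marker_genes_per_group = 1, effect_size = 0,
                     control_genes = 2, frac_failed_controls = 0, seed = 21)
  sim1 <- simulate_experiment(cfg1, dir = withr::local_tempdir())
  ef <- sim1$files$expression
  plates <- lapply(seq_len(nrow(ef)), function(i)
    read_biomark_table(ef$path[i], plate_id = ef$plate_id[i]))
  exp1 <- suppressWarnings(z_transform(invert_ct(concatenate_plates(plates))))
  set.seed(99)
  aris0 <- replicate(20, {
    cl <- kmeans_cluster(exp1$matrix, 3, seed = sample.int(1e6, 1))
    adjusted_rand_index(cl, sample(3, length(cl), TRUE))
  })
  expect_lt(mean(abs(aris0)), 0.1)
})

test_that("the worked micro-fixture matches its stored literals at every stage", {
  fx <- worked_micro_fixture()
  exp <- concatenate_plates(fx$plate)
  exp <- join_index(exp, fx$index)
  res <- apply_cell_filter(exp, fx$filter)
  expect_identical(res$removed$cell, fx$expected$removed_cell)
  expect_identical(res$experiment$matrix, fx$expected$after_filter_ct)
  inv <- invert_ct(res$experiment)
  expect_identical(inv$matrix, fx$expected$after_invert)
  z <- z_transform(inv)
  expect_equal(z$matrix, fx$expected$after_z, tolerance = 1e-9)
  # index intensities survive the join, including the negative one
  expect_equal(unname(res$experiment$index$matrix["P1:A01", "CD115"]), -12.3)
})
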