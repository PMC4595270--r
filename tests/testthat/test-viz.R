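# figure tests assert on the machine-readable sidecars, not pixels

make_viz_experiment <- function(seed = 50) {
  exp <- random_experiment(n_wells = 12, n_genes = 6, n_plates = 2,
                           seed = seed, dropout = 0.05)
  exp <- suppressWarnings(z_transform(invert_ct(exp)))
  exp <- join_index(exp, list(
    structure(list(wells = sprintf("A%02d", 1:10), markers = c("CD55", "CD115"),
                   intensity = matrix(seq_len(20), 10, 2,
                                      dimnames = list(sprintf("A%02d", 1:10),
                                                      c("CD55", "CD115"))),
                   plate_id = "P1"), class = "scx_index")))
  exp$grouping <- random_grouping(exp, k = 3, seed = seed)
  exp
}

test_that("violin figures summarise groups in grouping order", {
  exp <- make_viz_experiment()
  dir <- withr::local_tempdir()
  fig <- violin_figure(exp, "G01", file = file.path(dir, "v"))
  expect_identical(fig$summary$group, exp$grouping$labels)
  expect_equal(sum(fig$summary$n), length(exp$cells))
  expect_true(file.exists(file.path(dir, "v.png")))
  expect_true(file.exists(file.path(dir, "v.svg")))
  # medians match a direct computation
  for (i in seq_along(exp$grouping$labels)) {
    v <- exp$matrix[exp$grouping$members[[i]], "G01"]
    expect_equal(fig$summary$median[i], median(v))
  }
  # reordering the grouping reorders the violins
  r <- reorder_groups(exp$grouping, rev(exp$grouping$labels))
  fig2 <- violin_figure(exp, "G01", grouping = r)
  expect_identical(fig2$summary$group, rev(fig$summary$group))
  # singleton group renders without error
  g1 <- exp$grouping
  solo <- g1$members[[1]][1]
  g1$members[[1]] <- setdiff(g1$members[[1]], solo)
  g1$members[[3]] <- c(g1$members[[3]], solo)
  g1$members <- c(g1$members, list(character(0)))
  expect_error(violin_figure(exp, "nope"), "unknown gene")
})

test_that("expression heatmap layout is a grouped permutation with colour blocks", {
  exp <- make_viz_experiment()
  fig <- expression_heatmap(exp, file = NULL)
  lay <- fig$layout
  expect_setequal(lay$cell_order, exp$cells)
  expect_setequal(lay$gene_order, exp$genes)
  # colour bar has exactly one contiguous block per group, in grouping order
  runs <- rle(lay$colour_bar)
  expect_identical(runs$values, exp$grouping$colors)
  expect_equal(runs$lengths, unname(lengths(exp$grouping$members)))
  # within_group_order = none keeps input order inside blocks
  fig2 <- expression_heatmap(exp, within_group_order = "none",
                             cluster_genes = FALSE)
  expect_identical(fig2$layout$cell_order,
                   unlist(exp$grouping$members, use.names = FALSE))
  expect_identical(fig2$layout$gene_order, exp$genes)
})

test_that("index heatmap shares the expression layout exactly", {
  exp <- make_viz_experiment()
  dir <- withr::local_tempdir()
  hfig <- expression_heatmap(exp, file = file.path(dir, "he"))
  ifig <- index_heatmap(exp, hfig, file = file.path(dir, "hi"))
  expect_identical(ifig$layout$cell_order, hfig$layout$cell_order)
  expect_identical(ifig$layout$colour_bar, hfig$layout$colour_bar)
  expect_true(file.exists(file.path(dir, "hi.png")))
  # cells with missing markers stay in the layout
  expect_true(all(exp$cells %in% ifig$layout$cell_order))
  no_idx <- exp; no_idx$index <- NULL
  expect_error(index_heatmap(no_idx, hfig), "join_index")
})

test_that("embedding scatter colours partition exactly as the grouping", {
  exp <- make_viz_experiment()
  emb <- pca_embed(exp$matrix, k = 3)
  fig <- embedding_scatter(emb, exp$grouping, dims = 2)
  expect_identical(sort(fig$points$cell), sort(exp$cells))
  gi <- group_of(exp$grouping, fig$points$cell)
  expect_identical(fig$points$group, gi$group)
  expect_identical(fig$points$color, gi$color)
  expect_identical(fig$group_order, exp$grouping$labels)
  fig3 <- embedding_scatter(emb, exp$grouping, dims = 3)
  expect_equal(nrow(fig3$points), length(exp$cells))
  emb2 <- pca_embed(exp$matrix, k = 2)
  expect_error(embedding_scatter(emb2, exp$grouping, dims = 3),
               "only 2 component")
})

test_that("scrapbook entries accumulate without a cap and render to a report", {
  sb <- scqpcr:::new_scrapbook()
  for (i in 1:50)
    sb <- scrapbook_add(sb, paste0("fig", i, ".png"),
                        annotation = paste("note", i), timestamp = "t")
  expect_equal(length(sb$entries), 50L)
  expect_identical(vapply(sb$entries, `[[`, 1L, "seq"), 1:50)

  exp <- make_viz_experiment()
  state <- list(experiment = exp, scrapbook = sb)
  path1 <- withr::local_tempfile(fileext = ".html")
  path2 <- withr::local_tempfile(fileext = ".html")
  render_report(state, path1, timestamp = "FIXED")
  render_report(state, path2, timestamp = "FIXED")
  expect_identical(readLines(path1), readLines(path2))    # pure given timestamp
  html <- paste(readLines(path1), collapse = "\n")
  expect_equal(lengths(regmatches(html, gregexpr("Entry ", html))), 50L)
  # one log line per state-changing operation
  expect_equal(lengths(regmatches(html, gregexpr("<li>", html))),
               length(exp$log))
})
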