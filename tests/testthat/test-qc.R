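test_that("control summaries histogram pooled cells and densify per plate", {
  p1 <- scx_plate("P1", sprintf("A%02d", 1:6), c("Actb", "G1"),
                  cbind(Actb = rep(20, 6), G1 = 21:26), lod = 40)
  exp <- concatenate_plates(p1)
  s <- control_gene_summary(exp, "Actb")
  expect_equal(sum(s$Actb$histogram$counts), 6L)     # all detected, one plate
  expect_equal(s$Actb$per_plate$n_detected, 6L)
  # degenerate distribution: all Ct equal -> single occupied bin
  expect_equal(sum(s$Actb$histogram$counts > 0), 1L)
  expect_error(control_gene_summary(exp, "NotAGene"), "NotAGene")

  # two plates shifted by +4 cycles: per-plate means differ by ~4
  set.seed(3)
  base <- rnorm(40, 22, 0.3)
  p_a <- scx_plate("PA", sprintf("A%02d", 1:8), "Actb",
                   matrix(base[1:8], 8), lod = 40)
  p_b <- scx_plate("PB", sprintf("A%02d", 1:8), "Actb",
                   matrix(base[9:16] + 4, 8), lod = 40)
  s2 <- control_gene_summary(concatenate_plates(list(p_a, p_b)), "Actb")
  pp <- s2$Actb$per_plate
  expect_equal(pp$mean_ct[pp$plate == "PB"] - pp$mean_ct[pp$plate == "PA"],
               4, tolerance = 0.5)
  # independently recomputed means match the summary
  expect_equal(pp$mean_ct[pp$plate == "PA"], mean(base[1:8]))
})

test_that("cell filter applies rules, reports reasons, prunes consistently", {
  p <- scx_plate("P1", c("A01", "A02", "A03"), c("Actb", "G1"),
                 matrix(c(18, 25, NA, 20, 21, 22), 3), lod = 40)
  exp <- concatenate_plates(p)
  exp <- join_index(exp, structure(
    list(wells = c("A01", "A02", "A03"), markers = "CD55",
         intensity = matrix(1:3, 3, 1,
                            dimnames = list(c("A01", "A02", "A03"), "CD55")),
         plate_id = "P1"), class = "scx_index"))
  res <- apply_cell_filter(exp, filter_rule("Actb", 24, TRUE))
  expect_identical(res$experiment$cells, "P1:A01")
  expect_setequal(res$removed$cell, c("P1:A02", "P1:A03"))
  expect_match(res$removed$reason[res$removed$cell == "P1:A02"], "Ct 25")
  expect_match(res$removed$reason[res$removed$cell == "P1:A03"], "not detected")
  # index rows pruned with the cells
  expect_identical(rownames(res$experiment$index$matrix), "P1:A01")

  # vacuous threshold keeps everything detected
  res2 <- apply_cell_filter(exp, filter_rule("G1", 40, TRUE))
  expect_equal(length(res2$experiment$cells), 3L)

  # filtering only applies before inversion
  inv <- invert_ct(exp)
  expect_error(apply_cell_filter(inv, filter_rule("Actb", 24)),
               "requires stage raw_ct")
})

test_that("removed set is monotone in max_ct and filtering is idempotent", {
  exp <- random_experiment(n_wells = 40, n_genes = 6, seed = 99)
  removed_at <- function(th) {
    apply_cell_filter(exp, filter_rule("G01", th, TRUE))$removed$cell
  }
  # brute-force evaluation over a threshold ladder
  ths <- c(18, 20, 24, 28, 34)
  sets <- lapply(ths, removed_at)
  for (i in seq_along(ths)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # independent oracle: direct rule evaluation per cell
  th <- 24
  manual <- exp$cells[!(exp$detected[, "G01"] &
                          !is.na(exp$matrix[, "G01"]) &
                          exp$matrix[, "G01"] <= th)]
  expect_setequal(removed_at(th), manual)
  # idempotence: second application removes nothing
  once <- apply_cell_filter(exp, filter_rule("G01", th, TRUE))$experiment
  twice <- apply_cell_filter(once, filter_rule("G01", th, TRUE))
  expect_equal(nrow(twice$removed), 0L)
  expect_identical(twice$experiment$cells, once$cells)
  # removed + kept partitions the original cells
  expect_setequal(c(once$cells, removed_at(th)), exp$cells)
})

test_that("combinators differ where expected", {
  p <- scx_plate("P1", c("A01", "A02"), c("C1", "C2"),
                 matrix(c(20, 30, 30, 20), 2), lod = 40)
  exp <- concatenate_plates(p)
  rules <- list(filter_rule("C1", 24), filter_rule("C2", 24))
  all_res <- apply_cell_filter(exp, filter_spec(rules, "all"))
  any_res <- apply_cell_filter(exp, filter_spec(rules, "any"))
  expect_equal(length(all_res$experiment$cells), 0L)   # each cell fails one rule
  expect_equal(length(any_res$experiment$cells), 2L)   # each passes one rule
  expect_true(any(grepl("all cells removed",
                        all_res$experiment$flags)))
})

test_that("drop_plate removes exactly one plate's cells", {
  exp <- random_experiment(n_wells = 10, n_genes = 4, n_plates = 2, seed = 5)
  out <- drop_plate(exp, "P1")
  expect_equal(length(out$cells), 10L)
  expect_true(all(out$plates == "P2"))
  expect_error(drop_plate(exp, "P9"), "unknown plate")
  empty <- drop_plate(drop_plate(exp, "P1"), "P2")
  expect_equal(length(empty$cells), 0L)
  expect_true(any(grepl("all cells removed", empty$flags)))
})
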