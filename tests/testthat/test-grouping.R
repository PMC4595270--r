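test_that("plate grouping mirrors plate order with distinct colours", {
  exp <- random_experiment(n_wells = 6, n_genes = 3, n_plates = 3, seed = 1)
  g <- groups_from_plates(exp)
  expect_identical(g$labels, c("P1", "P2", "P3"))
  expect_equal(lengths(g$members), rep(6L, 3))
  expect_valid_partition(g, exp)
  single <- random_experiment(n_wells = 4, n_plates = 1, seed = 2)
  g1 <- groups_from_plates(single)
  expect_equal(length(g1$labels), 1L)
  expect_setequal(g1$members[[1]], single$cells)
})

test_that("assignment grouping orders clusters and validates coverage", {
  exp <- random_experiment(n_wells = 10, seed = 3)
  assign <- setNames(rep(c(2L, 1L), 5), exp$cells)
  g <- groups_from_assignment(exp, assign)
  expect_identical(g$labels, c("cluster 1", "cluster 2"))
  expect_valid_partition(g, exp)
  all_one <- setNames(rep(1L, 10), exp$cells)
  expect_equal(length(groups_from_assignment(exp, all_one)$labels), 1L)
  expect_error(groups_from_assignment(exp, assign[-1]), "exactly")
})

test_that("1-D binning uses half-open intervals, upper bin at the boundary", {
  p <- scx_plate("P1", c("A01", "A02", "A03"), "G1",
                 matrix(c(40, 35, 28), 3), lod = 40)
  exp <- invert_ct(concatenate_plates(p))         # values 0, 5, 12
  g <- groups_1d(exp, "G1", 10)
  expect_equal(lengths(g$members), c(2L, 1L))
  expect_valid_partition(g, exp)
  g2 <- groups_1d(exp, "G1", c(3, 9))
  expect_equal(lengths(g2$members), c(1L, 1L, 1L))
  # value exactly at a cutoff goes up
  g3 <- groups_1d(exp, "G1", 5)
  expect_true("P1:A02" %in% g3$members[[2]])
  # unsorted cutoffs warn and sort; unknown gene errors
  expect_warning(g4 <- groups_1d(exp, "G1", c(9, 3)), "sorting")
  expect_identical(lengths(g4$members), lengths(g2$members))
  expect_error(groups_1d(exp, "nope", 1), "unknown gene")
  # refinement: adding cutoffs only splits existing bins
  exp_big <- suppressWarnings(invert_ct(random_experiment(n_wells = 30, seed = 44)))
  coarse <- groups_1d(exp_big, "G01", 10)
  fine <- groups_1d(exp_big, "G01", c(5, 10, 15))
  for (fm in fine$members) {
    inside <- vapply(coarse$members, function(cm) all(fm %in% cm), logical(1))
    expect_equal(sum(inside), 1L)
  }
})

test_that("2-D gates are inclusive, first-wins, with an automatic rest group", {
  p <- scx_plate("P1", sprintf("A%02d", 1:4), c("Gx", "Gy"),
                 cbind(Gx = c(30, 20, 10, 35), Gy = c(30, 20, 10, 35)), lod = 40)
  exp <- invert_ct(concatenate_plates(p))         # coords (10,10),(20,20),(30,30),(5,5)
  full <- gate2d("Gx", "Gy", -Inf, Inf, -Inf, Inf)
  g <- groups_2d(exp, full)
  expect_equal(length(g$labels), 1L)              # no rest group
  expect_valid_partition(g, exp)
  # boundary cell included; overlap resolved to the first gate
  g2 <- groups_2d(exp, list(gate2d("Gx", "Gy", 10, 20, 10, 20, label = "low"),
                            gate2d("Gx", "Gy", 20, 30, 20, 30, label = "high")))
  expect_identical(g2$labels, c("low", "high", "rest"))
  expect_setequal(g2$members[[1]], c("P1:A01", "P1:A02"))  # (20,20) -> first gate
  expect_identical(g2$members[[2]], "P1:A03")
  expect_identical(g2$members[[3]], "P1:A04")
  expect_valid_partition(g2, exp)
  expect_error(groups_2d(exp, gate2d("Gx", "nope")), "unknown gene")
  expect_error(gate2d("a", "b", x_min = 2, x_max = 1), "min <= max")
})

test_that("merge keeps position and cell count; reorder keeps colours attached", {
  exp <- random_experiment(n_wells = 12, seed = 10)
  g <- random_grouping(exp, k = 3)
  m <- merge_groups(g, c("g1", "g2"), "g12")
  expect_identical(m$labels, c("g12", "g3"))
  expect_equal(length(m$members[[1]]),
               length(g$members[[1]]) + length(g$members[[2]]))
  expect_valid_partition(m, exp)
  all_merged <- merge_groups(g, c("g1", "g2", "g3"), "all")
  expect_equal(length(all_merged$labels), 1L)
  expect_setequal(all_merged$members[[1]], exp$cells)
  expect_error(merge_groups(g, c("g1", "nope"), "x"), "unknown group label")

  r <- reorder_groups(g, rev(g$labels))
  expect_identical(r$labels, rev(g$labels))
  expect_identical(r$colors, rev(g$colors))        # colours travel
  expect_identical(r$members, rev(g$members))
  expect_identical(reorder_groups(g, g$labels)$members, g$members)
  expect_error(reorder_groups(g, c("g1", "g2", "zzz")), "permutation")
  expect_error(reorder_groups(g, c("g1", "g2")), "permutation")
})

test_that("merge and reorder commute when compatible (random groupings)", {
  for (seed in 1:5) {
    exp <- random_experiment(n_wells = 15, seed = seed)
    g <- random_grouping(exp, k = 4, seed = seed)
    # reorder that keeps merged members adjacent in label space
    perm <- c("g3", "g4", "g1", "g2")
    a <- reorder_groups(merge_groups(g, c("g1", "g2"), "m"),
                        c("g3", "g4", "m"))
    b <- merge_groups(reorder_groups(g, perm), c("g1", "g2"), "m")
    b2 <- reorder_groups(b, c("g3", "g4", "m"))
    expect_identical(lapply(a$members, sort), lapply(b2$members, sort))
    expect_identical(a$labels, b2$labels)
  }
})

test_that("the palette cycles uniquely past 12 groups", {
  cols <- scx_palette(30)
  expect_equal(length(cols), 30L)
  expect_false(anyDuplicated(cols) > 0)
})
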