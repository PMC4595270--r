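# In-code fixtures shared across test files.

# a small random experiment at raw_ct stage, built through the public API
random_experiment <- function(n_wells = 8, n_genes = 5, n_plates = 1,
                              seed = 42, lod = 40, dropout = 0.15) {
  set.seed(seed)
  plates <- lapply(seq_len(n_plates), function(p) {
    wells <- sprintf("A%02d", seq_len(n_wells))
    genes <- sprintf("G%02d", seq_len(n_genes))
    ct <- matrix(round(runif(n_wells * n_genes, 15, 35), 2), n_wells)
    ct[matrix(runif(n_wells * n_genes) < dropout, n_wells)] <- NA
    scx_plate(paste0("P", p), wells, genes, ct, lod = lod)
  })
  concatenate_plates(plates)
}

# an experiment taken through invert + z, ready for embedding/clustering
random_z_experiment <- function(...) {
  exp <- random_experiment(...)
  suppressWarnings(z_transform(invert_ct(exp)))
}

# a random grouping over the experiment's cells
random_grouping <- function(exp, k = 3, seed = 1) {
  set.seed(seed)
  idx <- sample(rep(seq_len(k), length.out = length(exp$cells)))
  members <- lapply(seq_len(k), function(i) exp$cells[idx == i])
  keep <- lengths(members) > 0
  scqpcr:::new_grouping(paste0("g", seq_len(k))[keep],
                        scx_palette(k)[keep], members[keep], "cluster")
}

expect_valid_partition <- function(grouping, exp) {
  members <- unlist(grouping$members)
  expect_setequal(members, exp$cells)
  expect_equal(length(members), length(exp$cells))   # disjoint
  expect_false(anyDuplicated(grouping$colors) > 0)
}

# brute-force O(n^2) correlation-distance oracle, independent of the
# implementation under test
brute_cor_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- m[i, ]; xj <- m[j, ]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    d[i, j] <- 1 - r
  }
  diag(d) <- 0
  d
}
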