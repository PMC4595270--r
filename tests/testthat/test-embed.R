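test_that("correlation distance matches a brute-force Pearson oracle", {
  set.seed(12)
  m <- matrix(rnorm(20), 5, 4)
  d <- correlation_distance(m)
  expect_s3_class(d, "scx_dist")
  expect_equal(d$matrix, brute_cor_dist(m), tolerance = 1e-12)
  expect_equal(diag(d$matrix), rep(0, 5))
  expect_equal(d$matrix, t(d$matrix), tolerance = 1e-12)
  expect_true(all(d$matrix >= -1e-12 & d$matrix <= 2 + 1e-12))
  # identical rows and anti-correlated rows hit the extremes
  m2 <- rbind(1:4, 1:4, 4:1)
  d2 <- correlation_distance(m2)$matrix
  expect_equal(d2[1, 2], 0, tolerance = 1e-12)
  expect_equal(d2[1, 3], 2, tolerance = 1e-12)
  # zero-variance rows are an error naming the offender
  m3 <- rbind(A = c(1, 1, 1), B = c(1, 2, 3))
  expect_error(correlation_distance(m3), "A")
})

test_that("correlation distance is invariant to positive affine row maps", {
  set.seed(4)
  m <- matrix(rnorm(40), 8, 5)
  d0 <- correlation_distance(m)$matrix
  m2 <- m
  m2[1, ] <- m[1, ] * 2.5 + 7
  expect_equal(correlation_distance(m2)$matrix, d0, tolerance = 1e-12)
})

test_that("hierarchical clustering recovers a 2-block structure for all linkages", {
  set.seed(9)
  blob <- function(center, n) sweep(matrix(rnorm(n * 3, sd = 0.05), n), 2,
                                    center, `+`)
  m <- rbind(blob(c(0, 0, 0), 10), blob(c(10, 10, 10), 10))
  rownames(m) <- paste0("c", 1:20)
  truth <- rep(1:2, each = 10)
  d <- euclidean_distance(m)
  for (lk in c("single", "complete", "average", "ward")) {
    tree <- hcluster(d, lk)
    cut <- cut_tree(tree, 2)
    expect_equal(adjusted_rand_index(cut, truth), 1, info = lk)
    # monotone heights for the monotone linkages
    if (lk != "ward")
      expect_true(!is.unsorted(tree$hclust$height), info = lk)
  }
  tree <- hcluster(correlation_distance(m), "complete")
  expect_equal(length(unique(cut_tree(tree, 1))), 1L)
  expect_equal(length(unique(cut_tree(tree, 20))), 20L)
  expect_error(cut_tree(tree, 21), "between 1 and")
  expect_error(cut_tree(tree, 0), "between 1 and")
})

test_that("kmeans is seeded, deterministic, and recovers separated blobs", {
  set.seed(14)
  m <- rbind(matrix(rnorm(40, 0, 0.1), 20),
             matrix(rnorm(40, 5, 0.1), 20),
             matrix(rnorm(40, 10, 0.1), 20))
  rownames(m) <- paste0("c", 1:60)
  truth <- rep(1:3, each = 20)
  a1 <- kmeans_cluster(m, 3, seed = 0, restarts = 10)
  expect_equal(adjusted_rand_index(a1, truth), 1)
  a2 <- kmeans_cluster(m, 3, seed = 0, restarts = 10)
  expect_identical(unname(a1), unname(a2))
  expect_identical(names(a1), rownames(m))
  expect_error(kmeans_cluster(m, 61), "exceeds")
  expect_error(kmeans_cluster(m, 0), "at least 1")
  # the seeded call does not disturb the caller's RNG stream
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(kmeans_cluster(m, 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("ARI is symmetric, 1 on identical partitions, ~0 for noise", {
  set.seed(6)
  a <- sample(3, 50, TRUE); b <- sample(3, 50, TRUE)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  aris <- replicate(20, adjusted_rand_index(sample(3, 200, TRUE),
                                            sample(3, 200, TRUE)))
  expect_true(mean(abs(aris)) < 0.1)
  expect_error(adjusted_rand_index(a, b[-1]), "length")
})

test_that("PCA matches an independent covariance eigendecomposition", {
  set.seed(21)
  m <- matrix(rnorm(24), 6, 4)
  emb <- pca_embed(m, k = 4)
  # oracle: eigenvectors of the covariance of the centred data
  cm <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(cm), symmetric = TRUE)
  oracle <- cm %*% eig$vectors
  for (j in 1:4) {
    # per-component sign is arbitrary
    expect_lt(min(max(abs(emb$coords[, j] - oracle[, j])),
                  max(abs(emb$coords[, j] + oracle[, j]))), 1e-8)
  }
  # component variances non-increasing; total variance conserved at full rank
  v <- apply(emb$coords, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  expect_equal(sum(v), sum(apply(cm, 2, var)), tolerance = 1e-8)
  # loadings orthonormal
  rot <- emb$params$rotation
  expect_equal(unname(t(rot) %*% rot), diag(4), tolerance = 1e-8)
  # rank-1 data puts all variance on PC1
  line <- cbind(1:10, 2 * (1:10))
  emb2 <- pca_embed(line, k = 2)
  v2 <- apply(emb2$coords, 2, var)
  expect_equal(unname(v2[2]), 0, tolerance = 1e-10)
  expect_error(pca_embed(m, 7), "between 1 and")
})

test_that("isomap unrolls an S-curve and validates its inputs", {
  set.seed(30)
  n <- 200
  t_par <- sort(runif(n, -1.5 * pi, 1.5 * pi))   # arc-length ordering known
  x <- cbind(sin(t_par), 2 * runif(n), sign(t_par) * (cos(t_par) - 1))
  rownames(x) <- paste0("p", 1:n)
  emb <- isomap_embed(x, k = 1, n_neighbors = 10)
  expect_equal(dim(emb$coords), c(n, 1L))
  rho <- cor(emb$coords[, 1], t_par, method = "spearman")
  expect_gte(abs(rho), 0.95)
  expect_error(isomap_embed(x, k = 1, n_neighbors = n), "smaller than")
  # two far-apart blobs: neighbourhood graph disconnected
  y <- rbind(matrix(rnorm(30, 0, 0.01), 10),
             matrix(rnorm(30, 100, 0.01), 10))
  expect_error(isomap_embed(y, k = 1, n_neighbors = 3), "n_neighbors")
})

test_that("LLE returns well-shaped, ordered coordinates on a curve", {
  set.seed(31)
  n <- 120
  t_par <- sort(runif(n, 0, 2 * pi))
  x <- cbind(cos(t_par), sin(t_par), t_par / 3) +
    matrix(rnorm(n * 3, sd = 0.01), n)
  rownames(x) <- paste0("p", 1:n)
  emb <- lle_embed(x, k = 2, n_neighbors = 12)
  expect_equal(dim(emb$coords), c(n, 2L))
  expect_identical(rownames(emb$coords), rownames(x))
  expect_error(lle_embed(x, k = 2, n_neighbors = n), "smaller than")
  # deterministic: same inputs, same output
  emb2 <- lle_embed(x, k = 2, n_neighbors = 12)
  expect_identical(emb$coords, emb2$coords)
})
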