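# Dimensionality reduction and clustering. Cells are rows throughout.
# Hierarchical clustering uses correlation distance (1 - Pearson r between
# expression profiles) by default, with a choice of agglomeration rule;
# k-means and three embeddings (PCA, Isomap, LLE) complete the toolbox and
# apply equally to expression and index-marker matrices.

#' Pairwise correlation distance between rows
#'
#' `d_ij = 1 - r(row_i, row_j)` with Pearson correlation (Spearman available
#' as an option). Entries lie in `[0, 2]`.
#'
#' @param matrix numeric matrix, observations in rows.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return an object of class `scx_dist`: list with `matrix` (n x n,
#'   zero-diagonal, symmetric) and `metric`.
#' @export
correlation_distance <- function(matrix, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L) stop("need at least two rows", call. = FALSE)
  rv <- apply(matrix, 1, stats::sd)
  if (any(rv == 0)) {
    bad <- rownames(matrix)[rv == 0]
    if (is.null(bad)) bad <- which(rv == 0)
    stop("zero-variance row(s) (should have been filtered): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(t(matrix), method = method)
  diag(d) <- 0
  structure(list(matrix = d, metric = paste0(method, "_correlation")),
            class = "scx_dist")
}

#' Euclidean distance wrapped as an `scx_dist`
#'
#' @param matrix numeric matrix, observations in rows.
#' @return an `scx_dist` with metric `"euclidean"`.
#' @export
euclidean_distance <- function(matrix) {
  d <- as.matrix(stats::dist(as.matrix(matrix)))
  structure(list(matrix = d, metric = "euclidean"), class = "scx_dist")
}

#' Agglomerative hierarchical clustering
#'
#' @param dist an `scx_dist` (see [correlation_distance()]).
#' @param linkage `"single"`, `"complete"` (default, the classical companion
#'   of correlation distance), `"average"` or `"ward"`. Ward is intended for
#'   squared-Euclidean distances on z-scores; using it with another metric
#'   triggers a warning.
#' @return an object of class `scx_tree` wrapping the `hclust` merge
#'   sequence, with `linkage` and `metric` labels.
#' @export
hcluster <- function(dist, linkage = c("complete", "single", "average", "ward")) {
  stopifnot(inherits(dist, "scx_dist"))
  linkage <- match.arg(linkage)
  if (linkage == "ward" && dist$metric != "euclidean")
    warning("ward linkage assumes (squared-)Euclidean distances on z-scores; ",
            "metric is '", dist$metric, "'", call. = FALSE)
  method <- c(complete = "complete", single = "single",
              average = "average", ward = "ward.D2")[[linkage]]
  hc <- stats::hclust(stats::as.dist(dist$matrix), method = method)
  structure(list(hclust = hc, linkage = linkage, metric = dist$metric),
            class = "scx_tree")
}

#' Cut a cluster tree into k groups
#'
#' @param tree an `scx_tree` from [hcluster()].
#' @param k number of groups, `1 <= k <= n`.
#' @return named integer vector (cell -> group index 1..k).
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "scx_tree"))
  n <- length(tree$hclust$order)
  if (k < 1L || k > n) stop("k must be between 1 and ", n, call. = FALSE)
  stats::cutree(tree$hclust, k = k)
}

#' k-means clustering with seeded restarts
#'
#' Best-inertia assignment over `restarts` random starts; deterministic for a
#' fixed seed (the RNG state is saved and restored around the call).
#'
#' @param matrix numeric matrix, observations in rows.
#' @param k number of clusters.
#' @param seed integer RNG seed (default 0).
#' @param restarts number of random starts (default 10).
#' @return named integer vector (cell -> cluster 1..k) with attributes
#'   `inertia` (total within-cluster sum of squares) and `centers`.
#' @export
kmeans_cluster <- function(matrix, k, seed = 0, restarts = 10) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")",
                  call. = FALSE)
  res <- with_seed(seed, stats::kmeans(matrix, centers = k, nstart = restarts,
                                       iter.max = 100))
  assign <- res$cluster
  names(assign) <- rownames(matrix)
  attr(assign, "inertia") <- res$tot.withinss
  attr(assign, "centers") <- res$centers
  assign
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 on identical partitions, about 0 for random
#' relabellings.
#'
#' @param a,b label vectors of the same length (any types coercible to factor).
#' @return a number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)        # degenerate: single-cluster vs itself
  (sum_ij - expected) / (max_idx - expected)
}

new_embedding <- function(coords, method, params) {
  structure(list(coords = coords, method = method, params = params),
            class = "scx_embedding")
}

#' @export
print.scx_embedding <- function(x, ...) {
  cat("scx_embedding (", x$method, "): ", nrow(x$coords), " cells x ",
      ncol(x$coords), " components\n", sep = "")
  invisible(x)
}

#' Principal component embedding
#'
#' Projections of the column-centred matrix onto its top-k principal axes;
#' component variances are non-increasing.
#'
#' @param matrix numeric matrix, cells in rows.
#' @param k number of components, `k <= min(n, g)`.
#' @return an `scx_embedding`; `params` records per-component standard
#'   deviations, the variance explained, and the loadings (`rotation`).
#' @export
pca_embed <- function(matrix, k = 3) {
  matrix <- as.matrix(matrix)
  if (k < 1L || k > min(dim(matrix)))
    stop("k must be between 1 and min(n, g) = ", min(dim(matrix)), call. = FALSE)
  p <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  coords <- p$x[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(matrix)
  new_embedding(coords, "pca",
                list(k = k, sdev = p$sdev,
                     variance_explained = p$sdev[seq_len(k)]^2 / sum(p$sdev^2),
                     rotation = p$rotation[, seq_len(k), drop = FALSE]))
}

#' Isomap embedding
#'
#' Geodesic multidimensional scaling over a k-nearest-neighbour graph
#' (classical Isomap, via vegan). Requires the neighbourhood graph to be
#' connected.
#'
#' @param matrix numeric matrix, cells in rows.
#' @param k number of embedding dimensions.
#' @param n_neighbors neighbourhood size (must be `< n`).
#' @return an `scx_embedding`.
#' @export
isomap_embed <- function(matrix, k = 2, n_neighbors = 10) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (n_neighbors >= n)
    stop("n_neighbors (", n_neighbors, ") must be smaller than the number of ",
         "cells (", n, ")", call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  d <- stats::dist(matrix)
  res <- tryCatch(
    vegan::isomap(d, ndim = k, k = n_neighbors),
    error = function(e)
      stop("isomap failed (", conditionMessage(e),
           "); the neighbourhood graph may be disconnected - try a larger ",
           "n_neighbors", call. = FALSE))
  coords <- res$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(matrix)
  colnames(coords) <- paste0("DIM", seq_len(k))
  new_embedding(coords, "isomap", list(k = k, n_neighbors = n_neighbors))
}

#' Locally linear embedding
#'
#' Standard LLE (reconstruction of each point from its nearest neighbours,
#' then the bottom eigenvectors of `(I - W)'(I - W)`). Implemented directly
#' as no pre-packaged LLE is assumed.
#'
#' @param matrix numeric matrix, cells in rows.
#' @param k number of embedding dimensions.
#' @param n_neighbors neighbourhood size (must be `< n`).
#' @param reg local Gram regularisation (relative trace; default 1e-3).
#' @return an `scx_embedding`.
#' @export
lle_embed <- function(matrix, k = 2, n_neighbors = 10, reg = 1e-3) {
  x <- as.matrix(matrix)
  n <- nrow(x)
  if (n_neighbors >= n)
    stop("n_neighbors (", n_neighbors, ") must be smaller than the number of ",
         "cells (", n, ")", call. = FALSE)
  if (k < 1L || k >= n) stop("k must be in [1, n)", call. = FALSE)
  dmat <- as.matrix(stats::dist(x))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(n_neighbors + 1L)]
    Z <- sweep(x[nb, , drop = FALSE], 2, x[i, ])
    G <- Z %*% t(Z)
    G <- G + diag(n_neighbors) * reg * sum(diag(G)) / n_neighbors
    w <- solve(G, rep(1, n_neighbors))
    W[i, nb] <- w / sum(w)
  }
  M <- diag(n) - W
  M <- t(M) %*% M
  eig <- eigen(M, symmetric = TRUE)
  # discard the constant eigenvector (smallest eigenvalue), take the next k
  idx <- seq(n - 1L, by = -1L, length.out = k)
  coords <- eig$vectors[, idx, drop = FALSE] * sqrt(n)
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("DIM", seq_len(k))
  new_embedding(coords, "lle",
                list(k = k, n_neighbors = n_neighbors, reg = reg))
}
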