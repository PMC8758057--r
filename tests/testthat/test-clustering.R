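test_that("standardization yields z-scored continuous and untouched binary columns", {
  set.seed(1)
  raw <- data.frame(a = rnorm(30, 5, 2), b = rpois(30, 3),
                    bin = rbinom(30, 1, 0.4))
  fm <- standardize_features(raw, binary_cols = "bin")
  expect_equal(unname(colMeans(fm$x[, c("a", "b")])), c(0, 0),
               tolerance = 1e-12)
  expect_equal(unname(apply(fm$x[, c("a", "b")], 2, sd)), c(1, 1),
               tolerance = 1e-12)
  expect_identical(fm$x[, "bin"], as.double(raw$bin))

  # re-applying stored parameters reproduces the matrix bit-identically
  fm2 <- standardize_features(raw, binary_cols = "bin", params = fm$params)
  expect_identical(fm$x, fm2$x)

  # log columns applied before z-scoring
  fml <- standardize_features(raw, binary_cols = "bin", log_cols = "b")
  expect_equal(unname(fml$x[, "b"]),
               unname(scale(log1p(raw$b))[, 1]))

  raw$const <- 1
  expect_error(standardize_features(raw, binary_cols = "bin"), "const")
  raw$const <- NULL
  raw$bin[1] <- 2
  expect_error(standardize_features(raw, binary_cols = "bin"), "bin")
})

test_that("Ward merge heights equal within-cluster SS increases", {
  # two points on a line merge at ||a-b||^2 / 2
  tr <- ward_dendrogram(matrix(c(0, 2), ncol = 1))
  expect_equal(tr$height, 2)
  # duplicated point merges at height 0
  tr <- ward_dendrogram(matrix(c(1, 1, 5), ncol = 1))
  expect_equal(min(tr$height), 0)
  expect_true(all(diff(tr$height) >= 0))
  expect_error(ward_dendrogram(matrix(1, 1, 1)), "at least 2")
})

test_that("cutting the dendrogram recovers planted tight groups", {
  set.seed(3)
  x <- rbind(matrix(rnorm(6, 0, 0.05), 3), matrix(rnorm(6, 5, 0.05), 3))
  tr <- ward_dendrogram(x)
  lab <- cut_dendrogram(tr, 2)
  expect_equal(lab, c(1, 1, 1, 2, 2, 2))
  # the 2-partition matches the enumeration optimum
  oracle <- best_two_partition(x)
  expect_equal(lab, oracle$labels)
  expect_equal(cut_dendrogram(tr, 1), rep(1, 6))
  expect_equal(cut_dendrogram(tr, 6), 1:6)
  expect_error(cut_dendrogram(tr, 0))
  expect_error(cut_dendrogram(tr, 7))
})

test_that("K-means finds the enumerated global optimum on small data", {
  set.seed(9)
  x <- matrix(rnorm(16), 8, 2)
  km <- kmeans_fit(x, 2, seed = 5, n_restarts = 30)
  oracle <- best_two_partition(x)
  expect_equal(km$wss, oracle$wss, tolerance = 1e-8)
  expect_equal(align_labels(oracle$labels, km$labels)$kappa, 1)
  # wss is the recomputed sum of squared distances to centroids
  d2 <- rowSums((x - km$centroids[km$labels, ])^2)
  expect_equal(km$wss, sum(d2), tolerance = 1e-10)
  # centroids are member means
  for (j in 1:2) {
    expect_equal(km$centroids[j, ], colMeans(x[km$labels == j, , drop = FALSE]))
  }
})

test_that("K-means edge cases and determinism", {
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2)
  km1 <- kmeans_fit(x, 1, seed = 1)
  expect_equal(km1$centroids[1, ], colMeans(x))
  expect_equal(km1$wss, sum(sweep(x, 2, colMeans(x))^2))
  expect_identical(kmeans_fit(x, 3, seed = 2), kmeans_fit(x, 3, seed = 2))
  expect_error(kmeans_fit(x, 21, seed = 1), "exceeds")
  # independent route: stats::kmeans with many starts reaches the same optimum
  ref <- stats::kmeans(x, 3, nstart = 50, algorithm = "Lloyd", iter.max = 100)
  km3 <- kmeans_fit(x, 3, seed = 2, n_restarts = 50)
  expect_equal(km3$wss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("WSS curve is non-increasing and the elbow lands on planted k", {
  blobs <- make_blobs(15, rbind(c(0, 0), c(6, 0), c(0, 6)), sd = 0.3, seed = 2)
  cv <- wss_curve(blobs$x, k_max = 6, seed = 11, n_restarts = 20)
  expect_true(all(diff(cv$wss) <= 1e-8))
  expect_equal(suggest_k(cv), 3)
  # constructed curve with an unambiguous knee at k = 4
  curve <- data.frame(k = 1:6, wss = c(100, 80, 60, 40, 38, 36))
  expect_equal(suggest_k(curve), 4)
  # at k = n the objective vanishes
  tiny <- matrix(rnorm(8), 4, 2)
  expect_equal(kmeans_fit(tiny, 4, seed = 1, n_restarts = 10)$wss, 0,
               tolerance = 1e-12)
})

test_that("label permutation leaves wss and centroid sets unchanged", {
  blobs <- make_blobs(10, rbind(c(0, 0), c(5, 5)), sd = 0.5, seed = 6)
  km <- kmeans_fit(blobs$x, 2, seed = 3)
  perm <- c(2L, 1L)
  relabeled <- perm[km$labels]
  wss_re <- sum(vapply(1:2, function(cl) {
    xs <- blobs$x[relabeled == cl, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
  expect_equal(wss_re, km$wss)
})

test_that("K-means recovers the generating phenotypes on the default cohort", {
  g <- generate_cohort(cohort_config(seed = 21))
  cases <- g$responses[g$responses$group_label == "case", ]
  fm <- standardize_features(cases[, battery_item_ids()])
  km <- kmeans_fit(fm, 3, seed = 8, n_restarts = 25)
  truth <- as.integer(factor(g$true_labels[g$responses$group_label == "case"]))
  expect_gt(align_labels(truth, km$labels)$kappa, 0.6)
})

test_that("Bray-Curtis PCoA reproduces an independent eigendecomposition", {
  expect_equal(as.numeric(vegan::vegdist(rbind(c(1, 2), c(1, 2)), "bray")), 0)
  expect_equal(as.numeric(vegan::vegdist(rbind(c(1, 0), c(0, 1)), "bray")), 1)
  set.seed(5)
  x <- matrix(runif(8 * 4), 8, 4)
  got <- pcoa_bray(x, n_dims = 2)
  # oracle: explicit double-centering + eigendecomposition
  d <- as.matrix(vegan::vegdist(x, "bray"))
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  oracle <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  for (j in 1:2) { # eigenvectors are sign-indeterminate
    expect_equal(abs(got$coordinates[, j]), abs(oracle[, j]), tolerance = 1e-8)
  }
  expect_error(pcoa_bray(matrix(c(-1, 1), 2, 1)), "non-negative")
  # all-zero pair handled as dissimilarity 0
  z <- rbind(c(0, 0), c(0, 0), c(1, 2))
  expect_silent(pcoa_bray(z, n_dims = 1))
})
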