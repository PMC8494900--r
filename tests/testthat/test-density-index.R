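test_that("closed-form RMS pairwise distance equals the O(N^2) brute force", {
  # two points at +a / -a: brute-force mean square = 2 a^2 -> d_rms = a sqrt(2)
  a <- 1.7
  M2 <- matrix(c(a, -a), ncol = 1)
  expect_equal(rms_pairwise_distance(M2), a * sqrt(2))
  expect_equal(brute_rms_distance(M2), a * sqrt(2))

  expect_equal(rms_pairwise_distance(matrix(0, 5, 3)), 0)

  set.seed(71)
  M <- rand_centered(40, 5)
  expect_equal(rms_pairwise_distance(M), brute_rms_distance(M),
               tolerance = 1e-10)
})

test_that("identity holds across random sizes and dimensions", {
  set.seed(72)
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    d <- sample(1:20, 1)
    M <- rand_centered(n, d)
    expect_equal(rms_pairwise_distance(M), brute_rms_distance(M),
                 tolerance = 1e-10)
  }
})

test_that("mean kNN distance matches hand computation and edge cases", {
  M <- matrix(c(0, 1, 3), ncol = 1)
  expect_equal(mean_knn_distance(M, 1), mean(c(1, 1, 2)))  # = 4/3
  expect_equal(mean_knn_distance(matrix(1, 4, 2), 2), 0)   # duplicates
  # k = N - 1: mean distance to all other cells
  set.seed(73)
  M2 <- rand_centered(10, 3)
  dm <- as.matrix(dist(M2))
  expect_equal(mean_knn_distance(M2, 9),
               mean(sapply(1:10, function(i) mean(dm[i, -i]))))
  expect_error(mean_knn_distance(M2, 10), "k must satisfy")
})

test_that("DI is rotation- and scale-invariant and rewards clumping", {
  set.seed(74)
  M <- rand_centered(60, 4)
  di <- compute_density_index(M, k = 5)
  # random orthogonal rotation
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(compute_density_index(M %*% Q, k = 5), di, tolerance = 1e-9)
  expect_equal(compute_density_index(3.7 * M, k = 5), di, tolerance = 1e-9)

  # uniform 1-D grid vs two tight, well-separated clumps
  n <- 40
  uniform <- scale(matrix(seq_len(n), ncol = 1), scale = FALSE)
  clumped <- scale(matrix(c(rnorm(n / 2, 0, 0.05),
                            rnorm(n / 2, 20, 0.05)), ncol = 1),
                   scale = FALSE)
  expect_gt(compute_density_index(clumped, k = 3),
            compute_density_index(uniform, k = 3))

  expect_error(compute_density_index(matrix(1, 4, 2) - 1, k = 2),
               "duplicate")
})

test_that("PCA embedding is centered, complete and separates planted types", {
  set.seed(75)
  ds <- simulate_counts(n_cells = 120, n_genes = 80, n_types = 2,
                        de_per_type = 10, log2_fc = 4, seed = 7)
  m <- log_normalize(ds$counts)
  feats <- names(ds$de_mask)[ds$de_mask]
  emb <- suppressWarnings(pca_embed(m, feats, D = 2))
  expect_equal(unname(colMeans(emb$M)), rep(0, ncol(emb$M)),
               tolerance = 1e-9)
  # PC1 separates the two types: point-biserial correlation with labels
  expect_gt(abs(cor(emb$M[, 1], as.numeric(ds$cell_labels == 1))), 0.9)

  # full-rank embedding preserves total variance
  set.seed(76)
  small <- make_expr(matrix(rexp(9 * 10), nrow = 9), normalized = TRUE)
  embf <- pca_embed(small, small$feature_ids, D = 9, scale_features = TRUE)
  expect_equal(sum(embf$component_variance), 9, tolerance = 1e-9)

  expect_warning(pca_embed(small, small$feature_ids, D = 50), "clamped")
  expect_error(pca_embed(small, "nope", D = 2), "not in the matrix")
})

test_that("size optimization is self-consistent over its grid", {
  set.seed(77)
  ds <- simulate_counts(n_cells = 150, n_genes = 100, n_types = 2,
                        de_per_type = 10, log2_fc = 3, seed = 9)
  m <- log_normalize(ds$counts)
  g <- compute_ggc(m)
  seeds <- names(sort(correlation_range(g), decreasing = TRUE))[1:3]
  ord <- expand_by_association(g, seeds, max_size = 40)
  sizes <- c(5, 10, 20, 40)
  prof <- optimize_feature_size(m, ord, sizes = sizes, D = 5, k = 5)
  # brute-force recomputation at every grid point
  brute <- sapply(sizes, function(s) {
    emb <- suppressWarnings(
      pca_embed(m, ord$ordering$gene[1:s], D = 5))
    compute_density_index(emb, k = 5)
  })
  expect_equal(prof$profile$di, brute, tolerance = 1e-12)
  expect_equal(prof$optimal_size, sizes[which.max(brute)])

  single <- optimize_feature_size(m, ord, sizes = 10, D = 5, k = 5)
  expect_equal(single$optimal_size, 10L)
  expect_error(optimize_feature_size(m, ord, sizes = integer(0)), "empty")
})
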