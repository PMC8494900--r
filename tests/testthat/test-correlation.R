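test_that("gene-gene correlations match the textbook Pearson computation", {
  set.seed(41)
  m <- matrix(rexp(8 * 30), nrow = 8)
  x <- make_expr(m, normalized = TRUE)
  ggc <- compute_ggc(x)
  oracle <- stats::cor(t(m))
  expect_equal(unname(ggc$values), unname(oracle), tolerance = 1e-10)
  expect_equal(ggc$values, t(ggc$values))
  expect_equal(unname(diag(ggc$values)), rep(1, 8))

  # identical and mirrored expression vectors
  v <- rexp(20)
  y <- make_expr(rbind(v, v, max(v) - v + 1), normalized = TRUE)
  g2 <- compute_ggc(y)
  expect_equal(g2$values[1, 2], 1)
  expect_equal(g2$values[1, 3], -1)

  const <- make_expr(rbind(v, rep(2, 20)), normalized = TRUE)
  expect_error(compute_ggc(const), "zero-variance")
})

test_that("correlation range follows max_3 minus 0.75 * min", {
  col1 <- c(1.0, 0.9, 0.8, -0.4, 0.1)
  v <- diag(5)
  v[, 1] <- col1
  v[1, ] <- col1
  cr <- correlation_range(ggc_from_matrix(v))
  expect_equal(unname(cr[1]), 0.8 + 0.3)  # max_3 = 0.8, min = -0.4 -> 1.1

  # identity GGC: every column is (1, 0, ..., 0) -> c = 0
  cr_id <- correlation_range(ggc_from_matrix(diag(4)))
  expect_equal(unname(cr_id), rep(0, 4))

  # column (1, -1, 0): sorted desc (1, 0, -1), max_3 = -1 -> c = -0.25
  v3 <- matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 1), 3, 3)
  cr3 <- correlation_range(ggc_from_matrix(v3))
  expect_equal(unname(cr3[1]), -1 - 0.75 * (-1))

  expect_error(correlation_range(ggc_from_matrix(diag(2))), "at least 3")
})

test_that("adding a gene inside all existing order statistics leaves c alone", {
  set.seed(42)
  g <- rand_ggc(8)
  cr <- correlation_range(g)
  # new gene correlated at a level above every min, below every max_3
  max3s <- apply(g$values, 2, function(col) sort(col, decreasing = TRUE)[3])
  mins <- apply(g$values, 2, min)
  mid <- (max(mins) + min(max3s)) / 2
  v2 <- rbind(cbind(g$values, mid), c(rep(mid, 8), 1))
  cr2 <- correlation_range(ggc_from_matrix(v2))
  expect_equal(unname(cr2[1:8]), unname(cr), tolerance = 1e-12)
})

test_that("expression binning is equal-frequency with stable tie-breaks", {
  set.seed(43)
  m <- matrix(rexp(10 * 6), nrow = 10)
  x <- make_expr(m, normalized = TRUE)
  expect_equal(unname(bin_by_mean_expression(x, 1)), rep(1L, 10))

  means <- Matrix::rowMeans(x$values)
  b2 <- bin_by_mean_expression(x, 2)
  expect_equal(unname(b2[order(means)]), rep(1:2, each = 5))

  # 9 genes, 2 bins: sizes {5, 4}, deterministic across calls
  x9 <- subset_features(x, 1:9)
  b9a <- bin_by_mean_expression(x9, 2)
  b9b <- bin_by_mean_expression(x9, 2)
  expect_identical(b9a, b9b)
  expect_equal(sort(unname(table(b9a)), decreasing = TRUE), c(5L, 4L),
               ignore_attr = TRUE)

  # tied means: stable gene order decides the split
  xt <- make_expr(matrix(1, nrow = 4, ncol = 3) * c(1, 2, 2, 3),
                  normalized = TRUE)
  bt <- bin_by_mean_expression(xt, 2)
  expect_equal(unname(bt), c(1L, 1L, 2L, 2L))

  expect_error(bin_by_mean_expression(x9, 10), "exceeds")
})

test_that("binned z-scores standardize within bins", {
  c_scores <- c(1, 2, 3, 5, 5, 5)
  bins <- c(1, 1, 1, 2, 2, 2)
  z <- correlation_range_zscore(c_scores, bins)
  expect_equal(unname(z[3]), 1)           # (3 - 2) / sd(1,2,3) = 1
  expect_equal(unname(z[4:6]), rep(0, 3)) # zero-spread bin -> z = 0

  set.seed(44)
  cs <- rnorm(40)
  bs <- rep(1:4, each = 10)
  zz <- correlation_range_zscore(cs, bs)
  for (b in 1:4) {
    expect_equal(mean(zz[bs == b]), 0, tolerance = 1e-12)
    expect_equal(sd(zz[bs == b]), 1, tolerance = 1e-12)
  }
  expect_error(correlation_range_zscore(c(1, 2), c(1, 2)), "fewer than 2")
})

test_that("candidate selection excludes z equal to the threshold", {
  z <- c(a = 0.7, b = 0.7000001, c = 2, d = -1)
  mask <- select_candidates(z, 0.7)
  expect_equal(unname(mask), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(select_candidates(z, -Inf)))
  expect_error(select_candidates(z, 10), "lower the threshold")
})
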