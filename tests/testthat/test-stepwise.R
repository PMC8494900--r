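test_that("column centering zeroes column means and keeps centered input", {
  set.seed(51)
  G <- matrix(rnorm(36), 6, 6)
  Gc <- center_columns(G)
  expect_equal(unname(colMeans(Gc)), rep(0, 6), tolerance = 1e-12)
  expect_equal(center_columns(cbind(rep(3, 4), rnorm(4)))[, 1], rep(0, 4))
  sym <- matrix(c(1, -1, -1, 1), 2, 2)  # columns already zero-mean
  expect_equal(center_columns(sym), sym)
})

test_that("variance explained matches the worked 2x2 case and guards zeros", {
  G <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(variance_explained_all(G), c(4, 4))
  # zero column is guarded to V = 0
  G0 <- cbind(c(0, 0), c(1, 2))
  expect_equal(variance_explained_all(G0)[1], 0)
})

test_that("single-product variance equals explicit rank-one regression", {
  set.seed(52)
  for (rep in 1:5) {
    G <- center_columns(matrix(rnorm(100), 10, 10))
    V <- variance_explained_all(G)
    expect_equal(V, brute_variance_explained(G), tolerance = 1e-9)
  }
})

test_that("regress_out obeys the rank-one regression algebra", {
  set.seed(53)
  G <- center_columns(matrix(rnorm(64), 8, 8))
  eps <- regress_out(G, 3)
  # Pythagoras: ||G||^2 = V + ||eps||^2
  V <- variance_explained_all(G)[3]
  expect_equal(norm(G, "F")^2, V + norm(eps, "F")^2, tolerance = 1e-9)
  # self-regression annihilates its own column
  expect_equal(eps[, 3], rep(0, 8), tolerance = 1e-12)
  # an orthogonal column is unchanged
  g <- G[, 3]
  orth <- rnorm(8)
  orth <- orth - g * sum(orth * g) / sum(g^2)
  G2 <- cbind(G[, 1:3], orth)
  expect_equal(regress_out(G2, 3)[, 4], orth, tolerance = 1e-12)
  # exactly rank-one input leaves no residual
  w <- rnorm(8)
  R1 <- g %*% t(w)
  expect_equal(regress_out(R1, 1), matrix(0, 8, 8),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(regress_out(cbind(0, g), 1), "zero norm")
})

test_that("the first stepwise pick maximizes the exhaustive per-gene drop", {
  set.seed(54)
  g <- rand_ggc(15)
  Gc <- center_columns(g$values)
  oracle_pick <- which.max(brute_variance_explained(Gc))
  sw <- suppressWarnings(stepwise_select(g, computed_steps = 10,
                                         total_steps = 20))
  expect_equal(match(sw$ordered_genes[1], g$gene_index), oracle_pick)
})

test_that("scree is extrapolated flat and Frobenius mass shrinks stepwise", {
  set.seed(55)
  g <- rand_ggc(40)
  sw <- stepwise_select(g, computed_steps = 30, total_steps = 100)
  expect_equal(nrow(sw$scree), 100)
  expect_equal(sw$scree$var_explained[31:100],
               rep(sw$scree$var_explained[30], 70))
  expect_true(all(is.na(sw$scree$gene[31:100])))
  expect_false(anyDuplicated(sw$ordered_genes) > 0)
  expect_true(sw$elbow_index >= 1 && sw$elbow_index <= 30)
  expect_equal(sw$seed_genes, sw$ordered_genes[seq_len(sw$elbow_index)])

  # ||G_{k+1}||_F^2 = ||G_k||_F^2 - V_k >= 0 along explicit iterations
  G <- center_columns(g$values)
  for (k in 1:10) {
    V <- variance_explained_all(G)
    j <- which.max(V)
    eps <- regress_out(G, j)
    expect_equal(norm(eps, "F")^2, unname(norm(G, "F")^2 - V[j]),
                 tolerance = 1e-8)
    expect_gte(unname(norm(G, "F")^2 - V[j]), -1e-9)
    G <- eps
  }
})

test_that("two uncorrelated blocks are seeded from both blocks first", {
  set.seed(56)
  n <- 200
  sig1 <- rnorm(n)
  sig2 <- rnorm(n)
  block <- function(sig, p) {
    sapply(seq_len(p), function(i) sig + rnorm(n, sd = 0.3))
  }
  x <- cbind(block(sig1, 6), block(sig2, 6))
  g <- ggc_from_matrix(stats::cor(x))
  sw <- suppressWarnings(stepwise_select(g, computed_steps = 6,
                                         total_steps = 12))
  first_two <- match(sw$ordered_genes[1:2], g$gene_index)
  expect_equal(sort(c(first_two[1] <= 6, first_two[2] <= 6)),
               c(FALSE, TRUE))
})

test_that("stepwise lowers the step count when candidates are scarce", {
  set.seed(57)
  g <- rand_ggc(8)
  expect_warning(sw <- stepwise_select(g, computed_steps = 30,
                                       total_steps = 100),
                 "lowered")
  expect_equal(sw$computed_steps, 7)
  expect_equal(nrow(sw$scree), 100)
})

test_that("elbow point is the max distance to the chord", {
  scree <- c(10, 6, 1, 0.9, 0.9, 0.9)
  # brute-force distance-to-chord oracle
  L <- length(scree)
  d <- sapply(seq_len(L), function(i) {
    p1 <- c(1, scree[1]); p2 <- c(L, scree[L]); p <- c(i, scree[i])
    abs((p2[2] - p1[2]) * (p[1] - p1[1]) - (p2[1] - p1[1]) * (p[2] - p1[2])) /
      sqrt(sum((p2 - p1)^2))
  })
  expect_equal(elbow_point(scree), which.max(d))
  expect_equal(elbow_point(scree), 3)
  expect_equal(elbow_point(rep(2, 5)), 1)       # constant -> tie rule
  expect_equal(elbow_point(seq(9, 1, by = -2)), 1)  # linear -> tie rule
  expect_error(elbow_point(3), "length >= 2")
})
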