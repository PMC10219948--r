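test_that("build_graph applies a strict r-scale threshold and stores Fisher-z weights", {
  r <- matrix(c(NA, 0.9, 0.3, 0.1,
                0.9, NA, 0.5, 0.2,
                0.3, 0.5, NA, 0.31,
                0.1, 0.2, 0.31, NA), 4, 4)
  class(r) <- c("connectivity_matrix", class(r))
  g <- build_graph(r, 0.3)
  expect_identical(g$adjacency[1, 2], 1)
  expect_identical(g$adjacency[1, 3], 0)   # exactly 0.3: strict
  expect_identical(g$adjacency[3, 4], 1)   # 0.31 passes
  expect_true(all(diag(g$adjacency) == 0))
  expect_equal(g$weights[1, 2], atanh(0.9))
  expect_equal(g$weights[1, 3], 0)
  # complete and empty extremes
  strong <- matrix(0.9, 3, 3); diag(strong) <- NA
  class(strong) <- c("connectivity_matrix", class(strong))
  expect_true(all(build_graph(strong)$adjacency[upper.tri(strong)] == 1))
  weak <- matrix(0.1, 3, 3); diag(weak) <- NA
  class(weak) <- c("connectivity_matrix", class(weak))
  expect_true(all(build_graph(weak)$adjacency == 0))
  # z-scale option shifts the boundary: atanh(0.3) > 0.3
  zb <- matrix(0.305, 3, 3); diag(zb) <- NA
  class(zb) <- c("connectivity_matrix", class(zb))
  expect_true(all(build_graph(zb, scale = "r")$adjacency[upper.tri(zb)] == 1))
  expect_true(all(build_graph(zb, scale = "z")$adjacency[upper.tri(zb)] == 1))
})

test_that("known small graphs reproduce textbook metric values", {
  # complete graph K4
  r <- matrix(0.9, 4, 4); diag(r) <- NA
  class(r) <- c("connectivity_matrix", class(r))
  m <- graph_metrics(build_graph(r))
  expect_equal(m$clustering, rep(1, 4))
  expect_equal(m$degree, rep(1, 4))
  expect_equal(m$eigenvector, rep(0.5, 4), tolerance = 1e-9)
  expect_equal(m$betweenness, rep(0, 4))
  expect_equal(m$closeness, rep(1, 4))
  # path a-b-c-d
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- 1
  A <- A + t(A)
  rp <- ifelse(A > 0, 0.5, 0.1)
  diag(rp) <- NA
  class(rp) <- c("connectivity_matrix", class(rp))
  mp <- graph_metrics(build_graph(rp))
  # unnormalized betweenness of b is 2 (pairs (a,c),(a,d)); /3 normalized
  expect_equal(mp$betweenness, c(0, 2, 2, 0) / 3)
  # closeness(b): distances 1,1,2 -> 3/4 raw, full reachability leaves it
  expect_equal(mp$closeness[2], 3 / 4)
  expect_equal(mp$closeness[1], 3 / 6)
})

test_that("all six metrics match brute-force oracles on random small graphs", {
  set.seed(77)
  worst <- 0
  for (i in 1:60) {
    n <- sample(3:7, 1)
    r <- random_small_graph(n)
    g <- build_graph(r)
    m <- graph_metrics(g)
    A <- g$adjacency
    worst <- max(
      worst,
      max(abs(m$betweenness - oracle_betweenness(A))),
      max(abs(m$closeness - oracle_closeness(A))),
      max(abs(m$clustering - oracle_clustering(A))),
      max(abs(m$degree - colSums(A) / (n - 1))),
      max(abs(m$eigenvector - oracle_eigenvector(A))),
      max(abs(m$normalized_strength - oracle_strength(g$weights)))
    )
  }
  expect_lt(worst, 1e-10)
})

test_that("metrics are equivariant under node relabelling", {
  set.seed(13)
  r <- random_small_graph(7)
  rownames(r) <- colnames(r) <- paste0("p", 1:7)
  m <- graph_metrics(build_graph(r))
  perm <- sample(7)
  rp <- r[perm, perm]
  class(rp) <- c("connectivity_matrix", class(rp))
  mp <- graph_metrics(build_graph(rp))
  for (col in c("betweenness", "closeness", "clustering", "degree",
                "normalized_strength")) {
    expect_equal(mp[[col]], m[[col]][perm], tolerance = 1e-12)
  }
  expect_equal(mp$eigenvector, m$eigenvector[perm], tolerance = 1e-9)
})

test_that("empty graphs return all-zero metrics with a flag", {
  weak <- matrix(0.05, 5, 5); diag(weak) <- NA
  class(weak) <- c("connectivity_matrix", class(weak))
  m <- graph_metrics(build_graph(weak))
  expect_true(attr(m, "empty_graph"))
  for (col in c("betweenness", "closeness", "clustering", "degree",
                "eigenvector", "normalized_strength")) {
    expect_true(all(m[[col]] == 0))
  }
})

test_that("pc1_concordance is exactly 1 for identical or column-permuted matrices", {
  set.seed(23)
  x <- matrix(rnorm(30 * 8), 30, 8)
  expect_equal(pc1_concordance(x, x), 1)
  # permuting subject columns spans the same PC1 scores: verify against a
  # direct eigen-decomposition oracle
  xp <- x[, sample(8)]
  cx <- scale(x, scale = FALSE)
  e <- eigen(stats::cov(cx))
  scores <- as.numeric(cx %*% e$vectors[, 1])
  expect_equal(abs(stats::cor(stats::prcomp(x)$x[, 1], scores)), 1,
               tolerance = 1e-9)
  expect_equal(pc1_concordance(x, xp), 1, tolerance = 1e-9)
  expect_error(pc1_concordance(matrix(1, 4, 3), matrix(1, 4, 3)), "rank-0")
  expect_error(pc1_concordance(x, x[1:10, ]), "shape")
})

test_that("independent random metric matrices concord far below 1", {
  set.seed(29)
  conc <- replicate(40, {
    pc1_concordance(matrix(rnorm(60 * 10), 60, 10),
                    matrix(rnorm(60 * 10), 60, 10))
  })
  expect_lt(stats::quantile(conc, 0.975), 0.5)
})

test_that("the full graph stage returns concordance 1 for identical pipelines", {
  ds <- generate_paired_dataset(identical_config())
  gc <- graph_concordance(ds$subjects)
  expect_equal(unname(gc$concordance), rep(1, 6), tolerance = 1e-9)
})
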