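test_that("identical pipelines give zero significant parcels for every quantity", {
  ds <- generate_paired_dataset(identical_config())
  for (q in c("thickness", "gyrification", "volume")) {
    rep <- parcel_structural_comparison(ds$subjects, q)
    expect_identical(sum(rep$significant), 0L)
  }
})

test_that("a strong widespread offset is detected in every parcel with the right direction", {
  cfg <- small_config(n_subjects = 20, delta_thick_mm = 0.2,
                      subject_sd = 0.05, map_noise_sd = 0.05)
  ds <- generate_paired_dataset(cfg)
  rep <- parcel_structural_comparison(ds$subjects, "thickness")
  expect_true(all(rep$significant))
  expect_true(all(rep$direction == "B>A"))
  expect_equal(unique(rep$p_threshold_corrected), 0.05 / 34)
})

test_that("subcortical volumes are corrected at 0.05/7 and cortical at 0.05/34", {
  ds <- generate_paired_dataset(tiny_config(n_subjects = 6))
  rep <- parcel_structural_comparison(ds$subjects, "volume")
  cortical <- grepl("parcel", rep$parcel)
  expect_equal(unique(rep$p_threshold_corrected[cortical]), 0.05 / 8)
  expect_equal(unique(rep$p_threshold_corrected[!cortical]), 0.05 / 7)
  expect_identical(sum(!cortical), 14L)
})

test_that("a subject missing one pipeline is dropped with a warning", {
  ds <- generate_paired_dataset(tiny_config())
  ds$subjects[[3]]$B <- NULL
  expect_warning(rep <- parcel_structural_comparison(ds$subjects, "thickness"),
                 "1 subject")
  expect_s3_class(rep, "comparison_report")
})

test_that("jaccard matches hand counts, is symmetric, and is 1 iff sets are equal", {
  lab1 <- c(1, 1, 1, 2, 2)
  lab2 <- c(2, 1, 1, 1, 2)
  s1 <- parcel_scheme(lab1, c("a", "b"))
  s2 <- parcel_scheme(lab2, c("a", "b"))
  # parcel 1: {1,2,3} vs {2,3,4} -> 2/4
  expect_equal(jaccard(s1, s2, 1), 0.5)
  expect_equal(jaccard(s2, s1, 1), 0.5)
  expect_equal(jaccard(s1, s1, 1), 1)
  s3 <- parcel_scheme(c(2, 2, 2, 1, 1), c("a", "b"))
  expect_equal(jaccard(s1, s3, 1), 0)  # disjoint
  expect_error(jaccard(s1, s2, "zzz"), "absent")
  expect_error(jaccard(s1, parcel_scheme(c(1, 1, 2, 2), c("a", "b")), 1),
               "vertex count")
})

test_that("vertexwise comparison recovers an injected patch and honours the permutation request", {
  sphere <- test_sphere(level = 2, radius = 20)
  nv <- n_vertices(sphere)
  n <- 12
  adj <- surface_adjacency(sphere)
  # contiguous true patch: a vertex and its 2-ring
  patch <- 1L
  for (i in 1:2) patch <- unique(c(patch, unlist(adj[patch])))
  set.seed(11)
  A <- matrix(rnorm(nv * n, sd = 0.1), nv, n)
  B <- A + matrix(rnorm(nv * n, sd = 0.1), nv, n)
  B[patch, ] <- B[patch, ] + 1
  rep <- vertexwise_paired_comparison(A, B, sphere, n_perm = 500, seed = 2)
  expect_identical(rep$n_permutations, 500L)
  sig <- rep$clusters[vapply(rep$clusters, function(cl) cl$significant,
                             logical(1))]
  expect_gte(length(sig), 1L)
  masses <- vapply(sig, function(cl) cl$mass, numeric(1))
  found <- sig[[which.max(masses)]]$vertices
  jac <- length(intersect(found, patch)) / length(union(found, patch))
  expect_gte(jac, 0.8)
  # any additional suprathreshold clusters are isolated stray vertices
  for (cl in sig[-which.max(masses)]) expect_lte(length(cl$vertices), 3L)
})

test_that("vertexwise comparison is invariant to a common additive constant", {
  sphere <- test_sphere(level = 2)
  nv <- n_vertices(sphere)
  set.seed(4)
  A <- matrix(rnorm(nv * 8), nv, 8)
  B <- A + matrix(rnorm(nv * 8, sd = 0.5), nv, 8)
  r1 <- vertexwise_paired_comparison(A, B, sphere, n_perm = 200, seed = 3)
  r2 <- vertexwise_paired_comparison(A + 100, B + 100, sphere,
                                     n_perm = 200, seed = 3)
  expect_equal(r1$t_map, r2$t_map, tolerance = 1e-8)
  expect_equal(length(r1$clusters), length(r2$clusters))
})

test_that("cluster masses do not grow when the vertex threshold tightens", {
  sphere <- test_sphere(level = 2)
  nv <- n_vertices(sphere)
  set.seed(8)
  n <- 10
  A <- matrix(rnorm(nv * n), nv, n)
  B <- A + 0.8 + matrix(rnorm(nv * n, sd = 0.6), nv, n)
  masses <- vapply(c(1e-2, 1e-3, 1e-4), function(pv) {
    r <- vertexwise_paired_comparison(A, B, sphere, vertexwise_p = pv,
                                      n_perm = 100, seed = 5)
    if (!length(r$clusters)) return(0)
    max(vapply(r$clusters, function(cl) cl$mass, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(masses) <= 0))
})

test_that("exhaustive enumeration replaces random flips when 2^n <= n_perm", {
  sphere <- test_sphere(level = 1)
  nv <- n_vertices(sphere)
  set.seed(6)
  A <- matrix(rnorm(nv * 7), nv, 7)
  B <- A + matrix(rnorm(nv * 7), nv, 7)
  expect_message(
    r <- vertexwise_paired_comparison(A, B, sphere, n_perm = 5000, seed = 1),
    "exhaustive"
  )
  expect_identical(r$n_permutations, 128L)
})
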