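test_that("fc_strength follows the survivor-average definition", {
  r <- matrix(NA_real_, 4, 4)
  r[lower.tri(r)] <- c(0.5, 0.2, -0.4, 0.1, 0.25, 0.15)
  r[upper.tri(r)] <- t(r)[upper.tri(r)]
  colnames(r) <- rownames(r) <- paste0("p", 1:4)
  class(r) <- c("connectivity_matrix", class(r))
  # column p1 holds (0.5, 0.2, -0.4): survivors {0.5, -0.4}
  s <- fc_strength(r, 0.3, "mean")
  expect_equal(unname(s["p1"]), 0.05)
  # denominator = all off-diagonal entries instead
  s_all <- fc_strength(r, 0.3, "mean", denominator = "all")
  expect_equal(unname(s_all["p1"]), 0.1 / 3)
  # threshold 0: plain off-diagonal column means
  s0 <- fc_strength(r, 0, "mean")
  expect_equal(as.numeric(s0), unname(colMeans(r, na.rm = TRUE)))
  # no survivors: zero with flag
  weak <- matrix(0.1, 3, 3)
  diag(weak) <- NA
  class(weak) <- c("connectivity_matrix", class(weak))
  sw <- fc_strength(weak, 0.3)
  expect_true(all(sw == 0))
  expect_true(all(attr(sw, "empty")))
})

test_that("fc_strength is equivariant under simultaneous row/column permutation", {
  set.seed(12)
  x <- matrix(rnorm(10 * 50), 10, 50)
  rownames(x) <- paste0("p", 1:10)
  cm <- connectivity_matrix(x)
  s <- fc_strength(cm, 0.2)
  perm <- sample(10)
  cmp <- connectivity_matrix(x[perm, ])
  sp <- fc_strength(cmp, 0.2)
  expect_equal(as.numeric(sp), as.numeric(s[perm]))
})

test_that("median strength resists an injected outlier where the mean does not", {
  r <- matrix(0.4, 6, 6)
  diag(r) <- NA
  class(r) <- c("connectivity_matrix", class(r))
  base_mean <- fc_strength(r, 0.3, "mean")[1]
  base_med <- fc_strength(r, 0.3, "median")[1]
  expect_equal(base_mean, base_med)
  r2 <- r
  r2[1, 2] <- r2[2, 1] <- 0.99  # outlier edge
  expect_equal(unname(fc_strength(r2, 0.3, "median")[1]), 0.4)
  expect_gt(unname(fc_strength(r2, 0.3, "mean")[1]), 0.4)
})

test_that("identical pipelines give identical strengths and all-zero t-statistics", {
  ds <- generate_paired_dataset(identical_config())
  rep <- compare_fc_strength(ds$subjects, "mean")
  st <- attr(rep, "strengths")
  expect_equal(max(abs(st$A - st$B)), 0, tolerance = 1e-12)
  expect_true(all(rep$t_statistic == 0))
  expect_identical(sum(rep$significant), 0L)
})

test_that("boundary perturbation alone induces only small strength differences", {
  ds <- generate_paired_dataset(tiny_config(delta_thick_mm = 0, delta_gyr = 0,
                                            subject_sd = 0))
  rep <- compare_fc_strength(ds$subjects, "mean")
  st <- attr(rep, "strengths")
  expect_gt(max(abs(st$A - st$B)), 0)       # schemes differ, strengths shift
  expect_lt(mean(abs(st$A - st$B)), 0.1)    # but stay close on average
})

test_that("seed maps correlate the seed with itself and stay within hemisphere", {
  ds <- generate_paired_dataset(tiny_config(vertex_noise_sd = 0.2))
  b <- ds$subjects[[1]]$A
  sm <- seed_vertex_map(b, "lh_parcel_1")
  members <- which(b$scheme$labels == 1)
  expect_gt(mean(sm$values[members]), 0.8)       # near self-correlation
  right <- b$surface$vertex_hemi == "right"
  expect_true(all(is.na(sm$values[right])))      # opposite hemisphere missing
  expect_false(anyNA(sm$values[!right]))
  expect_error(seed_vertex_map(b, "no_such"), "not in scheme")
})

test_that("within-network vertex correlations exceed between-network ones", {
  cfg <- tiny_config(vertex_noise_sd = 0.5, n_timepoints = 300)
  ds <- generate_paired_dataset(cfg)
  b <- ds$subjects[[1]]$A
  block <- cfg$network_block
  seed_parcel <- 1L
  sm <- seed_vertex_map(b, seed_parcel)
  lab <- b$scheme$labels
  left <- b$surface$vertex_hemi == "left"
  same_net <- left & lab > 0 & block[pmax(lab, 1)] == block[seed_parcel] &
    lab != seed_parcel
  diff_net <- left & lab > 0 & block[pmax(lab, 1)] != block[seed_parcel]
  expect_gt(mean(sm$values[same_net]), mean(sm$values[diff_net]))
})

test_that("the area filter shunts small clusters into the excluded ledger", {
  sphere <- test_sphere(level = 2, radius = 20)
  nv <- n_vertices(sphere)
  n <- 10
  set.seed(21)
  A <- matrix(rnorm(nv * n, sd = 0.05), nv, n)
  B <- A
  B[3, ] <- B[3, ] + 5  # single-vertex effect: tiny area
  areas <- vertex_areas(sphere)
  rep_strict <- network_group_comparison(A, B, sphere,
                                         min_cluster_area_mm2 = areas[3] * 10,
                                         n_perm = 200, seed = 9)
  expect_identical(length(rep_strict$clusters), 0L)
  expect_identical(length(rep_strict$excluded_clusters), 1L)
  rep_loose <- network_group_comparison(A, B, sphere,
                                        min_cluster_area_mm2 = 0,
                                        n_perm = 200, seed = 9)
  expect_identical(length(rep_loose$excluded_clusters), 0L)
  expect_gte(length(rep_loose$clusters), 1L)
})
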