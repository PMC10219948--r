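test_that("same seed gives identical bundles; identical config gives A = B", {
  cfg <- tiny_config()
  d1 <- generate_paired_dataset(cfg)
  d2 <- generate_paired_dataset(cfg)
  expect_identical(d1, d2)

  di <- generate_paired_dataset(identical_config())
  s <- di$subjects[[1]]
  expect_identical(s$A$scheme$labels, s$B$scheme$labels)
  expect_identical(s$A$thickness$values, s$B$thickness$values)
  expect_identical(s$A$gyrification$values, s$B$gyrification$values)
  expect_identical(s$A$timeseries$data, s$B$timeseries$data)
})

test_that("run structure records the requested concatenation boundaries", {
  cfg <- tiny_config(n_timepoints = 90, n_runs = 3)
  ds <- generate_paired_dataset(cfg)
  ts <- ds$subjects[[1]]$A$timeseries
  expect_identical(ts$run_boundaries, c(31L, 61L))
  expect_identical(ncol(ts$data), 90L)
})

test_that("parcel-scheme Jaccard decreases monotonically with the boundary swap rate", {
  grid <- c(0, 0.1, 0.25, 0.5)
  mean_j <- vapply(grid, function(ps) {
    cfg <- small_config(n_subjects = 3, boundary_swap_prob = ps)
    ds <- generate_paired_dataset(cfg)
    mean(vapply(ds$subjects, function(s) {
      mean(vapply(seq_len(s$A$scheme$n_parcels), function(p) {
        jaccard(s$A$scheme, s$B$scheme, p)
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(mean_j[1], 1)
  expect_true(all(diff(mean_j) < 0))
})

test_that("empirical parcel FC approaches the noise-attenuated network correlations", {
  # analytic oracle: parcel mean of k vertices has variance 1 + sd^2/k, so
  # observed r = Sigma_pq / sqrt((1 + sd^2/k_p)(1 + sd^2/k_q))
  cfg <- tiny_config(n_subjects = 1, n_timepoints = 5000, n_runs = 1,
                     vertex_noise_sd = 1)
  ds <- generate_paired_dataset(cfg)
  b <- ds$subjects[[1]]$A
  k <- as.numeric(table(factor(b$scheme$labels,
                               levels = seq_len(b$scheme$n_parcels))))
  atten <- 1 / sqrt(1 + cfg$vertex_noise_sd^2 / k)
  expected <- cfg$sigma * outer(atten, atten)
  diag(expected) <- NA
  cm <- connectivity_matrix(parcel_timeseries(b$timeseries, b$scheme))
  expect_lt(max(abs(cm - expected), na.rm = TRUE), 0.05)
})

test_that("boundary relabelling only moves vertices that sit on parcel boundaries", {
  cfg <- small_config(n_subjects = 2)
  ds <- generate_paired_dataset(cfg)
  surface <- ds$subjects[[1]]$A$surface
  adj <- surface_adjacency(surface)
  lab_a <- ds$subjects[[1]]$A$scheme$labels
  moved <- ds$ground_truth$relabelled[[1]]
  expect_true(length(moved) > 0)
  for (v in moved) {
    expect_true(any(lab_a[adj[[v]]] != lab_a[v]))
  }
})

test_that("structural paired test recovers the injected thickness direction with high power", {
  cfg <- small_config(n_subjects = 12, delta_thick_mm = 0.2, subject_sd = 0.05)
  ds <- generate_paired_dataset(cfg)
  rep <- parcel_structural_comparison(ds$subjects, "thickness")
  expect_true(all(rep$direction == "B>A"))
  expect_gt(mean(rep$significant), 0.95)
  repg <- parcel_structural_comparison(ds$subjects, "gyrification")
  expect_true(mean(repg$direction == "A>B") > 0.95)  # B folds less
})

test_that("seed volumes: zero shift aligns peaks, noiseless shift moves the peak voxel", {
  cfg <- tiny_config()
  rois <- default_seed_rois()
  rois$roi_shifted$noise_sd <- 0
  rois$roi_shifted$shift_mm <- c(6, 0, 0)
  rois$roi_stable$noise_sd <- 0
  cfg2 <- synth_config(n_subjects = 2, n_parcels_per_hemisphere = 8,
                       mesh_subdivision_level = 2, n_timepoints = 90,
                       seed_rois = rois, voxel_size_mm = 3)
  a <- generate_seed_volume(cfg2, "roi_stable", "A")
  b <- generate_seed_volume(cfg2, "roi_stable", "B")
  expect_identical(fc_peak(a)$peak_voxel, fc_peak(b)$peak_voxel)

  pa <- fc_peak(generate_seed_volume(cfg2, "roi_shifted", "A"))
  pb <- fc_peak(generate_seed_volume(cfg2, "roi_shifted", "B"))
  expect_identical(pb$peak_voxel - pa$peak_voxel, c(2L, 0L, 0L))  # 6 mm / 3 mm

  rois$roi_shifted$shift_mm <- c(1000, 0, 0)
  cfg3 <- synth_config(seed_rois = rois)
  expect_error(generate_seed_volume(cfg3, "roi_shifted", "B"), "outside")
  expect_error(generate_seed_volume(cfg2, "nope", "A"), "not defined")
})

test_that("with no injected offset the Bonferroni family stays clean at its nominal rate", {
  # true null: delta = 0 but per-subject noise remains; the 0.05/n correction
  # is applied per hemisphere, so each hemisphere family should be free of
  # rejections in about (1 - 0.05/n)^n ~ 95% of replicates
  clean <- unlist(lapply(1:50, function(rep) {
    cfg <- tiny_config(n_subjects = 10, delta_thick_mm = 0,
                       boundary_swap_prob = 0, n_timepoints = 6,
                       rng_seed = 5000 + rep)
    ds <- generate_paired_dataset(cfg)
    r <- parcel_structural_comparison(ds$subjects, "thickness")
    lh <- grepl("^lh", r$parcel)
    c(sum(r$significant[lh]) == 0, sum(r$significant[!lh]) == 0)
  }))
  expect_gte(mean(clean), 0.94)
})

test_that("non-positive-definite network covariance is rejected with guidance", {
  expect_error(synth_config(rho_in = 0.1, rho_out = 0.4), "rho_in > rho_out")
  sig_bad <- matrix(0.9, 4, 4)
  sig_bad[1, 2] <- sig_bad[2, 1] <- -0.9
  diag(sig_bad) <- 1
  expect_error(synth_config(n_parcels_per_hemisphere = 2, sigma = sig_bad),
               "positive definite.*nearest")
})
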