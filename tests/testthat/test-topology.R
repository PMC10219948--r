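test_that("center_of_gravity maps voxel indices through the affine", {
  aff2 <- diag(c(2, 2, 2, 1))
  expect_equal(center_of_gravity(c(1, 2, 3), diag(4)), c(1, 2, 3))
  # two voxels symmetric about the origin
  expect_equal(center_of_gravity(rbind(c(-1, 0, 0), c(1, 0, 0)), diag(4)),
               c(0, 0, 0))
  # (0,0,0) and (2,0,0) at 2 mm isotropic: mean of (0,0,0) and (4,0,0)
  expect_equal(center_of_gravity(rbind(c(0, 0, 0), c(2, 0, 0)), aff2),
               c(2, 0, 0))
  expect_error(center_of_gravity(matrix(0, 0, 3), diag(4)), "empty")
})

test_that("fc_peak finds the maximum and breaks ties lexicographically", {
  a <- array(0, c(3, 3, 3))
  a[2, 3, 1] <- 5
  v <- volume_grid(a, diag(4))
  pk <- fc_peak(v)
  expect_identical(pk$peak_voxel, c(1L, 2L, 0L))  # 0-based
  expect_equal(pk$peak_mm, c(1, 2, 0))
  # ties at 0-based (1,1,1) and (0,2,2): the smaller i wins
  b <- array(0, c(3, 3, 3))
  b[2, 2, 2] <- 1
  b[1, 3, 3] <- 1
  expect_identical(fc_peak(volume_grid(b, diag(4)))$peak_voxel, c(0L, 2L, 2L))
  # fully masked map errors
  m <- array(FALSE, c(3, 3, 3))
  expect_error(fc_peak(volume_grid(b, diag(4), m)), "no in-mask")
})

test_that("peak-shift distance is invariant under a rigid rotation of affine and ROI", {
  cfg <- synth_config(n_parcels_per_hemisphere = 8, mesh_subdivision_level = 2)
  set.seed(31)
  v <- generate_seed_volume(cfg, "roi_shifted", "B")
  ps <- peak_shift(v)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0, 0),
             c(sin(theta), cos(theta), 0, 0),
             c(0, 0, 1, 0), c(0, 0, 0, 1))
  v_rot <- volume_grid(v$array, R %*% v$affine, v$mask)
  attr(v_rot, "roi_voxels") <- attr(v, "roi_voxels")
  ps_rot <- peak_shift(v_rot)
  expect_equal(ps_rot$distance_mm, ps$distance_mm, tolerance = 1e-10)
})

test_that("error maps: identical maps give 0 everywhere, opposite maps give 1", {
  dm <- c(6, 6, 6)
  a <- array(runif(prod(dm)), dm)
  va <- volume_grid(a, diag(4))
  for (em in error_maps(va, va)) expect_equal(em$mean_error, 0)
  ones <- volume_grid(array(1, dm), diag(4))
  zeros <- volume_grid(array(0, dm), diag(4))
  for (em in error_maps(ones, zeros)) expect_equal(em$mean_error, 1)
  expect_error(error_maps(va, volume_grid(array(0, c(5, 5, 5)), diag(4))),
               "share the grid")
})

test_that("error of a shifted bump equals the symmetric-difference voxel count", {
  dm <- c(16, 16, 16)
  g <- seq_len(dm[1]) - 1
  d2 <- function(cx) outer(outer((g - cx[1])^2, (g - cx[2])^2, `+`),
                           (g - cx[3])^2, `+`)
  bump_a <- exp(-d2(c(7, 7, 7)) / 18)
  bump_b <- exp(-d2(c(8, 7, 7)) / 18)  # one-voxel shift
  va <- volume_grid(bump_a, diag(4))
  vb <- volume_grid(bump_b, diag(4))
  for (em in error_maps(va, vb, thresholds = c(0.3, 0.5))) {
    bin_a <- bump_a >= em$threshold
    bin_b <- bump_b >= em$threshold
    expect_equal(em$mean_error, sum(xor(bin_a, bin_b)) / prod(dm))
    expect_gt(em$mean_error, 0)
  }
  # symmetry in A/B
  e_ab <- error_maps(va, vb)
  e_ba <- error_maps(vb, va)
  for (i in seq_along(e_ab)) {
    expect_equal(e_ab[[i]]$mean_error, e_ba[[i]]$mean_error)
  }
})

test_that("TFCE of an isolated voxel approaches the closed-form h^(H+1)/(H+1) integral", {
  for (h in c(2, 5, 9)) {
    a <- array(0, c(7, 7, 7))
    a[4, 4, 4] <- h
    enh <- tfce(volume_grid(a, diag(4)), E = 0.5, H = 2, dh = h / 1000)
    expect_equal(enh$array[4, 4, 4], h^3 / 3, tolerance = 0.02)
  }
  # doubling heights scales a single-voxel TFCE by 2^(H+1)
  a <- array(0, c(7, 7, 7))
  a[4, 4, 4] <- 1
  e1 <- tfce(volume_grid(a, diag(4)), dh = 1 / 2000)$array[4, 4, 4]
  e2 <- tfce(volume_grid(2 * a, diag(4)), dh = 1 / 1000)$array[4, 4, 4]
  expect_equal(e2 / e1, 8, tolerance = 0.01)
})

test_that("TFCE is monotone, handles signs antisymmetrically, and zero maps stay zero", {
  z <- tfce(volume_grid(array(0, c(5, 5, 5)), diag(4)))
  expect_true(all(z$array == 0))
  set.seed(41)
  x <- array(abs(rnorm(6^3)), c(6, 6, 6))
  vx <- volume_grid(x, diag(4))
  ex <- tfce(vx, dh = max(x) / 50)
  ey <- tfce(volume_grid(x * 1.5, diag(4)), dh = max(x) / 50)
  expect_true(all(ey$array >= ex$array - 1e-12))  # pointwise-larger map dominates
  eneg <- tfce(volume_grid(-x, diag(4)), dh = max(x) / 50)
  expect_equal(eneg$array, -ex$array)
})

test_that("noiseless injected shift produces the constructed delta distances", {
  rois <- default_seed_rois()
  rois$roi_shifted$noise_sd <- 0
  rois$roi_shifted$shift_mm <- c(6, 0, 0)
  rois$roi_stable$noise_sd <- 0
  cfg <- synth_config(n_parcels_per_hemisphere = 8,
                      mesh_subdivision_level = 2, seed_rois = rois)
  seed_maps <- lapply(1:6, function(s) {
    list(A = list(roi_shifted = generate_seed_volume(cfg, "roi_shifted", "A"),
                  roi_stable = generate_seed_volume(cfg, "roi_stable", "A")),
         B = list(roi_shifted = generate_seed_volume(cfg, "roi_shifted", "B"),
                  roi_stable = generate_seed_volume(cfg, "roi_stable", "B")))
  })
  psa <- peak_shift_analysis(seed_maps, "roi_shifted", "roi_stable")
  expect_true(all(psa$delta[, "roi_stable"] == 0))
  expect_true(all(psa$delta[, "roi_shifted"] > 0))
  # every subject identical: the delta test degenerates by construction
  expect_true(psa$delta_test$degenerate)
  expect_true(psa$per_roi_tests$roi_stable$p == 1)
})

test_that("tfce_permutation_fwe flags a strong focal effect and honours n_perm", {
  dm <- c(8, 8, 8)
  set.seed(17)
  n <- 10
  diffs <- lapply(1:n, function(i) {
    a <- array(rnorm(prod(dm), sd = 0.2), dm)
    a[4:5, 4:5, 4:5] <- a[4:5, 4:5, 4:5] + 2
    volume_grid(a, diag(4))
  })
  res <- tfce_permutation_fwe(diffs, n_perm = 300, seed = 5)
  expect_identical(res$n_permutations, 300L)
  expect_true(all(res$pfwe$array[4:5, 4:5, 4:5] < 0.05))
  expect_gt(min(res$pfwe$array), 0)  # +1 convention: never exactly 0
  far <- res$pfwe$array[1, 1, ]
  expect_true(all(far > 0.05))
})
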