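#' Center of gravity of an ROI voxel set
#'
#' Unweighted mean of the member voxels' world coordinates.
#'
#' @param roi_voxels n x 3 matrix of 0-based voxel indices.
#' @param affine 4x4 voxel-to-mm affine.
#' @return Length-3 numeric mm coordinate.
#' @export
center_of_gravity <- function(roi_voxels, affine) {
  if (is.null(dim(roi_voxels))) roi_voxels <- matrix(roi_voxels, nrow = 1)
  if (nrow(roi_voxels) == 0L) stop("empty ROI voxel set")
  colMeans(voxel_to_mm(roi_voxels, affine))
}

#' Locate the FC peak voxel of a volumetric map
#'
#' Argmax of the map within the search mask; ties are broken by the
#' lexicographically smallest 0-based (i, j, k) index triple.
#'
#' @param map a `volume_grid`.
#' @param search_mask optional logical array further restricting the map's
#'   own mask.
#' @return List with `peak_voxel` (0-based index triple), `peak_mm`, and
#'   `value`.
#' @export
fc_peak <- function(map, search_mask = NULL) {
  m <- map$mask
  if (!is.null(search_mask)) {
    if (!identical(dim(search_mask), dim(map$array))) {
      stop("search_mask shape must equal the map grid")
    }
    m <- m & search_mask
  }
  vals <- map$array
  vals[!m] <- NA_real_
  if (all(is.na(vals))) stop("no in-mask voxels with defined values")
  mx <- max(vals, na.rm = TRUE)
  cand <- which(vals == mx, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
  ijk0 <- as.integer(cand[1, ]) - 1L
  list(peak_voxel = ijk0,
       peak_mm = as.numeric(voxel_to_mm(ijk0, map$affine)),
       value = mx)
}

#' Peak-shift distances for one subject/ROI/pipeline map
#'
#' @param map a `volume_grid` carrying a `roi_voxels` attribute (0-based
#'   indices of the ROI's member voxels), or supply `roi_voxels` directly.
#' @param roi_voxels optional n x 3 matrix overriding the attribute.
#' @return List with `peak_voxel`, `peak_mm`, `cog_mm`, `distance_mm`.
#' @export
peak_shift <- function(map, roi_voxels = NULL) {
  if (is.null(roi_voxels)) roi_voxels <- attr(map, "roi_voxels")
  if (is.null(roi_voxels)) stop("no ROI voxel set supplied")
  pk <- fc_peak(map)
  cog <- center_of_gravity(roi_voxels, map$affine)
  c(pk[c("peak_voxel", "peak_mm")],
    list(cog_mm = cog, distance_mm = sqrt(sum((pk$peak_mm - cog)^2))))
}

#' Paired peak-shift analysis across subjects for two ROIs
#'
#' For every subject, ROI, and pipeline, computes the Euclidean distance
#' between the FC peak and the ROI center of gravity. Then (i) per ROI, a
#' paired t-test of the distances between pipelines, and (ii) the delta
#' test: per subject, `delta_roi = |d_A - d_B|`, compared between the two
#' ROIs by a paired t-test. A significant delta test indicates the peak of
#' one ROI shifted more between pipelines than the other's.
#'
#' @param seed_maps list over subjects of `list(A =, B =)`, each a named
#'   list of `volume_grid` FC maps (with `roi_voxels` attributes).
#' @param roi_x,roi_y the two ROI names to contrast.
#' @return List with `distances` (long data.frame), `per_roi_tests` (named
#'   list of [paired_t()] results), `delta` (subjects x 2 matrix), and
#'   `delta_test`.
#' @export
peak_shift_analysis <- function(seed_maps, roi_x, roi_y) {
  rois <- c(roi_x, roi_y)
  rows <- list()
  for (s in seq_along(seed_maps)) {
    for (roi in rois) {
      for (p in c("A", "B")) {
        map <- seed_maps[[s]][[p]][[roi]]
        if (is.null(map)) {
          stop("subject ", s, " pipeline ", p, " is missing ROI '", roi, "'")
        }
        ps <- peak_shift(map)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, roi = roi, pipeline = p,
          distance_mm = ps$distance_mm,
          peak_i = ps$peak_voxel[1], peak_j = ps$peak_voxel[2],
          peak_k = ps$peak_voxel[3]
        )
      }
    }
  }
  dist_df <- do.call(rbind, rows)
  per_roi <- lapply(stats::setNames(rois, rois), function(roi) {
    da <- dist_df$distance_mm[dist_df$roi == roi & dist_df$pipeline == "A"]
    db <- dist_df$distance_mm[dist_df$roi == roi & dist_df$pipeline == "B"]
    paired_t(da, db)
  })
  delta <- sapply(stats::setNames(rois, rois), function(roi) {
    da <- dist_df$distance_mm[dist_df$roi == roi & dist_df$pipeline == "A"]
    db <- dist_df$distance_mm[dist_df$roi == roi & dist_df$pipeline == "B"]
    abs(da - db)
  })
  list(distances = dist_df, per_roi_tests = per_roi, delta = delta,
       delta_test = paired_t(delta[, roi_x], delta[, roi_y]))
}

#' Binarized error maps between two FC volumes
#'
#' At each threshold, both maps are binarized (signed values compared as
#' r >= threshold by default, or |r| >= threshold with `mode = "absolute"`);
#' the error volume marks voxels where the binarized maps disagree
#' (exclusive-or) and `mean_error` is its mean over the mask, so 0 means
#' identical binarized topology and 1 total disagreement.
#'
#' @param map_a,map_b `volume_grid`s on the same grid.
#' @param thresholds numeric vector of binarization thresholds.
#' @param mode `"signed"` or `"absolute"` binarization.
#' @return List of results, one per threshold: `threshold`, `error_volume`
#'   (a 0/1 `volume_grid`), `mean_error`.
#' @export
error_maps <- function(map_a, map_b, thresholds = c(0.3, 0.4, 0.5, 0.6),
                       mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!identical(dim(map_a$array), dim(map_b$array))) {
    stop("maps must share the grid")
  }
  mask <- map_a$mask & map_b$mask
  lapply(thresholds, function(th) {
    val_a <- if (mode == "signed") map_a$array else abs(map_a$array)
    val_b <- if (mode == "signed") map_b$array else abs(map_b$array)
    err <- array(0, dim = dim(val_a))
    err[mask] <- as.numeric((val_a[mask] >= th) != (val_b[mask] >= th))
    list(threshold = th,
         error_volume = volume_grid(err, map_a$affine, mask),
         mean_error = mean(err[mask]))
  })
}

#' Threshold-free cluster enhancement
#'
#' Integrates `extent(cluster at height h)^E * h^H` over thresholds
#' `h = dh, 2dh, ...` up to each voxel's value, boosting spatially extended
#' signal without a fixed cluster-forming threshold. Negative values are
#' enhanced by applying the transform to the negated map and negating the
#' result. Out-of-mask voxels are zeroed before enhancement.
#'
#' @param stat a `volume_grid` of test statistics.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; `NULL` uses max(|stat|)/100.
#' @param connectivity lattice connectivity: 6 (faces), 18, or 26.
#' @return A `volume_grid` of signed enhanced values.
#' @export
tfce <- function(stat, E = 0.5, H = 2.0, dh = NULL, connectivity = 6) {
  stopifnot(inherits(stat, "volume_grid"))
  x <- stat$array
  x[!stat$mask] <- 0
  if (!all(is.finite(x))) stop("statistic map must be finite")
  mx <- max(abs(x))
  if (mx == 0) {
    return(volume_grid(array(0, dim(x)), stat$affine, stat$mask))
  }
  if (is.null(dh)) dh <- mx / 100
  if (dh <= 0) stop("dh must be > 0")
  dims <- as.integer(dim(x))
  pos <- tfce_enhance_cpp(as.numeric(pmax(x, 0)), dims, E, H, dh, connectivity)
  neg <- tfce_enhance_cpp(as.numeric(pmax(-x, 0)), dims, E, H, dh, connectivity)
  volume_grid(array(pos - neg, dim(x)), stat$affine, stat$mask)
}

#' TFCE with sign-flip permutation family-wise error correction
#'
#' Observed statistic: the TFCE-enhanced voxelwise paired t-map of the
#' per-subject difference maps. Null distribution: the maximum |enhanced|
#' value over the mask under sign-flipping of subjects' difference maps.
#' Corrected p per voxel uses the `(1 + count) / (1 + n_perm)` convention,
#' so p is never 0.
#'
#' @param diff_maps list of per-subject difference `volume_grid`s (B - A)
#'   on a common grid.
#' @param n_perm number of sign-flip permutations.
#' @param seed RNG seed for the permutations.
#' @param E,H,dh,connectivity TFCE parameters (see [tfce()]).
#' @param alpha corrected significance level for the summary count.
#' @return List of class `tfce_result`: `enhanced` (`volume_grid`),
#'   `pfwe` (`volume_grid`), `t_map`, `null_max`, parameters, and
#'   `n_significant` voxels at `alpha`.
#' @export
tfce_permutation_fwe <- function(diff_maps, n_perm = 5000, seed = 1L,
                                 E = 0.5, H = 2.0, dh = NULL,
                                 connectivity = 6, alpha = 0.05) {
  n <- length(diff_maps)
  if (n < 6L) stop("need >= 6 subjects for sign-flip permutation resolution")
  dims <- dim(diff_maps[[1]]$array)
  affine <- diff_maps[[1]]$affine
  mask <- diff_maps[[1]]$mask
  for (m in diff_maps) {
    if (!identical(dim(m$array), dims)) stop("difference maps must share the grid")
  }
  D <- sapply(diff_maps, function(m) as.numeric(m$array))
  sumsq <- rowSums(D^2)
  t_map_of <- function(signs) {
    mu <- as.numeric(D %*% signs) / n
    va <- (sumsq - n * mu^2) / (n - 1)
    va[va < 1e-300] <- NA
    tt <- mu / sqrt(va / n)
    tt[is.na(tt)] <- 0
    tt
  }
  enhance <- function(tvec) {
    tfce(volume_grid(array(tvec, dims), affine, mask),
         E = E, H = H, dh = dh, connectivity = connectivity)
  }
  obs <- enhance(t_map_of(rep(1, n)))
  if (2^n <= n_perm) {
    message("n_perm = ", n_perm, " exceeds 2^", n,
            " sign patterns; using exhaustive enumeration")
    signs <- t(as.matrix(expand.grid(rep(list(c(-1, 1)), n))))
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  }
  null_max <- apply(signs, 2, function(s) {
    e <- enhance(t_map_of(s))
    max(abs(e$array[mask]))
  })
  n_used <- ncol(signs)
  obs_abs <- abs(obs$array)
  pf <- array(1, dims)
  pf[mask] <- vapply(obs_abs[mask], function(v) {
    (1 + sum(null_max >= v)) / (1 + n_used)
  }, numeric(1))
  structure(
    list(enhanced = obs, pfwe = volume_grid(pf, affine, mask),
         t_map = volume_grid(array(t_map_of(rep(1, n)), dims), affine, mask),
         null_max = null_max, E = E, H = H, dh = dh,
         connectivity = connectivity, n_permutations = n_used,
         n_significant = sum(pf[mask] < alpha)),
    class = "tfce_result"
  )
}

#' @export
print.tfce_result <- function(x, ...) {
  cat("<tfce_result>", x$n_permutations, "permutations;",
      x$n_significant, "voxel(s) with p_FWE < 0.05; E =", x$E,
      "H =", x$H, "\n")
  invisible(x)
}
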