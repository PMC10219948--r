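#' Per-parcel functional-connectivity strength
#'
#' For each column of the connectivity matrix: drop the diagonal, drop
#' entries with `|r|` below the threshold (correlations that weak are
#' unlikely to represent connections), and summarise the survivors with the
#' requested statistic. Surviving negative correlations keep their sign. By
#' default the average is over surviving entries only; `denominator =
#' "all"` divides the survivor sum by all off-diagonal entries instead
#' (mean only). A column with no survivors gets strength 0 and is flagged.
#'
#' @param conn a `connectivity_matrix`.
#' @param threshold absolute-correlation removal threshold (>= 0).
#' @param stat `"mean"` or `"median"`.
#' @param denominator `"survivors"` (default) or `"all"`.
#' @return Named numeric vector of per-parcel strengths with attribute
#'   `empty` (logical vector flagging no-survivor columns).
#' @export
fc_strength <- function(conn, threshold = 0.3, stat = c("mean", "median"),
                        denominator = c("survivors", "all")) {
  stat <- match.arg(stat)
  denominator <- match.arg(denominator)
  if (threshold < 0) stop("threshold must be >= 0")
  r <- unclass(conn)
  n <- ncol(r)
  out <- numeric(n)
  empty <- logical(n)
  for (j in seq_len(n)) {
    col <- r[-j, j]
    col <- col[!is.na(col)]
    keep <- col[abs(col) >= threshold]
    if (!length(keep)) {
      empty[j] <- TRUE
      out[j] <- 0
    } else if (stat == "mean") {
      out[j] <- if (denominator == "survivors") mean(keep)
                else sum(keep) / (n - 1)
    } else {
      out[j] <- stats::median(keep)
    }
  }
  names(out) <- colnames(r)
  attr(out, "empty") <- empty
  out
}

#' Paired comparison of FC strength between pipelines
#'
#' Runs the full per-subject chain — optional surface smoothing of the BOLD
#' timeseries, parcel timeseries extraction under each pipeline's own
#' scheme, Pearson connectivity, thresholded strength — then a per-parcel
#' paired t-test between pipelines, Bonferroni-corrected at
#' `alpha / (n_parcels/2)` (34 per hemisphere in the DKT convention).
#'
#' @param bundles list of per-subject `list(A =, B =)` pipeline bundles.
#' @param stat `"mean"` or `"median"` strength statistic.
#' @param smoothing_fwhm surface smoothing FWHM in mm applied to every
#'   vertex timepoint map before parcel extraction (0 = none).
#' @param threshold `|r|` removal threshold.
#' @param alpha family-wise alpha before correction.
#' @param denominator see [fc_strength()].
#' @return A `comparison_report` with attribute `strengths` (list with
#'   per-pipeline parcels x subjects matrices).
#' @export
compare_fc_strength <- function(bundles, stat = c("mean", "median"),
                                smoothing_fwhm = 0, threshold = 0.3,
                                alpha = 0.05,
                                denominator = c("survivors", "all")) {
  stat <- match.arg(stat)
  denominator <- match.arg(denominator)
  bundles <- complete_pairs(bundles)
  if (length(bundles) < 2L) stop("need >= 2 complete subjects")
  strength_of <- function(bundle) {
    ts <- bundle$timeseries
    if (smoothing_fwhm > 0) {
      smoothed <- smooth_timeseries(ts, bundle$surface, smoothing_fwhm)
      ts <- smoothed
    }
    pts <- parcel_timeseries(ts, bundle$scheme)
    conn <- connectivity_matrix(pts)
    fc_strength(conn, threshold, stat, denominator)
  }
  sa <- sapply(bundles, function(s) strength_of(s$A))
  sb <- sapply(bundles, function(s) strength_of(s$B))
  n_per_hemi <- bundles[[1]]$A$scheme$n_parcels / 2
  thr <- bonferroni_threshold(alpha, n_per_hemi)
  tests <- lapply(seq_len(nrow(sa)), function(i) paired_t(sa[i, ], sb[i, ]))
  rep <- comparison_report(rownames(sa), tests, thr,
                           sprintf("bonferroni(%d)", n_per_hemi))
  attr(rep, "strengths") <- list(A = sa, B = sb)
  rep
}

#' Smooth every timepoint of a vertex timeseries on the surface
#'
#' Applies [smooth_surface()]'s diffusion operator to each timepoint column.
#'
#' @param ts a `timeseries_bundle`.
#' @param surface the owning `surface_model`.
#' @param fwhm_mm smoothing FWHM in mm.
#' @return A smoothed `timeseries_bundle`.
#' @export
smooth_timeseries <- function(ts, surface, fwhm_mm) {
  n_it <- smoothing_iterations(surface, fwhm_mm)
  if (n_it == 0L) return(ts)
  S <- diffusion_operator(surface)
  x <- ts$data
  for (i in seq_len(n_it)) x <- as.matrix(S %*% x)
  timeseries_bundle(x, ts$tr_seconds, ts$run_boundaries)
}

#' Seed-to-vertex correlation map
#'
#' Pearson correlation between the seed parcel's mean timeseries and every
#' vertex timeseries in the same hemisphere; opposite-hemisphere vertices
#' are missing in the returned map.
#'
#' @param bundle a `pipeline_bundle`.
#' @param seed_parcel parcel name or identifier in the bundle's scheme.
#' @return A `scalar_map` of correlations over the bundle's surface.
#' @export
seed_vertex_map <- function(bundle, seed_parcel) {
  sch <- bundle$scheme
  id <- if (is.character(seed_parcel)) {
    match(seed_parcel, sch$parcel_names)
  } else {
    as.integer(seed_parcel)
  }
  if (is.na(id) || id < 1 || id > sch$n_parcels) {
    stop("seed parcel '", seed_parcel, "' not in scheme")
  }
  members <- which(sch$labels == id)
  if (!length(members)) stop("seed parcel '", seed_parcel, "' is empty")
  hemi <- unique(bundle$surface$vertex_hemi[members])
  if (length(hemi) > 1L) hemi <- hemi[1]
  seed_ts <- colMeans(bundle$timeseries$data[members, , drop = FALSE])
  same_hemi <- bundle$surface$vertex_hemi == hemi
  r <- rep(NA_real_, n_vertices(bundle$surface))
  r[same_hemi] <- suppressWarnings(
    as.numeric(stats::cor(t(bundle$timeseries$data[same_hemi, , drop = FALSE]),
                          seed_ts))
  )
  scalar_map(r, "other", bundle$surface)
}

#' Group comparison of seed-network maps with a minimum-area filter
#'
#' Identical inference to [vertexwise_paired_comparison()] (paired t,
#' cluster-mass sign-flip FWE) with an additional minimum cluster area:
#' clusters smaller than `min_cluster_area_mm2` (summed vertex Voronoi
#' areas) are reported in the excluded-clusters ledger rather than tested.
#'
#' @inheritParams vertexwise_paired_comparison
#' @param min_cluster_area_mm2 minimum surviving cluster area (mm^2).
#' @return A `vertex_cluster_report`.
#' @export
network_group_comparison <- function(maps_a, maps_b, surface,
                                     min_cluster_area_mm2 = 50,
                                     vertexwise_p = 1e-4, n_perm = 5000,
                                     seed = 1L, cluster_alpha = 0.05) {
  vertexwise_paired_comparison(
    maps_a, maps_b, surface,
    vertexwise_p = vertexwise_p, n_perm = n_perm, seed = seed,
    min_cluster_area_mm2 = min_cluster_area_mm2,
    cluster_alpha = cluster_alpha
  )
}
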