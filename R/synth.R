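#' Subdivided-icosahedron sphere mesh
#'
#' Standard icosphere construction: the regular icosahedron is subdivided
#' `level` times (each triangle into four) and vertices are projected to the
#' sphere. Vertex count per hemisphere mesh is `10 * 4^level + 2`.
#'
#' @param level subdivision level (>= 0).
#' @param radius sphere radius in mm.
#' @param center length-3 numeric center in mm.
#' @param hemisphere `"left"` or `"right"` tag for the resulting surface.
#' @return A `surface_model`.
#' @export
icosphere <- function(level = 3, radius = 30, center = c(0, 0, 0),
                      hemisphere = "left") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (l in seq_len(level)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    get_mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
      newf[(4 * t - 3):(4 * t), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca)
      )
    }
    v <- verts
    f <- newf
  }
  coords <- sweep(v * radius, 2, center, `+`)
  surface_model(coords, f, hemisphere = hemisphere)
}

# join two hemisphere meshes into one disconnected "both" surface
combine_hemispheres <- function(left, right) {
  nl <- n_vertices(left)
  surface_model(
    rbind(left$vertex_coords, right$vertex_coords),
    rbind(left$faces, right$faces + nl),
    hemisphere = "both",
    vertex_hemi = c(rep("left", nl), rep("right", n_vertices(right)))
  )
}

#' Nearest-seed (Voronoi) parcellation of a surface
#'
#' Seeds are placed by farthest-point sampling from a random start vertex
#' (quasi-uniform coverage, so parcel sizes are roughly even, as in real
#' atlases) and every vertex is labelled by its nearest seed (Euclidean
#' distance), which yields contiguous parcels with shared boundaries on a
#' convex mesh. Left-hemisphere parcels take identifiers 1..n, right
#' n+1..2n; names are prefixed `lh_` / `rh_`. Uses the current RNG state.
#'
#' @param surface a `surface_model` (single or combined hemisphere).
#' @param n_per_hemi parcels per hemisphere.
#' @return A `parcel_scheme`.
#' @export
voronoi_parcels <- function(surface, n_per_hemi = 34) {
  hemis <- unique(surface$vertex_hemi)
  labels <- integer(n_vertices(surface))
  names_out <- character(0)
  offset <- 0L
  for (h in c("left", "right")) {
    idx <- which(surface$vertex_hemi == h)
    if (!length(idx)) next
    if (length(idx) < n_per_hemi) {
      stop("hemisphere ", h, " has ", length(idx),
           " vertices; cannot host ", n_per_hemi, " parcels")
    }
    vc_all <- surface$vertex_coords[idx, , drop = FALSE]
    seeds_local <- integer(n_per_hemi)
    seeds_local[1] <- sample(length(idx), 1)
    mind <- rowSums(sweep(vc_all, 2, vc_all[seeds_local[1], ])^2)
    if (n_per_hemi > 1) for (k in 2:n_per_hemi) {
      seeds_local[k] <- which.max(mind)
      mind <- pmin(mind, rowSums(sweep(vc_all, 2, vc_all[seeds_local[k], ])^2))
    }
    sc <- vc_all[seeds_local, , drop = FALSE]
    vc <- surface$vertex_coords[idx, , drop = FALSE]
    d2 <- outer(rowSums(vc^2), rep(1, n_per_hemi)) -
      2 * vc %*% t(sc) + outer(rep(1, length(idx)), rowSums(sc^2))
    labels[idx] <- offset + max.col(-d2, ties.method = "first")
    names_out <- c(names_out,
                   paste0(substr(h, 1, 1), "h_parcel_", seq_len(n_per_hemi)))
    offset <- offset + n_per_hemi
  }
  parcel_scheme(labels, names_out)
}

#' Relabel parcel-boundary vertices
#'
#' Emulates a pipeline-dependent vertex-to-parcel assignment: each vertex
#' with at least one 1-ring neighbour in a different parcel is, with
#' probability `p_swap`, relabelled to the majority foreign neighbouring
#' label (ties broken by the lowest parcel identifier). One uniform draw per
#' boundary vertex is thresholded at `p_swap`, so under a fixed RNG state
#' the swapped set grows monotonically with `p_swap`.
#'
#' @param scheme a `parcel_scheme`.
#' @param surface the owning `surface_model`.
#' @param p_swap probability in \[0, 1\] that a boundary vertex is swapped.
#' @return List with `scheme` (perturbed `parcel_scheme`) and `relabelled`
#'   (integer vertex indices that changed parcel).
#' @export
perturb_boundary_labels <- function(scheme, surface, p_swap) {
  if (p_swap < 0 || p_swap > 1) stop("p_swap must be in [0, 1]")
  adj <- surface_adjacency(surface)
  lab <- scheme$labels
  boundary <- which(vapply(seq_along(lab), function(v) {
    lab[v] > 0L && any(lab[adj[[v]]] != lab[v] & lab[adj[[v]]] > 0L)
  }, logical(1)))
  u <- stats::runif(length(boundary))
  to_swap <- boundary[u < p_swap]
  new_lab <- lab
  for (v in to_swap) {
    foreign <- lab[adj[[v]]]
    foreign <- foreign[foreign != lab[v] & foreign > 0L]
    tab <- table(foreign)
    best <- as.integer(names(tab)[tab == max(tab)])
    new_lab[v] <- min(best)
  }
  counts <- tabulate(new_lab[new_lab > 0L], nbins = scheme$n_parcels)
  if (any(counts == 0L)) {
    stop("p_swap = ", p_swap, " emptied parcel(s): ",
         paste(scheme$parcel_names[counts == 0L], collapse = ", "),
         "; reduce p_swap")
  }
  list(scheme = parcel_scheme(new_lab, scheme$parcel_names),
       relabelled = to_swap[new_lab[to_swap] != lab[to_swap]])
}

#' Block covariance matrix for parcel networks
#'
#' Unit-variance covariance with within-network correlation and
#' between-network correlation `rho_out`; parcels are assigned to
#' `n_blocks` networks in contiguous runs. Networks are heterogeneous, as
#' in real resting-state data: block b's within-correlation ramps from
#' `0.7 * rho_in` to `1.3 * rho_in` across blocks, so parcels carry a
#' stable network-strength profile (this is what makes first principal
#' components of graph metrics reproducible across subjects).
#'
#' @param n_parcels total parcel count.
#' @param n_blocks number of networks.
#' @param rho_in,rho_out mean within / constant between correlations;
#'   requires `0.7 * rho_in > rho_out >= 0`.
#' @return List with `sigma` (matrix) and `block` (parcel -> network index).
#' @export
block_covariance <- function(n_parcels, n_blocks = 5, rho_in = 0.4,
                             rho_out = 0.1) {
  if (!(0.7 * rho_in > rho_out && rho_out >= 0)) {
    stop("need rho_in > rho_out >= 0 with margin (0.7 * rho_in > rho_out)")
  }
  block <- sort(((seq_len(n_parcels) - 1L) * n_blocks) %/% n_parcels + 1L)
  rho_b <- rho_in * seq(0.7, 1.3, length.out = n_blocks)
  sigma <- matrix(rho_out, n_parcels, n_parcels)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    sigma[idx, idx] <- rho_b[b]
  }
  diag(sigma) <- 1
  list(sigma = sigma, block = block)
}

#' Configuration of the synthetic paired-pipeline generator
#'
#' Defaults mirror the study conditions the analysis targets: 58 subjects,
#' a 34-parcel-per-hemisphere scheme on paired icosphere hemispheres, 888
#' timepoints as three concatenated runs (the post-scrub length of 3 runs of
#' 300 TRs at TR = 1 s with the first 4 frames dropped), pipeline B thicker
#' cortex and lower gyrification, and a small boundary-relabelling rate.
#' Geometry is a scaled-down cortex (30 mm hemisphere radius) so vertex
#' analyses stay tractable.
#'
#' @param n_subjects number of subjects.
#' @param n_parcels_per_hemisphere parcels per hemisphere (34 DKT-style;
#'   use ~167 for a Gordon-style 333-parcel graph analysis).
#' @param mesh_subdivision_level icosphere subdivision per hemisphere.
#' @param mesh_radius_mm hemisphere sphere radius (mm).
#' @param n_timepoints total concatenated timepoints.
#' @param n_runs number of equal concatenated runs.
#' @param tr_seconds repetition time (s).
#' @param thickness_base_mm,gyrification_base mean cortical thickness (mm)
#'   and gyrification index of pipeline A.
#' @param delta_thick_mm pipeline offset B - A for thickness (mm).
#' @param delta_gyr pipeline offset B - A for gyrification (negative:
#'   B folds less).
#' @param subject_sd per-subject, per-parcel standard deviation of the B - A
#'   structural difference.
#' @param map_noise_sd vertex-level map noise (mm).
#' @param boundary_swap_prob fraction of parcel-boundary vertices relabelled
#'   in pipeline B.
#' @param n_networks,rho_in,rho_out block-covariance parcel network model.
#' @param vertex_noise_sd BOLD noise added on top of the own-parcel latent
#'   signal (latent sd is 1).
#' @param volume_grid_shape,voxel_size_mm seed-map volume geometry.
#' @param seed_rois named list of ROI definitions for seed volumes; each a
#'   list with `center_mm`, `shift_mm` (3-vector applied to pipeline B's FC
#'   peak), `amplitude`, `bump_sigma_mm`, `roi_radius_mm`, `noise_sd`,
#'   `noise_smooth_sigma_mm`.
#' @param sigma optional explicit parcel covariance overriding the block
#'   model; symmetric positive-definite, `2 * n_parcels_per_hemisphere`
#'   square.
#' @param rng_seed integer seed controlling the whole dataset.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 58,
                         n_parcels_per_hemisphere = 34,
                         mesh_subdivision_level = 4,
                         mesh_radius_mm = 30,
                         n_timepoints = 888,
                         n_runs = 3,
                         tr_seconds = 1.0,
                         thickness_base_mm = 2.5,
                         gyrification_base = 2.5,
                         delta_thick_mm = 0.1,
                         delta_gyr = -0.1,
                         subject_sd = 0.1,
                         map_noise_sd = 0.05,
                         boundary_swap_prob = 0.13,
                         n_networks = 5,
                         rho_in = 0.4,
                         rho_out = 0.1,
                         vertex_noise_sd = 1.0,
                         volume_grid_shape = c(24, 24, 24),
                         voxel_size_mm = 3,
                         seed_rois = default_seed_rois(),
                         sigma = NULL,
                         rng_seed = 1L) {
  cfg <- as.list(environment())
  n_parcels <- 2L * n_parcels_per_hemisphere
  if (is.null(sigma)) {
    bc <- block_covariance(n_parcels, n_networks, rho_in, rho_out)
  } else {
    if (!isSymmetric(unname(sigma)) || nrow(sigma) != n_parcels) {
      stop("sigma must be a symmetric ", n_parcels, " x ", n_parcels, " matrix")
    }
    bc <- list(sigma = sigma,
               block = sort(((seq_len(n_parcels) - 1L) * n_networks) %/%
                              n_parcels + 1L))
  }
  ev <- eigen(bc$sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("network covariance is not positive definite (min eigenvalue ",
         signif(min(ev), 3),
         "); increase rho_in - rho_out separation or project to the ",
         "nearest PD matrix before use")
  }
  cfg$sigma <- bc$sigma
  cfg$network_block <- bc$block
  class(cfg) <- "synth_config"
  cfg
}

#' Default seed-map ROI set
#'
#' Two left-hemisphere ROIs at opposite ends of the structural-difference
#' axis: `roi_shifted` receives a 3 mm FC-peak displacement in pipeline B,
#' `roi_stable` none.
#'
#' @return Named list of ROI definitions (see [synth_config()]).
#' @export
default_seed_rois <- function() {
  list(
    roi_shifted = list(center_mm = c(-12, 9, 6), shift_mm = c(3, 0, 0),
                       amplitude = 1, bump_sigma_mm = 6, roi_radius_mm = 6,
                       noise_sd = 0.05, noise_smooth_sigma_mm = 3),
    roi_stable = list(center_mm = c(9, -12, -6), shift_mm = c(0, 0, 0),
                      amplitude = 1, bump_sigma_mm = 6, roi_radius_mm = 6,
                      noise_sd = 0.05, noise_smooth_sigma_mm = 3)
  )
}

#' Generate a paired-pipeline synthetic dataset
#'
#' Emits, for every subject, a pipeline-A and a pipeline-B bundle sharing
#' the same cortical mesh and the same vertex BOLD signal (the two pipelines
#' reconstruct the same acquisition), differing by: a B - A thickness offset
#' plus per-subject noise, a B - A gyrification offset plus noise, and a
#' boundary-perturbed parcel scheme in B. Vertex BOLD is the subject's
#' own-parcel latent network signal (timepoint-wise draws from the block
#' covariance) plus white vertex noise. Fully reproducible from
#' `config$rng_seed`.
#'
#' @param config a `synth_config`.
#' @return List with `subjects` (list of `list(A =, B =)` pipeline bundles)
#'   and `ground_truth` (offsets, covariance, relabelled vertex sets,
#'   injected peak shifts).
#' @export
generate_paired_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed)
  lh <- icosphere(config$mesh_subdivision_level, config$mesh_radius_mm,
                  center = c(-1.5 * config$mesh_radius_mm, 0, 0),
                  hemisphere = "left")
  rh <- icosphere(config$mesh_subdivision_level, config$mesh_radius_mm,
                  center = c(1.5 * config$mesh_radius_mm, 0, 0),
                  hemisphere = "right")
  surface <- combine_hemispheres(lh, rh)
  scheme_a <- voronoi_parcels(surface, config$n_parcels_per_hemisphere)
  n_parcels <- scheme_a$n_parcels
  nv <- n_vertices(surface)
  areas <- vertex_areas(surface)
  chol_sigma <- chol(config$sigma)
  run_len <- config$n_timepoints %/% config$n_runs
  lens <- rep(run_len, config$n_runs)
  lens[config$n_runs] <- config$n_timepoints - sum(lens[-config$n_runs])
  run_boundaries <- if (config$n_runs > 1) cumsum(lens)[-config$n_runs] + 1L else integer()

  subcort <- subcortical_base_volumes()
  subjects <- vector("list", config$n_subjects)
  relabelled <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("sub-%03d", s)
    pb <- perturb_boundary_labels(scheme_a, surface, config$boundary_swap_prob)
    scheme_b <- pb$scheme
    relabelled[[s]] <- pb$relabelled

    thick_a <- config$thickness_base_mm +
      stats::rnorm(1, 0, config$subject_sd) +
      stats::rnorm(nv, 0, config$map_noise_sd)
    thick_a <- pmax(thick_a, 0)
    d_thick <- config$delta_thick_mm +
      stats::rnorm(n_parcels, 0, config$subject_sd)
    thick_b <- pmax(thick_a + d_thick[pmax(scheme_a$labels, 1L)], 0)
    gyr_a <- config$gyrification_base +
      stats::rnorm(1, 0, config$subject_sd) +
      stats::rnorm(nv, 0, config$map_noise_sd)
    d_gyr <- config$delta_gyr + stats::rnorm(n_parcels, 0, config$subject_sd)
    gyr_b <- gyr_a + d_gyr[pmax(scheme_a$labels, 1L)]

    latent <- t(chol_sigma) %*%
      matrix(stats::rnorm(n_parcels * config$n_timepoints),
             n_parcels, config$n_timepoints)
    bold <- latent[pmax(scheme_a$labels, 1L), , drop = FALSE] +
      matrix(stats::rnorm(nv * config$n_timepoints, 0, config$vertex_noise_sd),
             nv, config$n_timepoints)
    ts <- timeseries_bundle(bold, config$tr_seconds, run_boundaries)

    parcel_vol <- function(sch, thick) {
      cort <- data.frame(
        parcel = sch$parcel_names,
        volume_mm3 = vapply(seq_len(n_parcels), function(p) {
          members <- sch$labels == p
          sum(areas[members]) * mean(thick[members])
        }, numeric(1))
      )
      sub <- data.frame(
        parcel = names(subcort),
        volume_mm3 = subcort * exp(stats::rnorm(length(subcort), 0, 0.02))
      )
      rbind(cort, sub)
    }
    vols <- list(A = parcel_vol(scheme_a, thick_a),
                 B = parcel_vol(scheme_b, thick_b))

    mk <- function(pid, sch, thick, gyr, pv) {
      pipeline_bundle(
        subject_id = sid, pipeline_id = pid, surface = surface, scheme = sch,
        thickness = scalar_map(thick, "thickness_mm", surface),
        gyrification = scalar_map(gyr, "gyrification", surface),
        parcel_volumes = pv, timeseries = ts
      )
    }
    subjects[[s]] <- list(
      A = mk("A", scheme_a, thick_a, gyr_a, vols$A),
      B = mk("B", scheme_b, thick_b, gyr_b, vols$B)
    )
  }
  list(
    subjects = subjects,
    ground_truth = list(
      delta_thick_mm = config$delta_thick_mm,
      delta_gyr = config$delta_gyr,
      sigma = config$sigma,
      network_block = config$network_block,
      relabelled = relabelled,
      peak_shift_mm = lapply(config$seed_rois, `[[`, "shift_mm")
    )
  )
}

# 7 subcortical structures per hemisphere, typical adult volumes (mm^3)
subcortical_base_volumes <- function() {
  base <- c(thalamus = 7500, caudate = 3700, putamen = 4800, pallidum = 1700,
            hippocampus = 4200, amygdala = 1600, accumbens = 600)
  out <- c(base, base)
  names(out) <- c(paste0("lh_", names(base)), paste0("rh_", names(base)))
  out
}

#' Generate one synthetic seed-FC volume
#'
#' The FC map is a Gaussian bump of the configured amplitude at the ROI
#' center — displaced by the ROI's `shift_mm` for pipeline B — plus
#' spatially smooth noise rescaled to the configured standard deviation.
#' Uses the current RNG state; seed before calling for reproducibility.
#'
#' @param config a `synth_config`.
#' @param roi_id name of an ROI in `config$seed_rois`.
#' @param pipeline_id `"A"` or `"B"`.
#' @return A `volume_grid` with attributes `roi_voxels` (0-based index
#'   matrix of the ROI's member voxels) and `true_peak_mm`.
#' @export
generate_seed_volume <- function(config, roi_id, pipeline_id = c("A", "B")) {
  stopifnot(inherits(config, "synth_config"))
  pipeline_id <- match.arg(pipeline_id)
  roi <- config$seed_rois[[roi_id]]
  if (is.null(roi)) stop("ROI '", roi_id, "' is not defined in the config")
  dm <- config$volume_grid_shape
  vs <- config$voxel_size_mm
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -vs * (dm - 1) / 2  # grid centered on the origin
  center <- roi$center_mm
  if (pipeline_id == "B") center <- center + roi$shift_mm
  g <- lapply(1:3, function(ax) (seq_len(dm[ax]) - 1) * vs + affine[ax, 4])
  lo <- vapply(g, min, numeric(1)); hi <- vapply(g, max, numeric(1))
  if (any(center < lo) || any(center > hi)) {
    stop("injected shift moves the FC peak of '", roi_id,
         "' outside the volume mask")
  }
  d2 <- outer(outer((g[[1]] - center[1])^2, (g[[2]] - center[2])^2, `+`),
              (g[[3]] - center[3])^2, `+`)
  bump <- roi$amplitude * exp(-d2 / (2 * roi$bump_sigma_mm^2))
  vol <- volume_grid(bump, affine)
  if (roi$noise_sd > 0) {
    noise <- volume_grid(array(stats::rnorm(prod(dm)), dim = dm), affine)
    noise <- smooth_volume(noise, roi$noise_smooth_sigma_mm)$array
    noise <- noise / stats::sd(noise) * roi$noise_sd
    vol$array <- vol$array + noise
  }
  d2roi <- outer(outer((g[[1]] - roi$center_mm[1])^2,
                       (g[[2]] - roi$center_mm[2])^2, `+`),
                 (g[[3]] - roi$center_mm[3])^2, `+`)
  roi_vox <- which(d2roi <= roi$roi_radius_mm^2, arr.ind = TRUE) - 1L
  attr(vol, "roi_voxels") <- unname(roi_vox)
  attr(vol, "true_peak_mm") <- center
  vol
}
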