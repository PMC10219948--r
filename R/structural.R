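#' Per-parcel subject means of a structural quantity
#'
#' @param bundle a `pipeline_bundle`.
#' @param quantity `"thickness"` or `"gyrification"`.
#' @return Named numeric vector over the bundle's parcels (its own scheme).
#' @keywords internal
parcel_scalar_means <- function(bundle, quantity) {
  map <- switch(quantity,
                thickness = bundle$thickness$values,
                gyrification = bundle$gyrification$values,
                stop("unknown quantity: ", quantity))
  sch <- bundle$scheme
  out <- vapply(seq_len(sch$n_parcels), function(p) {
    mean(map[sch$labels == p], na.rm = TRUE)
  }, numeric(1))
  names(out) <- sch$parcel_names
  out
}

# drop subjects missing a pipeline, warning with the count
complete_pairs <- function(bundles) {
  ok <- vapply(bundles, function(s) {
    !is.null(s$A) && !is.null(s$B)
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " subject(s) dropped: missing one pipeline")
  }
  bundles[ok]
}

#' Parcel-level paired structural comparison between pipelines
#'
#' For each parcel, a paired two-sided t-test of the per-subject parcel
#' means (thickness, gyrification) or parcel volumes between pipelines A
#' and B, Bonferroni-corrected at 0.05/34 per hemisphere for cortical
#' parcels and 0.05/7 for the subcortical volume table.
#'
#' @param bundles list of per-subject `list(A =, B =)` pipeline bundles.
#' @param quantity `"thickness"`, `"gyrification"`, or `"volume"`.
#' @param alpha family-wise alpha before correction.
#' @return A `comparison_report` data.frame with one row per parcel; the
#'   volume report covers cortical parcels and the subcortical table, each
#'   with its own corrected threshold.
#' @export
parcel_structural_comparison <- function(bundles,
                                         quantity = c("thickness",
                                                      "gyrification",
                                                      "volume"),
                                         alpha = 0.05) {
  quantity <- match.arg(quantity)
  bundles <- complete_pairs(bundles)
  if (length(bundles) < 2L) stop("need >= 2 complete subjects")
  if (quantity == "volume") {
    get_vol <- function(b) {
      stats::setNames(b$parcel_volumes$volume_mm3, b$parcel_volumes$parcel)
    }
    va <- sapply(bundles, function(s) get_vol(s$A))
    vb <- sapply(bundles, function(s) get_vol(s$B))
    parcels <- rownames(va)
    cortical <- parcels %in% bundles[[1]]$A$scheme$parcel_names
    n_per_hemi <- bundles[[1]]$A$scheme$n_parcels / 2
    n_subcort_per_hemi <- sum(cortical == FALSE) / 2
    thr <- ifelse(cortical,
                  bonferroni_threshold(alpha, n_per_hemi),
                  bonferroni_threshold(alpha, n_subcort_per_hemi))
    tests <- lapply(seq_along(parcels), function(i) paired_t(va[i, ], vb[i, ]))
    return(comparison_report(
      parcels, tests, thr,
      sprintf("bonferroni(cortical %d/hemi, subcortical %d/hemi)",
              n_per_hemi, n_subcort_per_hemi)
    ))
  }
  ma <- sapply(bundles, function(s) parcel_scalar_means(s$A, quantity))
  mb <- sapply(bundles, function(s) parcel_scalar_means(s$B, quantity))
  n_per_hemi <- bundles[[1]]$A$scheme$n_parcels / 2
  thr <- bonferroni_threshold(alpha, n_per_hemi)
  tests <- lapply(seq_len(nrow(ma)), function(i) paired_t(ma[i, ], mb[i, ]))
  comparison_report(rownames(ma), tests, thr,
                    sprintf("bonferroni(%d)", n_per_hemi))
}

#' Jaccard overlap of one parcel's vertex sets between two schemes
#'
#' `|V_A intersect V_B| / |V_A union V_B|` over the vertex sets the two
#' schemes assign to the parcel. 1 iff the sets are equal, 0 iff disjoint.
#'
#' @param scheme_a,scheme_b `parcel_scheme`s over the same vertex set.
#' @param parcel parcel name or integer identifier.
#' @return Jaccard coefficient in \[0, 1\].
#' @export
jaccard <- function(scheme_a, scheme_b, parcel) {
  if (length(scheme_a$labels) != length(scheme_b$labels)) {
    stop("schemes must share the vertex count")
  }
  resolve <- function(sch) {
    if (is.character(parcel)) {
      id <- match(parcel, sch$parcel_names)
      if (is.na(id)) stop("parcel '", parcel, "' absent from scheme")
      id
    } else {
      if (parcel < 1 || parcel > sch$n_parcels) {
        stop("parcel ", parcel, " absent from scheme")
      }
      as.integer(parcel)
    }
  }
  va <- which(scheme_a$labels == resolve(scheme_a))
  vb <- which(scheme_b$labels == resolve(scheme_b))
  length(intersect(va, vb)) / length(union(va, vb))
}

# connected components of a vertex subset under mesh 1-ring adjacency
mesh_components <- function(vertices, adj) {
  inset <- logical(length(adj))
  inset[vertices] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (v in vertices) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      nb <- adj[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Vertex-wise paired comparison with cluster-mass permutation FWE
#'
#' Per-vertex paired t-tests between pipelines, thresholded at the
#' two-sided `vertexwise_p`; suprathreshold vertices are grouped into
#' connected clusters on the mesh (1-ring adjacency) scored by mass (sum of
#' |t|). Family-wise correction compares each observed mass to the
#' distribution of the maximum cluster mass under sign-flipping of the
#' paired differences (the exchangeability the paired design guarantees);
#' corrected p uses the (1 + count)/(1 + n_perm) convention. If `n_perm`
#' exceeds the number of distinct sign patterns, the enumeration becomes
#' exhaustive with a message.
#'
#' @param maps_a,maps_b per-subject maps: numeric matrices
#'   (vertices x subjects) or lists of `scalar_map`s.
#' @param surface the common `surface_model`.
#' @param vertexwise_p two-sided vertex-forming threshold.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer RNG seed for the permutations.
#' @param min_cluster_area_mm2 clusters whose summed vertex Voronoi area is
#'   below this are moved to `excluded_clusters` (0 disables).
#' @param cluster_alpha corrected significance level reported per cluster.
#' @return List of class `vertex_cluster_report`: `clusters` (vertices,
#'   mass, area_mm2, p_corrected, significant), `excluded_clusters`,
#'   `t_map`, `null_max_mass`, `vertexwise_threshold_p`, `n_permutations`.
#' @export
vertexwise_paired_comparison <- function(maps_a, maps_b, surface,
                                         vertexwise_p = 1e-4,
                                         n_perm = 5000, seed = 1L,
                                         min_cluster_area_mm2 = 0,
                                         cluster_alpha = 0.05) {
  as_mat <- function(m) {
    if (is.list(m)) sapply(m, function(x) x$values) else as.matrix(m)
  }
  A <- as_mat(maps_a)
  B <- as_mat(maps_b)
  stopifnot(identical(dim(A), dim(B)), nrow(A) == n_vertices(surface))
  n <- ncol(A)
  if (n < 6L) stop("need >= 6 subjects for sign-flip permutation resolution")
  D <- B - A
  sumsq <- rowSums(D^2)
  t_of <- function(signs) {
    mu <- as.numeric(D %*% signs) / n
    va <- (sumsq - n * mu^2) / (n - 1)
    va[va < 0] <- 0
    se <- sqrt(va / n)
    tt <- mu / se
    tt[se == 0 & mu == 0] <- 0
    tt[se == 0 & mu != 0] <- Inf * sign(mu[se == 0 & mu != 0])
    tt
  }
  t_obs <- t_of(rep(1, n))
  t_crit <- stats::qt(1 - vertexwise_p / 2, df = n - 1)
  adj <- surface_adjacency(surface)
  areas <- vertex_areas(surface)

  if (2^n <= n_perm) {
    message("n_perm = ", n_perm, " exceeds 2^", n,
            " sign patterns; using exhaustive enumeration")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    signs <- t(signs)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  }
  n_used <- ncol(signs)
  # one multiply gives all permuted means; sd follows from the flip-invariant sum of squares
  mu <- (D %*% signs) / n
  va <- (sumsq - n * mu^2) / (n - 1)
  va[va < 0] <- 0
  se <- sqrt(va / n)
  Tperm <- as.matrix(mu / se)
  Tperm[!is.finite(Tperm)] <- 0
  null_max <- vapply(seq_len(n_used), function(k) {
    supra <- which(abs(Tperm[, k]) > t_crit)
    if (!length(supra)) return(0)
    max(vapply(mesh_components(supra, adj), function(cc) {
      sum(abs(Tperm[cc, k]))
    }, numeric(1)))
  }, numeric(1))

  supra_obs <- which(abs(t_obs) > t_crit)
  comps <- if (length(supra_obs)) mesh_components(supra_obs, adj) else list()
  clusters <- lapply(comps, function(cc) {
    mass <- sum(abs(t_obs[cc]))
    list(vertices = cc, mass = mass, area_mm2 = sum(areas[cc]),
         p_corrected = (1 + sum(null_max >= mass)) / (1 + n_used))
  })
  excluded <- list()
  if (min_cluster_area_mm2 > 0 && length(clusters)) {
    small <- vapply(clusters, function(cl) {
      cl$area_mm2 < min_cluster_area_mm2
    }, logical(1))
    excluded <- clusters[small]
    clusters <- clusters[!small]
  }
  for (i in seq_along(clusters)) {
    clusters[[i]]$significant <- clusters[[i]]$p_corrected < cluster_alpha
  }
  structure(
    list(clusters = clusters, excluded_clusters = excluded, t_map = t_obs,
         null_max_mass = null_max, vertexwise_threshold_p = vertexwise_p,
         n_permutations = n_used, cluster_alpha = cluster_alpha,
         min_cluster_area_mm2 = min_cluster_area_mm2),
    class = "vertex_cluster_report"
  )
}

#' @export
print.vertex_cluster_report <- function(x, ...) {
  cat("<vertex_cluster_report>", length(x$clusters), "cluster(s),",
      x$n_permutations, "permutations, vertexwise p <",
      x$vertexwise_threshold_p, "\n")
  for (cl in x$clusters) {
    cat(sprintf("  %d vertices, mass %.1f, area %.1f mm^2, p_FWE = %.4f%s\n",
                length(cl$vertices), cl$mass, cl$area_mm2, cl$p_corrected,
                if (isTRUE(cl$significant)) " *" else ""))
  }
  invisible(x)
}
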