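#' Triangulated cortical surface
#'
#' A light container for one hemisphere's triangle mesh: vertex positions in
#' mm and faces as 1-based vertex index triples. All vertex-level analyses
#' (smoothing, cluster formation) derive adjacency from the faces.
#'
#' @param vertex_coords numeric matrix, n_vertices x 3, positions in mm.
#' @param faces integer matrix, n_faces x 3, 1-based vertex indices.
#' @param hemisphere `"left"`, `"right"`, or `"both"` for a combined mesh
#'   whose two hemispheres are disjoint components.
#' @param vertex_hemi for `hemisphere = "both"`: character vector giving
#'   `"left"`/`"right"` per vertex. Ignored otherwise.
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(vertex_coords, faces,
                          hemisphere = c("left", "right", "both"),
                          vertex_hemi = NULL) {
  hemisphere <- match.arg(hemisphere)
  vertex_coords <- as.matrix(vertex_coords)
  storage.mode(vertex_coords) <- "double"
  dimnames(vertex_coords) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertex_coords) != 3L) stop("vertex_coords must be n x 3")
  if (ncol(faces) != 3L) stop("faces must be n x 3")
  nv <- nrow(vertex_coords)
  if (any(faces < 1L) || any(faces > nv)) {
    stop("face vertex index out of range [1, ", nv, "]")
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  if (any(degen)) stop(sum(degen), " degenerate face(s) with repeated vertices")
  if (hemisphere == "both") {
    if (is.null(vertex_hemi) || length(vertex_hemi) != nv ||
        !all(vertex_hemi %in% c("left", "right"))) {
      stop("hemisphere = 'both' requires per-vertex vertex_hemi of 'left'/'right'")
    }
  } else {
    vertex_hemi <- rep(hemisphere, nv)
  }
  structure(
    list(vertex_coords = vertex_coords, faces = faces,
         hemisphere = hemisphere, vertex_hemi = vertex_hemi),
    class = "surface_model"
  )
}

#' Number of vertices of a surface
#' @param surface a `surface_model`.
#' @return Integer vertex count.
#' @export
n_vertices <- function(surface) nrow(surface$vertex_coords)

#' Undirected edge list of a surface mesh
#'
#' @param surface a `surface_model`.
#' @return Two-column integer matrix of unique 1-ring edges (i < j).
#' @export
surface_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Vertex adjacency list of a surface mesh
#'
#' @param surface a `surface_model`.
#' @return List of integer vectors; element v holds the 1-ring neighbors of v.
#' @export
surface_adjacency <- function(surface) {
  e <- surface_edges(surface)
  nv <- n_vertices(surface)
  adj <- split(
    c(e[, 2], e[, 1]),
    factor(c(e[, 1], e[, 2]), levels = seq_len(nv))
  )
  lapply(adj, function(x) sort(unique(x)))
}

#' Mean edge length of a surface mesh (mm)
#' @param surface a `surface_model`.
#' @return Mean Euclidean length over unique edges.
#' @export
mean_edge_length <- function(surface) {
  e <- surface_edges(surface)
  d <- surface$vertex_coords[e[, 1], , drop = FALSE] -
    surface$vertex_coords[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Per-vertex Voronoi areas (mm^2)
#'
#' Each triangle contributes one third of its area to each of its vertices;
#' the per-vertex sums tile the mesh, so cluster areas add up to total
#' surface area.
#'
#' @param surface a `surface_model`.
#' @return Numeric vector of per-vertex areas.
#' @export
vertex_areas <- function(surface) {
  v <- surface$vertex_coords
  f <- surface$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  out <- numeric(nrow(v))
  for (k in 1:3) {
    s <- tapply(tri_area / 3, factor(f[, k], levels = seq_len(nrow(v))), sum)
    s[is.na(s)] <- 0
    out <- out + as.numeric(s)
  }
  out
}

#' Parcellation scheme over surface vertices
#'
#' Label 0 marks unassigned vertices (medial-wall convention); named parcels
#' carry dense identifiers 1..n_parcels.
#'
#' @param labels integer vector, one label per vertex (0 = unassigned).
#' @param parcel_names character vector of length `max(labels)`; names for
#'   identifiers 1..n. Defaults to `parcel_1`, `parcel_2`, ...
#' @return An object of class `parcel_scheme`.
#' @export
parcel_scheme <- function(labels, parcel_names = NULL) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L)) {
    stop("labels must be non-negative integers (0 = unassigned)")
  }
  n <- max(labels, 0L)
  if (is.null(parcel_names)) parcel_names <- paste0("parcel_", seq_len(n))
  if (length(parcel_names) != n) {
    stop("parcel_names must have one entry per parcel identifier 1..", n)
  }
  present <- tabulate(labels[labels > 0L], nbins = n)
  if (n > 0L && any(present == 0L)) {
    stop(
      "empty parcel(s): ",
      paste(parcel_names[present == 0L], collapse = ", ")
    )
  }
  structure(
    list(labels = labels, parcel_names = as.character(parcel_names),
         n_parcels = n),
    class = "parcel_scheme"
  )
}

#' Per-vertex scalar map
#'
#' @param values numeric vector, one value per vertex; `NA` marks unassigned
#'   vertices (missing values propagate through downstream averaging with a
#'   warning rather than erroring).
#' @param quantity one of `"thickness_mm"`, `"gyrification"`, `"other"`.
#' @param surface owning `surface_model` (optional but required by
#'   surface-aware operations such as smoothing).
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, quantity = c("other", "thickness_mm", "gyrification"),
                       surface = NULL) {
  quantity <- match.arg(quantity)
  values <- as.numeric(values)
  if (!is.null(surface)) {
    stopifnot(inherits(surface, "surface_model"))
    if (length(values) != n_vertices(surface)) {
      stop("scalar map length ", length(values), " != vertex count ",
           n_vertices(surface))
    }
  }
  if (quantity == "thickness_mm" && any(values < 0, na.rm = TRUE)) {
    stop("thickness values must be >= 0 where assigned")
  }
  structure(
    list(values = values, quantity = quantity, surface = surface),
    class = "scalar_map"
  )
}

#' Concatenated-run BOLD timeseries over surface vertices
#'
#' @param data numeric matrix, vertices x timepoints.
#' @param tr_seconds repetition time in seconds.
#' @param run_boundaries 1-based indices of the first timepoint of runs 2..R
#'   (empty for a single run); strictly increasing and < n_timepoints.
#' @return An object of class `timeseries_bundle`.
#' @export
timeseries_bundle <- function(data, tr_seconds = 1.0, run_boundaries = integer()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("timeseries may not contain missing values")
  if (ncol(data) < 2L) stop("need at least 2 timepoints")
  run_boundaries <- as.integer(run_boundaries)
  if (length(run_boundaries)) {
    if (is.unsorted(run_boundaries, strictly = TRUE) ||
        any(run_boundaries <= 1L) || any(run_boundaries > ncol(data))) {
      stop("run_boundaries must be strictly increasing indices in (1, n_timepoints]")
    }
  }
  structure(
    list(data = data, tr_seconds = tr_seconds, run_boundaries = run_boundaries),
    class = "timeseries_bundle"
  )
}

#' Volumetric scalar grid with affine
#'
#' Voxel indices are 0-based in the affine convention: world mm coordinate of
#' voxel (i,j,k) is `affine %*% c(i,j,k,1)`, matching NIfTI. R array access
#' remains 1-based; converters handle the offset.
#'
#' @param array 3D numeric array.
#' @param affine 4x4 voxel-index (0-based) to mm transform.
#' @param mask 3D logical array of in-brain voxels; defaults to all `TRUE`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(array, affine = diag(4), mask = NULL) {
  if (length(dim(array)) != 3L) stop("array must be 3D")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(array))
  if (!identical(dim(mask), dim(array))) stop("mask shape must equal array shape")
  structure(
    list(array = array, affine = affine, mask = mask),
    class = "volume_grid"
  )
}

#' Voxel size of a volume grid (mm per axis)
#' @param vol a `volume_grid`.
#' @return Length-3 numeric of per-axis voxel edge lengths.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Convert 0-based voxel indices to world mm coordinates
#' @param ijk numeric matrix (n x 3) or length-3 vector of 0-based indices.
#' @param affine 4x4 affine.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, affine) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  h <- cbind(ijk, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' Full per-subject, per-pipeline output bundle
#'
#' @param subject_id character scalar.
#' @param pipeline_id `"A"` or `"B"`.
#' @param surface `surface_model`.
#' @param scheme `parcel_scheme` over the surface's vertices.
#' @param thickness,gyrification `scalar_map`s over the same vertices.
#' @param parcel_volumes data.frame with columns `parcel`, `volume_mm3`
#'   (cortical parcels plus subcortical structures).
#' @param timeseries `timeseries_bundle` over the same vertices.
#' @param seed_volumes optional named list of `volume_grid` FC maps per ROI.
#' @return An object of class `pipeline_bundle`.
#' @export
pipeline_bundle <- function(subject_id, pipeline_id, surface, scheme,
                            thickness, gyrification, parcel_volumes,
                            timeseries, seed_volumes = NULL) {
  stopifnot(inherits(surface, "surface_model"),
            inherits(scheme, "parcel_scheme"),
            inherits(thickness, "scalar_map"),
            inherits(gyrification, "scalar_map"),
            inherits(timeseries, "timeseries_bundle"))
  pipeline_id <- match.arg(pipeline_id, c("A", "B"))
  nv <- n_vertices(surface)
  comp <- c(
    labels = length(scheme$labels),
    thickness = length(thickness$values),
    gyrification = length(gyrification$values),
    timeseries = nrow(timeseries$data)
  )
  if (any(comp != nv)) {
    bad <- names(comp)[comp != nv]
    stop("vertex-count mismatch for: ", paste(bad, collapse = ", "),
         " (surface has ", nv, ")")
  }
  stopifnot(is.data.frame(parcel_volumes),
            all(c("parcel", "volume_mm3") %in% names(parcel_volumes)))
  rownames(parcel_volumes) <- NULL
  structure(
    list(subject_id = as.character(subject_id), pipeline_id = pipeline_id,
         surface = surface, scheme = scheme, thickness = thickness,
         gyrification = gyrification, parcel_volumes = parcel_volumes,
         timeseries = timeseries, seed_volumes = seed_volumes),
    class = "pipeline_bundle"
  )
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle> subject", x$subject_id, "pipeline", x$pipeline_id,
      "\n  ", n_vertices(x$surface), "vertices,", x$scheme$n_parcels,
      "parcels,", ncol(x$timeseries$data), "timepoints\n")
  invisible(x)
}

#' @export
print.surface_model <- function(x, ...) {
  cat("<surface_model>", x$hemisphere, "hemisphere:", n_vertices(x),
      "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}
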