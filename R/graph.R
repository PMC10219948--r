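#' Build a binarized FC graph from a connectivity matrix
#'
#' Correlations are Fisher-transformed and the matrix is thresholded at
#' r = 0.3 and binarized: an edge exists iff the raw correlation strictly
#' exceeds the threshold (the threshold is applied on the r scale;
#' `scale = "z"` applies it to the Fisher-z values instead). Retained
#' Fisher-z values are stored as edge weights for the strength metric.
#'
#' @param conn a `connectivity_matrix`.
#' @param r_threshold edge threshold (strict `>`).
#' @param scale `"r"` (default) or `"z"`: which scale the threshold is
#'   compared on.
#' @return An object of class `adjacency_graph`: list with `adjacency`
#'   (binary symmetric matrix, zero diagonal) and `weights` (thresholded
#'   Fisher-z matrix, zero where no edge).
#' @export
build_graph <- function(conn, r_threshold = 0.3, scale = c("r", "z")) {
  scale <- match.arg(scale)
  r <- unclass(conn)
  z <- suppressWarnings(fisher_z(r))
  cmp <- if (scale == "r") r else z
  adj <- !is.na(cmp) & cmp > r_threshold
  adj <- adj | t(adj)  # NA-asymmetry guard; conn is symmetric anyway
  diag(adj) <- FALSE
  w <- ifelse(adj, z, 0)
  diag(w) <- 0
  structure(
    list(adjacency = adj * 1, weights = w, r_threshold = r_threshold,
         scale = scale),
    class = "adjacency_graph"
  )
}

#' Six per-node graph metrics
#'
#' Computes, on the binarized graph: betweenness centrality (shortest-path
#' pair dependencies, normalized by (n-1)(n-2)/2), closeness centrality in
#' the component-scaled convention
#' `((reachable-1)/dist_sum) * ((reachable-1)/(n-1))` (finite on
#' disconnected graphs), local clustering coefficient (triangles over
#' connected triples, 0 where degree < 2), degree centrality (degree /
#' (n-1)), eigenvector centrality (dominant adjacency eigenvector by power
#' iteration, unit Euclidean norm, nonnegative orientation), and normalized
#' strength (sum of retained Fisher-z edge weights / (n-1); set
#' `strength_weights = "binary"` for a degree-based fallback).
#'
#' Shortest-path and triangle machinery is delegated to igraph; the
#' conventions above are applied on top.
#'
#' @param g an `adjacency_graph`.
#' @param strength_weights `"fisher_z"` (default) or `"binary"`.
#' @param tol power-iteration convergence tolerance.
#' @return data.frame with columns `node`, `betweenness`, `closeness`,
#'   `clustering`, `degree`, `eigenvector`, `normalized_strength`, plus an
#'   `empty_graph` attribute flag.
#' @export
graph_metrics <- function(g, strength_weights = c("fisher_z", "binary"),
                          tol = 1e-10) {
  strength_weights <- match.arg(strength_weights)
  A <- g$adjacency
  n <- nrow(A)
  if (n < 2L) stop("need >= 2 nodes")
  nodes <- colnames(A)
  if (is.null(nodes)) nodes <- paste0("node_", seq_len(n))
  deg <- colSums(A)
  empty <- all(deg == 0)
  out <- data.frame(node = nodes,
                    betweenness = 0, closeness = 0, clustering = 0,
                    degree = deg / (n - 1), eigenvector = 0,
                    normalized_strength = 0, stringsAsFactors = FALSE)
  if (!empty) {
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    bw <- igraph::betweenness(ig, directed = FALSE)
    out$betweenness <- if (n > 2) bw / ((n - 1) * (n - 2) / 2) else bw * 0
    dmat <- igraph::distances(ig)
    out$closeness <- apply(dmat, 1, function(dr) {
      finite <- is.finite(dr)
      reach <- sum(finite) - 1L  # excluding self
      if (reach == 0L) return(0)
      s <- sum(dr[finite])
      (reach / s) * (reach / (n - 1))
    })
    cl <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    cl[deg < 2] <- 0
    out$clustering <- cl
    out$eigenvector <- power_iteration_eigenvector(A, tol = tol)
    out$normalized_strength <- if (strength_weights == "fisher_z") {
      colSums(g$weights) / (n - 1)
    } else {
      deg / (n - 1)
    }
  }
  attr(out, "empty_graph") <- empty
  out
}

# Dominant eigenvector of a nonnegative symmetric matrix by power iteration,
# unit norm, oriented nonnegative (Perron-Frobenius). Iterates on A + I so
# the dominant eigenvalue is strictly largest in magnitude even on bipartite
# graphs (spectrum is shifted, eigenvectors unchanged). Started from the
# uniform vector; if the dominant eigenvalue is degenerate (isomorphic
# disconnected components) the limit is the normalised projection of the
# uniform vector onto the dominant eigenspace.
power_iteration_eigenvector <- function(A, tol = 1e-10, max_iter = 100000L) {
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  tol <- min(tol, 1e-14)
  for (i in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(rep(0, n))
    y <- y / ny
    if (max(abs(y - x)) < tol) {
      x <- y
      break
    }
    x <- y
  }
  if (sum(x) < 0) x <- -x
  x
}

#' First-principal-component concordance of a graph metric across pipelines
#'
#' Each pipeline contributes a parcels x subjects matrix of one metric.
#' With parcels as observations and subjects as (centered) variables, the
#' PC1 scores (length = n parcels) are extracted per pipeline and the
#' concordance is the absolute Pearson correlation between the two score
#' vectors. The absolute value resolves the sign indeterminacy of principal
#' components; identical matrices give exactly 1.
#'
#' @param metric_a,metric_b numeric matrices, parcels x subjects, same shape.
#' @param use `"scores"` (default) or `"loadings"`: compare PC1 scores over
#'   parcels or PC1 variable loadings over subjects.
#' @return Concordance in \[0, 1\].
#' @export
pc1_concordance <- function(metric_a, metric_b, use = c("scores", "loadings")) {
  use <- match.arg(use)
  metric_a <- as.matrix(metric_a)
  metric_b <- as.matrix(metric_b)
  if (!identical(dim(metric_a), dim(metric_b))) {
    stop("metric matrices must share the shape")
  }
  pc1 <- function(x) {
    if (all(apply(x, 2, stats::sd) == 0)) stop("rank-0 metric matrix")
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    if (use == "scores") p$x[, 1] else p$rotation[, 1]
  }
  abs(stats::cor(pc1(metric_a), pc1(metric_b)))
}

#' Full graph-concordance stage over a paired dataset
#'
#' For every subject and pipeline: parcel timeseries, connectivity,
#' thresholded binarized graph, six metrics. Each metric's parcels x
#' subjects matrices for pipelines A and B are compared by
#' [pc1_concordance()].
#'
#' @param bundles list of per-subject `list(A =, B =)` pipeline bundles.
#' @param r_threshold edge threshold on the r scale.
#' @return List with `concordance` (named numeric over the six metrics) and
#'   `metric_matrices` (per metric, per pipeline parcels x subjects).
#' @export
graph_concordance <- function(bundles, r_threshold = 0.3) {
  bundles <- complete_pairs(bundles)
  metric_names <- c("betweenness", "closeness", "clustering", "degree",
                    "eigenvector", "normalized_strength")
  per_pipeline <- lapply(c(A = "A", B = "B"), function(p) {
    mats <- lapply(bundles, function(s) {
      b <- s[[p]]
      conn <- connectivity_matrix(parcel_timeseries(b$timeseries, b$scheme))
      m <- graph_metrics(build_graph(conn, r_threshold))
      mm <- as.matrix(m[, metric_names])
      rownames(mm) <- m$node
      mm
    })
    stats::setNames(lapply(metric_names, function(mn) {
      sapply(mats, function(m) m[, mn])
    }), metric_names)
  })
  conc <- vapply(metric_names, function(mn) {
    pc1_concordance(per_pipeline$A[[mn]], per_pipeline$B[[mn]])
  }, numeric(1))
  list(concordance = conc,
       metric_matrices = lapply(stats::setNames(metric_names, metric_names),
                                function(mn) {
                                  list(A = per_pipeline$A[[mn]],
                                       B = per_pipeline$B[[mn]])
                                }))
}
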