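# Brute-force graph-metric oracles for small graphs, fully independent of
# the package implementation (path enumeration, triple loops, base eigen()).

# all simple paths from s to t by DFS
enumerate_paths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(v, visited, path) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (A[v, w] > 0 && !visited[w]) {
        vis <- visited
        vis[w] <- TRUE
        walk(w, vis, c(path, w))
      }
    }
  }
  vis <- rep(FALSE, n)
  vis[s] <- TRUE
  walk(s, vis, s)
  paths
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  bw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_paths(A, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(shortest, function(p) {
        v %in% p[-c(1, length(p))]
      }, logical(1)))
      bw[v] <- bw[v] + through / sigma
    }
  }
  if (n > 2) bw / ((n - 1) * (n - 2) / 2) else bw * 0
}

oracle_distances <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  d <- oracle_distances(A)
  vapply(seq_len(n), function(v) {
    dr <- d[v, -v]
    reach <- sum(is.finite(dr))
    if (reach == 0) return(0)
    (reach / sum(dr[is.finite(dr)])) * (reach / (n - 1))
  }, numeric(1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (A[nb[i], nb[j]] > 0) tri <- tri + 1
    }
    tri / (k * (k - 1) / 2)
  }, numeric(1))
}

# projection of the uniform vector onto the dominant eigenspace of A + I,
# matching the documented uniform-start power-iteration convention
oracle_eigenvector <- function(A) {
  n <- nrow(A)
  if (all(A == 0)) return(rep(0, n))  # edgeless graphs carry no centrality
  e <- eigen(A + diag(n), symmetric = TRUE)
  lmax <- e$values[1]
  basis <- e$vectors[, abs(e$values - lmax) < 1e-9, drop = FALSE]
  u <- rep(1 / sqrt(n), n)
  proj <- basis %*% (t(basis) %*% u)
  proj <- proj / sqrt(sum(proj^2))
  if (sum(proj) < 0) proj <- -proj
  as.numeric(proj)
}

oracle_strength <- function(W) {
  colSums(W) / (nrow(W) - 1)
}

# random undirected graph on n nodes with edge probability p, plus random
# correlation-like weights above the threshold for retained edges
random_small_graph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- stats::rbinom(sum(up), 1, p)
  A <- A + t(A)
  r <- matrix(0, n, n)
  r[up] <- stats::runif(sum(up), 0.31, 0.95)
  r <- r + t(r)
  r[A == 0] <- stats::runif(sum(A == 0), -0.29, 0.29)
  diag(r) <- NA
  r <- (r + t(r)) / 2
  diag(r) <- NA
  class(r) <- c("connectivity_matrix", class(r))
  r
}
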