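#' Surface smoothing by iterated graph diffusion
#'
#' Approximates a Gaussian kernel of the given full-width-half-maximum by
#' repeated 1-ring diffusion on the mesh: `x <- x + alpha (A x - D x)` with
#' `alpha = 1/(max_degree + 1)`, the symmetric form of neighbour averaging.
#' Because the update operator is symmetric with zero row sums, the vertex
#' sum (hence the global mean on a closed mesh) is preserved exactly and a
#' constant map is a fixed point. The iteration count is calibrated from the
#' per-step diffusion variance:
#' `n_iter = round((fwhm / 2.355)^2 / (mean_edge_length^2 / 2))`.
#'
#' Missing (`NA`) vertices are handled by diffusing the value-times-mask and
#' the mask separately and renormalising, so assigned values never bleed a
#' missing marker; missing vertices stay missing.
#'
#' @param map a `scalar_map` with a `surface` reference.
#' @param fwhm_mm smoothing kernel FWHM in mm (>= 0; 0 is the identity).
#' @return A smoothed `scalar_map` over the same surface.
#' @export
smooth_surface <- function(map, fwhm_mm) {
  stopifnot(inherits(map, "scalar_map"))
  if (is.null(map$surface)) stop("scalar_map must carry its surface for smoothing")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  n_it <- smoothing_iterations(map$surface, fwhm_mm)
  if (n_it == 0L) return(map)
  S <- diffusion_operator(map$surface)
  x <- map$values
  miss <- is.na(x)
  if (any(miss)) {
    m <- as.numeric(!miss)
    xv <- ifelse(miss, 0, x)
    for (i in seq_len(n_it)) {
      xv <- as.numeric(S %*% xv)
      m <- as.numeric(S %*% m)
    }
    out <- ifelse(miss, NA_real_, xv / m)
  } else {
    for (i in seq_len(n_it)) x <- as.numeric(S %*% x)
    out <- x
  }
  scalar_map(out, quantity = map$quantity, surface = map$surface)
}

#' Iteration count used by [smooth_surface()] for a given FWHM
#' @param surface a `surface_model`.
#' @param fwhm_mm kernel FWHM in mm.
#' @return Integer number of diffusion iterations.
#' @export
smoothing_iterations <- function(surface, fwhm_mm) {
  if (fwhm_mm == 0) return(0L)
  sigma <- fwhm_mm / 2.355
  h <- mean_edge_length(surface)
  as.integer(round(sigma^2 / (h^2 / 2)))
}

# one diffusion step as a sparse operator: I + alpha (A - D)
diffusion_operator <- function(surface) {
  e <- surface_edges(surface)
  nv <- n_vertices(surface)
  A <- Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]), x = 1, dims = c(nv, nv)
  )
  deg <- Matrix::rowSums(A)
  alpha <- 1 / (max(deg) + 1)
  Matrix::Diagonal(nv, 1 - alpha * deg) + alpha * A
}

#' Masked Gaussian volume smoothing
#'
#' Separable Gaussian convolution (truncated at 4 sigma) with mask-boundary
#' renormalisation: the value-times-mask and the mask are convolved
#' separately and their ratio is taken inside the mask, so a constant map
#' stays exactly constant and no signal bleeds from outside the mask.
#' Voxels outside the mask are set to 0. Only isotropic grids are supported.
#'
#' @param vol a `volume_grid`.
#' @param sigma_mm Gaussian sigma in mm (>= 0; 0 is the identity).
#' @return A smoothed `volume_grid` on the same grid.
#' @export
smooth_volume <- function(vol, sigma_mm) {
  stopifnot(inherits(vol, "volume_grid"))
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  vs <- voxel_size(vol)
  if (max(vs) - min(vs) > 1e-6 * mean(vs)) {
    stop("anisotropic voxels are not supported (voxel sizes ",
         paste(signif(vs, 4), collapse = " x "), " mm)")
  }
  if (sigma_mm == 0) return(vol)
  sig_vox <- sigma_mm / vs[1]
  r <- max(1L, ceiling(4 * sig_vox))
  w <- stats::dnorm(-r:r, sd = sig_vox)
  w <- w / sum(w)
  m <- array(as.numeric(vol$mask), dim = dim(vol$array))
  x <- ifelse(vol$mask, vol$array, 0)
  xs <- conv3d_separable(x, w)
  ms <- conv3d_separable(m, w)
  out <- array(0, dim = dim(vol$array))
  inside <- vol$mask & ms > 0
  out[inside] <- xs[inside] / ms[inside]
  volume_grid(out, affine = vol$affine, mask = vol$mask)
}

# zero-padded separable convolution of a 3D array with 1D kernel w
conv3d_separable <- function(x, w) {
  d <- dim(x)
  for (ax in 1:3) {
    K <- band_kernel_matrix(d[ax], w)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- K %*% matrix(xp, nrow = dp[1])
    xp <- array(m, dim = dp)
    x <- aperm(xp, order(perm))
  }
  x
}

band_kernel_matrix <- function(n, w) {
  r <- (length(w) - 1L) / 2L
  i <- rep(seq_len(n), each = length(w))
  j <- i + rep(-r:r, times = n)
  x <- rep(w, times = n)
  keep <- j >= 1 & j <= n
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep], dims = c(n, n))
}
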