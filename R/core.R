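#' Parcel-averaged timeseries
#'
#' Averages vertex BOLD series within each named parcel: row p of the result
#' is the unweighted mean over all vertices labelled p, per timepoint.
#' Unassigned vertices (label 0) are excluded.
#'
#' @param ts a `timeseries_bundle`.
#' @param scheme a `parcel_scheme` sharing the vertex count.
#' @return Numeric matrix, n_parcels x n_timepoints, rows ordered and named
#'   by parcel identifier.
#' @export
parcel_timeseries <- function(ts, scheme) {
  stopifnot(inherits(ts, "timeseries_bundle"), inherits(scheme, "parcel_scheme"))
  if (nrow(ts$data) != length(scheme$labels)) {
    stop("vertex-count mismatch: timeseries has ", nrow(ts$data),
         ", scheme has ", length(scheme$labels))
  }
  n <- scheme$n_parcels
  counts <- tabulate(scheme$labels[scheme$labels > 0L], nbins = n)
  if (any(counts == 0L)) {
    stop("empty parcel(s): ",
         paste(scheme$parcel_names[counts == 0L], collapse = ", "))
  }
  keep <- scheme$labels > 0L
  # group-sum via sparse indicator, then divide by member counts
  ind <- Matrix::sparseMatrix(
    i = scheme$labels[keep], j = which(keep), x = 1,
    dims = c(n, length(scheme$labels))
  )
  out <- as.matrix(ind %*% ts$data) / counts
  rownames(out) <- scheme$parcel_names
  out
}

#' Parcel-wise Pearson connectivity matrix
#'
#' Pairwise Pearson correlations between parcel timeseries; the diagonal
#' (self-correlation, identically 1) is removed, i.e. set to `NA`. A parcel
#' with a constant series cannot be correlated: its row and column are set
#' to `NA` with a warning rather than propagating silently.
#'
#' @param parcel_ts numeric matrix, parcels x timepoints (rows as from
#'   [parcel_timeseries()]).
#' @return An object of class `connectivity_matrix`: a symmetric parcels x
#'   parcels matrix with `NA` diagonal.
#' @export
connectivity_matrix <- function(parcel_ts) {
  parcel_ts <- as.matrix(parcel_ts)
  if (ncol(parcel_ts) < 3L) stop("need >= 3 timepoints")
  sds <- apply(parcel_ts, 1, stats::sd)
  const <- sds == 0 | is.na(sds)
  r <- matrix(NA_real_, nrow(parcel_ts), nrow(parcel_ts))
  if (any(!const)) {
    r[!const, !const] <- stats::cor(t(parcel_ts[!const, , drop = FALSE]))
  }
  if (any(const)) {
    nm <- rownames(parcel_ts)[const]
    if (is.null(nm)) nm <- which(const)
    warning("constant timeseries for parcel(s) ", paste(nm, collapse = ", "),
            "; correlations set to missing")
  }
  # numerical guard: cor() can exceed 1 by ~1e-16
  r[] <- pmin(pmax(r, -1), 1)
  r <- (r + t(r)) / 2
  diag(r) <- NA_real_
  dimnames(r) <- list(rownames(parcel_ts), rownames(parcel_ts))
  class(r) <- c("connectivity_matrix", class(r))
  r
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilising transform for Pearson
#' correlations. Odd and strictly increasing on (-1, 1); `|r| = 1` maps to
#' signed infinity; `|r| > 1` is an error. `NA` propagates.
#'
#' @param r numeric vector of correlations.
#' @return Numeric vector of z-values.
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) stop("|r| > 1 in fisher_z: ", paste(r[bad], collapse = ", "))
  atanh(r)
}

#' Paired two-sided t-test
#'
#' Thin wrapper around [stats::t.test()] with explicit degenerate handling:
#' identical samples give t = 0, p = 1; a nonzero but zero-variance
#' difference (every subject shifted equally) is flagged degenerate and no
#' t is emitted.
#'
#' @param a,b numeric vectors of per-subject values, equal length >= 2.
#' @return List with `t`, `p`, `mean_diff` (mean of b - a), `df`,
#'   `degenerate` (logical).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("need >= 2 subjects")
  d <- b - a
  md <- mean(d)
  if (stats::sd(d) == 0) {
    if (md == 0) {
      return(list(t = 0, p = 1, mean_diff = 0, df = length(d) - 1L,
                  degenerate = FALSE))
    }
    return(list(t = NA_real_, p = NA_real_, mean_diff = md,
                df = length(d) - 1L, degenerate = TRUE))
  }
  ht <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, mean_diff = md,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Bonferroni-corrected alpha threshold
#'
#' @param alpha family-wise alpha in (0, 1).
#' @param n_tests number of tests (>= 1), e.g. 34 cortical parcels per
#'   hemisphere or 7 subcortical structures.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(n_tests) != 1L || n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Assemble a per-parcel comparison report
#'
#' Shared result table for parcel-level paired tests (structural or FC
#' strength): one row per parcel with t, uncorrected p, the corrected alpha
#' threshold it was compared to, the significance decision, and the sign of
#' the mean B - A difference.
#'
#' @param parcel character vector of parcel names.
#' @param tests list of [paired_t()] results, one per parcel.
#' @param p_threshold corrected alpha each p is compared to.
#' @param correction label, e.g. `"bonferroni(34)"`.
#' @return data.frame of class `comparison_report`.
#' @keywords internal
comparison_report <- function(parcel, tests, p_threshold, correction) {
  df <- data.frame(
    parcel = parcel,
    t_statistic = vapply(tests, function(x) x$t, numeric(1)),
    p_uncorrected = vapply(tests, function(x) x$p, numeric(1)),
    mean_diff = vapply(tests, function(x) x$mean_diff, numeric(1)),
    degenerate = vapply(tests, function(x) x$degenerate, logical(1)),
    stringsAsFactors = FALSE
  )
  df$p_threshold_corrected <- p_threshold
  df$significant <- !is.na(df$p_uncorrected) & df$p_uncorrected < p_threshold
  df$direction <- ifelse(df$mean_diff > 0, "B>A",
                         ifelse(df$mean_diff < 0, "A>B", "equal"))
  attr(df, "correction") <- correction
  class(df) <- c("comparison_report", class(df))
  df
}
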