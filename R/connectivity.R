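#' Pearson correlation matrix of ROI time series
#'
#' Computes the region-by-region functional connectivity matrix: the Pearson
#' correlation of the averaged time series of every pair of regions, with
#' the diagonal fixed at 1.
#'
#' @param ts A T x R numeric matrix (rows = timepoints, columns = regions);
#'   T >= 3 and no constant column.
#' @return An R x R symmetric correlation matrix with unit diagonal,
#'   dimnames taken from the column names of `ts`.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  v <- apply(ts, 2, var)
  if (any(v == 0 | is.na(v))) {
    bad <- colnames(ts)[v == 0 | is.na(v)]
    if (is.null(bad)) bad <- which(v == 0 | is.na(v))
    stop("zero-variance time series for region(s): ",
         paste(bad, collapse = ", "))
  }
  fc <- cor(ts)
  diag(fc) <- 1
  fc
}

#' Fisher r-to-z transformation
#'
#' The variance-stabilizing transform z = arctanh(r) = 0.5 * log((1+r)/(1-r))
#' applied to correlation coefficients to improve their normality.
#'
#' @param r Correlations with |r| < 1 (vectorised).
#' @return Transformed values.
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1; exclude the diagonal / perfectly ",
         "collinear pairs")
  atanh(r)
}

#' Vectorize an FC matrix into a canonical Fisher-z edge vector
#'
#' Extracts the upper triangle of a correlation matrix in canonical
#' row-major edge order (see [edge_index()]) and applies [fisher_z()].
#'
#' @param fc Symmetric correlation matrix with unit diagonal.
#' @param clip If TRUE, correlations with |r| >= 1 - 1e-12 are clipped to
#'   +/-(1 - 1e-12) before the transform. Intended for synthetic data where
#'   exact collinearity can be constructed; leave FALSE on real data so
#'   genuine degeneracies surface as errors.
#' @return Numeric vector of length n(n-1)/2 in canonical edge order.
#' @export
vectorize_fc <- function(fc, clip = FALSE) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  stopifnot(n == ncol(fc))
  r <- t(fc)[lower.tri(fc)]  # row-major upper triangle
  if (clip) {
    lim <- 1 - 1e-12
    r <- pmin(pmax(r, -lim), lim)
  }
  fisher_z(r)
}

#' Rebuild a correlation matrix from a canonical edge vector
#'
#' Plumbing inverse of [vectorize_fc()]: maps Fisher-z edge values back to
#' correlations (tanh) and fills a symmetric matrix with unit diagonal.
#'
#' @param z Edge vector of length n(n-1)/2.
#' @param n Number of regions.
#' @return An n x n symmetric correlation matrix.
#' @export
unvectorize_edges <- function(z, n) {
  stopifnot(length(z) == n_edges(n))
  fc <- diag(n)
  p <- pair_of_edge(seq_along(z), n)
  fc[p] <- tanh(z)
  fc[p[, c(2, 1), drop = FALSE]] <- tanh(z)
  fc
}

#' Subjects-by-edges Fisher-z feature matrix for a cohort
#'
#' @param ts_list Named list of per-subject T x R time-series matrices.
#' @param clip Passed to [vectorize_fc()]; defaults to TRUE for the
#'   synthetic path.
#' @return A subjects x edges numeric matrix, rownames = subject ids.
#' @export
cohort_edge_matrix <- function(ts_list, clip = TRUE) {
  mats <- lapply(ts_list, function(x) vectorize_fc(compute_fc(x), clip = clip))
  do.call(rbind, mats)
}

#' Write / read an FC matrix as labelled TSV
#'
#' @param fc Correlation matrix with region labels as dimnames.
#' @param path File path.
#' @return `write_fc_matrix` returns the path invisibly; `read_fc_matrix`
#'   the matrix.
#' @export
write_fc_matrix <- function(fc, path) {
  write.table(cbind(label = rownames(fc), as.data.frame(fc)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d$label
  m
}
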