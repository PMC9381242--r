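#' Pearson correlation matrix of ROI time series
#'
#' Computes the region-by-region functional connectivity matrix of one
#' subject: the Pearson correlation coefficient between the BOLD time series
#' of every pair of regions of interest (ROIs). The result is symmetric with
#' unit diagonal.
#'
#' @param ts Numeric matrix, ROIs in rows and timepoints in columns.
#' @return A symmetric \code{n_rois x n_rois} correlation matrix with 1 on
#'   the diagonal.
#' @examples
#' ts <- matrix(rnorm(5 * 40), nrow = 5)
#' p <- correlation_matrix(ts)
#' all(diag(p) == 1)
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts) || anyNA(ts))
    stop("time-series matrix must be numeric with no missing values")
  if (ncol(ts) < 2L) stop("need at least 2 timepoints")
  v <- apply(ts, 1L, stats::var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    stop(sprintf("ROI row(s) with zero variance: %s",
                 paste(bad, collapse = ", ")))
  }
  p <- stats::cor(t(ts))
  p <- (p + t(p)) / 2          # enforce exact symmetry
  diag(p) <- 1
  p
}

#' Fisher-Z transform of a correlation matrix
#'
#' Applies z = (1/2) * (log(1 + p) - log(1 - p)) to every off-diagonal
#' entry, the variance-stabilising transform that brings correlation
#' coefficients close to normality. The diagonal is stored as 1, mirroring
#' the conventional presentation of the Z-matrix; no downstream computation
#' uses it.
#'
#' Off-diagonal entries with |p| = 1 (possible in synthetic data with
#' duplicated series) are clipped to +/-(1 - 1e-7) with a warning when
#' \code{clip = TRUE}; with clipping disabled they raise an error.
#'
#' @param p Symmetric correlation matrix.
#' @param clip Clip perfect correlations before transforming?
#' @return Matrix of Fisher-Z values, diagonal 1.
#' @export
fisher_z <- function(p, clip = TRUE) {
  p <- as.matrix(p)
  off <- row(p) != col(p)
  bad <- abs(p[off]) >= 1
  if (any(bad)) {
    if (!clip)
      stop("off-diagonal |correlation| >= 1; Fisher-Z undefined")
    warning(sprintf("clipping %d off-diagonal |p| >= 1 to 1 - 1e-7",
                    sum(bad)))
    p[off] <- pmin(pmax(p[off], -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- 0.5 * (log1p(p) - log1p(-p))
  diag(z) <- 1
  z
}

#' Inverse Fisher-Z transform
#'
#' @param z Fisher-Z value(s).
#' @return Correlation value(s), tanh(z).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Binarize a connectivity matrix at a sparsity threshold
#'
#' Retains the \code{round(s * n * (n - 1) / 2)} strongest edges of a
#' weighted connectivity matrix and sets all others to zero, where the
#' sparsity \code{s} is the proportion of possible edges kept. Ranking is by
#' the signed weight (most positive first) by default, the dominant
#' convention for binarised functional connectomes; \code{ranking =
#' "absolute"} ranks by magnitude instead. Ties are broken by lexicographic
#' (row, column) order so the result is deterministic, and the edge set at a
#' lower sparsity is always a subset of the edge set at a higher one.
#'
#' @param z Symmetric weight matrix (typically Fisher-Z values); the
#'   diagonal is ignored.
#' @param sparsity Proportion of edges to retain, in (0, 1].
#' @param ranking "signed" (default) or "absolute".
#' @return A symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
binarize_at_sparsity <- function(z, sparsity,
                                 ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  z <- as.matrix(z)
  n <- nrow(z)
  if (n != ncol(z)) stop("weight matrix must be square")
  assert_number(sparsity, "sparsity", lower = 0, strict_lower = TRUE,
                upper = 1)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[upper.tri(z)]
  if (ranking == "absolute") w <- abs(w)
  m <- round(sparsity * n * (n - 1) / 2)
  ord <- order(-w, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(m)]
  adj <- matrix(0, n, n)
  adj[cbind(ut[keep, 1L], ut[keep, 2L])] <- 1
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(z)
  adj
}

#' The standard sparsity-threshold grid
#'
#' 31 thresholds from 0.10 to 0.40 in steps of 0.01, realised by integer
#' stepping to avoid floating-point drift.
#'
#' @param from,to,by Grid limits and step (defaults 0.10, 0.40, 0.01).
#' @return Numeric vector of sparsity values.
#' @export
sparsity_grid <- function(from = 0.10, to = 0.40, by = 0.01) {
  seq.int(round(from * 100), round(to * 100), by = round(by * 100)) / 100
}

#' Read a subject time-series matrix from delimited text
#'
#' Header-free numeric text, ROIs as rows, timepoints as columns; any of
#' whitespace, tab or comma delimiters are accepted.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_timeseries <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  as.matrix(utils::read.table(path, header = FALSE, sep = sep))
}

#' Write a binary graph as an edge-list text file
#'
#' One edge per line, two 1-based node indices separated by a tab, each
#' undirected edge written once (i < j).
#'
#' @param adj 0/1 adjacency matrix.
#' @param path Output file path.
#' @export
write_edge_list <- function(adj, path) {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  utils::write.table(idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE],
                     path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
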