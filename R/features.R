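# PCA-based weighting and selection over the seven AUC features. The
# canonical feature order (columns of the A-matrix) is gamma, lambda,
# sigma, Cp, Lp, Eglobal, Elocal.

#' Canonical AUC feature order
#' @export
feature_order <- c("auc_gamma", "auc_lambda", "auc_sigma", "auc_cp",
                   "auc_lp", "auc_eglobal", "auc_elocal")

#' Column-standardize a feature matrix
#'
#' Centers each column and scales by the sample (n - 1) standard deviation,
#' so every column of the result has mean 0 and unit sample SD.
#'
#' @param A Numeric matrix or data.frame of features (subjects x features).
#' @return Standardized numeric matrix.
#' @export
standardize_features <- function(A) {
  A <- as.matrix(A)
  sds <- apply(A, 2L, stats::sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    bad <- colnames(A)[sds <= 0 | !is.finite(sds)] %||%
      which(sds <= 0 | !is.finite(sds))
    stop(sprintf("constant feature column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  B <- scale(A, center = TRUE, scale = sds)
  attr(B, "scaled:center") <- NULL
  attr(B, "scaled:scale") <- NULL
  B
}

#' Covariance matrix of standardized features
#'
#' Sample covariance with the (n - 1) denominator; on standardized input
#' this equals the feature correlation matrix, with unit diagonal.
#'
#' @param B Standardized feature matrix.
#' @return Symmetric covariance matrix.
#' @export
feature_covariance <- function(B) {
  R <- stats::cov(as.matrix(B))
  (R + t(R)) / 2
}

# One-to-one attribution of eigenvalues to original features: walk the
# eigenvectors in order of descending eigenvalue and assign each to the
# not-yet-assigned feature carrying its largest absolute loading (ties by
# lowest feature index). The literal order-pairing (eigenvalue j <-> feature
# j) is available as attribution = "order".
attribute_eigenvalues <- function(eig, attribution = c("loading", "order")) {
  attribution <- match.arg(attribution)
  m <- length(eig$values)
  assign <- integer(m)
  if (attribution == "order") {
    assign <- seq_len(m)
  } else {
    free <- rep(TRUE, m)
    for (j in seq_len(m)) {
      load <- abs(eig$vectors[, j])
      load[!free] <- -Inf
      i <- which.max(load)
      assign[j] <- i
      free[i] <- FALSE
    }
  }
  assign    # assign[j] = feature index owning eigenvalue j
}

#' Feature weights from the covariance spectrum
#'
#' Computes the eigenvalues of the feature covariance matrix and expresses
#' each as a share of the total variance, w = lambda / sum(lambda). Each
#' eigenvalue is attributed to one original feature: by default to the
#' feature on which its eigenvector has the largest absolute loading (a
#' one-to-one greedy matching in descending eigenvalue order), since the
#' literal pairing of the j-th eigenvalue with the j-th feature is not well
#' defined; the literal pairing is available via \code{attribution =
#' "order"}.
#'
#' @param R Symmetric feature covariance matrix.
#' @param attribution "loading" (default) or "order".
#' @return Named numeric vector of weights summing to 1, in feature order.
#' @export
feature_weights <- function(R, attribution = c("loading", "order")) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) stop("covariance matrix must be symmetric")
  eig <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (any(!is.finite(eig$values))) stop("non-finite eigenvalue")
  assign <- attribute_eigenvalues(eig, attribution)
  w <- numeric(length(eig$values))
  w[assign] <- eig$values / sum(eig$values)
  names(w) <- colnames(R) %||% paste0("feature", seq_along(w))
  w
}

#' Select features by weight threshold
#'
#' Returns the indices of features whose weight exceeds the threshold
#' (default 0.6; with weights summing to 1 this admits at most one
#' feature). If no weight clears the threshold the single largest-weight
#' feature is returned with a warning.
#'
#' @param w Weight vector from \code{feature_weights}.
#' @param threshold Selection threshold (default 0.6).
#' @return Integer indices of selected features.
#' @export
select_features <- function(w, threshold = 0.6) {
  assert_number(threshold, "threshold", lower = 0)
  sel <- which(w > threshold)
  if (length(sel) == 0L) {
    warning("no feature weight exceeds the threshold; falling back to the largest")
    sel <- which.max(w)
  }
  unname(sel)
}

#' Project standardized features onto an eigenvector
#'
#' c = B v, the principal-component score. The eigenvector sign is fixed so
#' that its largest-magnitude component is positive, making the projection
#' deterministic.
#'
#' @param B Standardized feature matrix.
#' @param v Eigenvector of the feature covariance matrix.
#' @return Numeric vector of projected values (one per subject).
#' @export
project_component <- function(B, v) {
  B <- as.matrix(B)
  if (ncol(B) != length(v)) stop("dimension mismatch between B and v")
  v <- fix_sign(v)
  drop(B %*% v)
}

fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' PCA feature weighting and selection in one step
#'
#' Standardizes the AUC feature matrix, forms its covariance, computes
#' per-feature weights, selects features above the threshold and attaches
#' the principal-component projections of the selected features'
#' eigenvectors. Intended to be fitted on the patient group of the training
#' fold only.
#'
#' @param A Feature matrix (subjects x 7 AUC features) in the canonical
#'   order.
#' @param threshold Selection threshold (default 0.6).
#' @param attribution Eigenvalue-to-feature attribution rule.
#' @return Object of class \code{"pca_selection"}: list with \code{B},
#'   \code{R}, \code{eigenvalues}, \code{eigenvectors} (sign-fixed),
#'   \code{weights}, \code{selected}, \code{projected}.
#' @export
pca_feature_selection <- function(A, threshold = 0.6,
                                  attribution = c("loading", "order")) {
  attribution <- match.arg(attribution)
  B <- standardize_features(A)
  R <- feature_covariance(B)
  eig <- eigen(R, symmetric = TRUE)
  vecs <- apply(eig$vectors, 2L, fix_sign)
  assign <- attribute_eigenvalues(eig, attribution)
  w <- numeric(length(eig$values))
  w[assign] <- eig$values / sum(eig$values)
  names(w) <- colnames(R) %||% paste0("feature", seq_along(w))
  sel <- select_features(w, threshold)
  own_vec <- vecs[, order(assign), drop = FALSE]  # eigenvector owned by feature i
  proj <- sapply(sel, function(i) project_component(B, own_vec[, i]))
  if (length(sel)) proj <- matrix(proj, ncol = length(sel),
                                  dimnames = list(NULL, names(w)[sel]))
  structure(list(B = B, R = R, eigenvalues = eig$values,
                 eigenvectors = vecs, weights = w, selected = sel,
                 projected = proj, threshold = threshold,
                 attribution = attribution),
            class = "pca_selection")
}

#' @export
print.pca_selection <- function(x, ...) {
  cat("PCA feature weighting (weights in % of total variance):\n")
  print(round(100 * x$weights, 2))
  cat(sprintf("Selected (threshold %.2f): %s\n", x$threshold,
              paste(names(x$weights)[x$selected], collapse = ", ")))
  invisible(x)
}

#' Per-subject AUC feature table of a cohort
#'
#' Runs every subject of a cohort through the connectome and graph-metric
#' stages and assembles the feature table: one row per subject with the
#' requested AUC features in canonical order, plus subject_id, group and
#' score columns. Feature extraction uses no labels, so it may be computed
#' once before cross-validation.
#'
#' @param cohort A \code{cohort}.
#' @param grid Sparsity grid.
#' @param metrics Metrics to compute (default all seven).
#' @param null_n Null graphs per grid point for gamma/lambda/sigma.
#' @param null_rewires Swap attempts per edge in each null.
#' @param seed Seed for the null ensembles (default: the cohort's seed).
#' @return data.frame with subject_id, group, score and auc_* columns.
#' @export
cohort_features <- function(cohort, grid = sparsity_grid(),
                            metrics = all_metrics, null_n = 100,
                            null_rewires = 10, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  seed <- seed %||% cohort$config$seed
  rows <- lapply(seq_along(cohort$subjects), function(i) {
    z <- fisher_z(correlation_matrix(cohort$subjects[[i]]))
    mc <- metric_curves(z, grid = grid, metrics = metrics, null_n = null_n,
                        null_rewires = null_rewires,
                        seed = derive_seed(seed, "feat", i))
    as.list(mc$aucs)
  })
  met2col <- c(gamma = "auc_gamma", lambda = "auc_lambda",
               sigma = "auc_sigma", Cp = "auc_cp", Lp = "auc_lp",
               Eglobal = "auc_eglobal", Elocal = "auc_elocal")
  auc <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(stats::setNames(r, met2col[names(r)]))))
  auc <- auc[, intersect(feature_order, colnames(auc)), drop = FALSE]
  cbind(cohort$manifest[, c("subject_id", "group", "score")], auc)
}

#' Write a Table-style feature weight report
#'
#' @param weights Weight vector from \code{feature_weights}.
#' @param path CSV path.
#' @export
write_weight_report <- function(weights, path) {
  utils::write.csv(data.frame(feature = names(weights),
                              weight_percent = round(100 * weights, 2)),
                   path, row.names = FALSE)
  invisible(path)
}
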