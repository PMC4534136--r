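#' Principal component reduction of a selected component subset
#'
#' Mean-centering, sample covariance (`n - 1` denominator), symmetric
#' eigendecomposition and cumulative-variance principal-component selection:
#' the steps that project a selected set of color components onto the
#' orthogonal axes of maximal variance. Only centering is applied — no
#' variance scaling — so this is covariance PCA, not correlation PCA.
#'
#' @name pca-reduction
NULL

#' Mean-center a data matrix
#'
#' @param x An `n x d` numeric matrix, `n >= 2`.
#' @return A `centered_matrix`: list with `values` (centered data) and
#'   `column_means`.
#' @export
center_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("centering requires at least 2 rows")
  mu <- colMeans(x)
  structure(list(values = sweep(x, 2L, mu), column_means = mu),
            class = "centered_matrix")
}

#' Sample covariance of a centered matrix
#'
#' @param centered A `centered_matrix` from [center_matrix()].
#' @return A `d x d` symmetric covariance matrix (denominator `n - 1`).
#' @export
covariance_matrix <- function(centered) {
  stopifnot(inherits(centered, "centered_matrix"))
  v <- centered$values
  crossprod(v) / (nrow(v) - 1)
}

#' Eigendecompose a covariance matrix into a PCA model
#'
#' Eigenpairs are sorted by eigenvalue descending. Because an eigenvector's
#' sign is arbitrary, each is flipped so that its largest-magnitude entry is
#' positive (ties broken by lowest index), making results deterministic.
#'
#' @param cov A symmetric `d x d` covariance matrix.
#' @param column_means Length-`d` means recorded at centering.
#' @param component_ids Length-`d` component identifiers.
#' @param tol Symmetry tolerance; asymmetry beyond it is an error.
#' @return A `pca_model`: `eigenvalues` (descending), `eigenvectors`
#'   (columns paired with eigenvalues, unit norm), `column_means`,
#'   `component_ids`.
#' @export
eigendecompose <- function(cov, column_means = rep(0, ncol(cov)),
                           component_ids = colnames(cov) %||%
                             paste0("c", seq_len(ncol(cov))),
                           tol = 1e-9) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) stopf("covariance matrix must be square")
  if (max(abs(cov - t(cov))) > tol * max(1, max(abs(cov))))
    stopf("covariance matrix is not symmetric within tolerance")
  if (length(column_means) != ncol(cov) ||
      length(component_ids) != ncol(cov))
    stopf("means and component ids must have length %d", ncol(cov))
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))  # which.max takes lowest index on ties
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(eigenvalues = e$values, eigenvectors = vec,
                 column_means = as.numeric(column_means),
                 component_ids = component_ids),
            class = "pca_model")
}

#' Fit a PCA model to the selected columns of a feature matrix
#'
#' Convenience composition of [center_matrix()], [covariance_matrix()] and
#' [eigendecompose()].
#'
#' @param x An `n x d` matrix (or `pixel_feature_matrix` plus `subset`).
#' @param subset Optional logical mask over feature columns.
#' @return A `pca_model`.
#' @export
fit_pca <- function(x, subset = NULL) {
  if (inherits(x, "pixel_feature_matrix")) {
    ids <- x$column_ids
    if (!is.null(subset)) {
      ids <- ids[subset]
      x <- subset_features(x, subset)
    } else x <- x$values
    colnames(x) <- ids
  }
  ctr <- center_matrix(x)
  eigendecompose(covariance_matrix(ctr), ctr$column_means,
                 colnames(x) %||% paste0("c", seq_len(ncol(x))))
}

#' Cumulative fraction of variance explained by the leading components
#'
#' @param model A `pca_model`.
#' @param k Number of leading principal components, `1 <= k <= d`.
#' @return `sum(lambda[1:k]) / sum(lambda)`; 0 for an all-zero spectrum.
#' @export
explained_variance <- function(model, k) {
  stopifnot(inherits(model, "pca_model"))
  d <- length(model$eigenvalues)
  if (!is_count(k) || k > d) stopf("k must be an integer in [1, %d]", d)
  tot <- sum(model$eigenvalues)
  if (tot == 0) return(0)
  sum(model$eigenvalues[seq_len(k)]) / tot
}

#' Turn a PCA model into a hybrid color space
#'
#' The first `k` eigenvectors become the loading rows of a [hybrid_space()]
#' over the model's component identifiers; the recorded component means are
#' subtracted before projection. The default `k = 3` mirrors the published
#' three-component reduction.
#'
#' @param model A `pca_model`.
#' @param k Output dimensionality (default 3).
#' @param names Optional output plane names (default `PC1..PCk`).
#' @return A `hybrid_space`.
#' @export
make_space <- function(model, k = 3, names = NULL) {
  stopifnot(inherits(model, "pca_model"))
  d <- length(model$eigenvalues)
  if (!is_count(k) || k > d) stopf("k must be an integer in [1, %d]", d)
  hybrid_space(component_ids = model$component_ids,
               means = model$column_means,
               loadings = t(model$eigenvectors[, seq_len(k), drop = FALSE]),
               names = names %||% paste0("PC", seq_len(k)),
               eigenvalues = model$eigenvalues)
}
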