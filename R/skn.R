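#' Hybrid color spaces and the canonical SKN transform
#'
#' A hybrid space is a linear map from a subset of registry components to a
#' small number of output planes: per pixel, `output = loadings %*%
#' (components - means)`. Spaces produced by [make_space()] have unit-norm
#' loading rows (eigenvectors); arbitrary affine maps — such as the published
#' SKN equations, whose constant terms are absorbed as synthetic means — are
#' also representable.
#'
#' The canonical SKN transform is, with `g = G/(R+G+B)` (and `g = 1/3` for
#' the black pixel):
#' \deqn{S = 0.088 g - 58.89 G - 30.014 R - 11.952 B - 7.24}
#' \deqn{K = 0.62 g + 14.859 G + 6.921 R + 2.122 B + 1.744}
#' \deqn{N = 0.342 g - 3.698 G - 2.25 R - 0.103 B - 0.464}
#' RGB channels are on the `[0, 1]` scale (a documented convention; the
#' coefficients' native scale is not fixed by their source).
#'
#' @name skn-space
NULL

.SKN_COEF <- rbind(
  S = c(g = 0.088,  G = -58.89, R = -30.014, B = -11.952),
  K = c(g = 0.62,   G = 14.859, R = 6.921,   B = 2.122),
  N = c(g = 0.342,  G = -3.698, R = -2.25,   B = -0.103))
.SKN_CONST <- c(S = -7.24, K = 1.744, N = -0.464)

#' Construct a hybrid color space
#'
#' @param component_ids Ordered registry identifiers of the input components.
#' @param means Per-component values subtracted before projection.
#' @param loadings `k x d` coefficient matrix (`k` output planes).
#' @param names Output plane names (default `PC1..PCk`).
#' @param eigenvalues Optional spectrum carried over from a PCA fit.
#' @return A `hybrid_space` object.
#' @seealso [make_space()], [apply_hybrid()], [skn_space()]
#' @export
hybrid_space <- function(component_ids, means, loadings, names = NULL,
                         eigenvalues = NULL) {
  loadings <- as.matrix(loadings)
  d <- length(component_ids)
  if (ncol(loadings) != d || length(means) != d)
    stopf("loadings columns and means must match the %d component ids", d)
  if (anyDuplicated(component_ids)) stopf("component ids must be unique")
  names <- names %||% paste0("PC", seq_len(nrow(loadings)))
  if (length(names) != nrow(loadings))
    stopf("need one name per loading row")
  rownames(loadings) <- names
  colnames(loadings) <- component_ids
  structure(list(component_ids = as.character(component_ids),
                 means = as.numeric(means), loadings = loadings,
                 names = names, eigenvalues = eigenvalues),
            class = "hybrid_space")
}

#' @export
print.hybrid_space <- function(x, ...) {
  cat(sprintf("<hybrid_space> %d planes (%s) over %d components: %s\n",
              nrow(x$loadings), paste(x$names, collapse = ","),
              length(x$component_ids),
              paste(x$component_ids, collapse = ", ")))
  invisible(x)
}

#' Check that a hybrid space has eigenvector (unit-norm) loading rows
#'
#' @param space A `hybrid_space`.
#' @param tol Tolerance on the row norms.
#' @return `TRUE` invisibly, or an error naming the offending row.
#' @export
validate_unit_loadings <- function(space, tol = 1e-8) {
  stopifnot(inherits(space, "hybrid_space"))
  nrm <- sqrt(rowSums(space$loadings^2))
  bad <- which(abs(nrm - 1) > tol)
  if (length(bad))
    stopf("loading row %d has norm %.6f, expected 1", bad[1], nrm[bad[1]])
  invisible(TRUE)
}

#' The canonical SKN hybrid space
#'
#' The published three-plane transform expressed as a [hybrid_space()] over
#' the registry components `G_nRGB`, `G_RGB`, `R_RGB`, `B_RGB`; the constant
#' terms of the defining equations are absorbed into the mean vector (the
#' minimum-norm solution of `loadings %*% means = -constants`), so
#' [apply_hybrid()] on this object reproduces [rgb_to_skn()] exactly.
#'
#' @return A `hybrid_space` named `S`, `K`, `N`.
#' @export
skn_space <- function() {
  L <- unname(.SKN_COEF)
  mu <- -drop(t(L) %*% solve(L %*% t(L), .SKN_CONST))
  hybrid_space(component_ids = c("G_nRGB", "G_RGB", "R_RGB", "B_RGB"),
               means = mu, loadings = L, names = c("S", "K", "N"))
}

#' SKN coordinates of RGB pixels
#'
#' @param rgb Either a length-3 vector `(R, G, B)` or an `n x 3` matrix of
#'   RGB rows, channels in `[0, 1]`.
#' @return A matrix with columns `S`, `K`, `N` (one row per input pixel);
#'   for a single vector input, a named length-3 vector.
#' @examples
#' rgb_to_skn(c(0, 0, 0))   # approx (-7.2107, 1.9507, -0.3500)
#' @export
rgb_to_skn <- function(rgb) {
  vec <- is.null(dim(rgb))
  if (vec) rgb <- matrix(rgb, nrow = 1)
  if (ncol(rgb) != 3L) stopf("rgb must have 3 columns")
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 1))
    stopf("RGB channels must lie in [0, 1]")
  g <- rgb_chromaticity(rgb)[, 2]
  X <- cbind(g, rgb[, 2], rgb[, 1], rgb[, 3])
  out <- X %*% t(.SKN_COEF) +
    matrix(.SKN_CONST, nrow(rgb), 3, byrow = TRUE)
  colnames(out) <- c("S", "K", "N")
  if (vec) drop(out) else out
}

#' Transform a whole image to SKN planes
#'
#' Vectorized, pixel-independent application of [rgb_to_skn()].
#'
#' @inheritParams color_transform
#' @return An `H x W x 3` array with planes `S`, `K`, `N`.
#' @export
rgb_image_to_skn <- function(image) {
  check_rgb_image(image)
  rows_to_planes(rgb_to_skn(planes_to_rows(image)),
                 dim(image)[1], dim(image)[2])
}

#' Apply a hybrid space to an image
#'
#' Resolves the space's component identifiers in the registry, computes the
#' needed planes, and projects each pixel: `loadings %*% (x - means)`.
#'
#' @param space A `hybrid_space`.
#' @param image An `H x W x 3` RGB array in `[0, 1]`.
#' @param registry Registry used to resolve component ids (default: the
#'   extended registry, so `V_HSV` is available).
#' @return An `H x W x k` array of output planes.
#' @export
apply_hybrid <- function(space, image, registry = component_registry("extended")) {
  stopifnot(inherits(space, "hybrid_space"))
  check_rgb_image(image)
  vals <- hybrid_feature_rows(space, planes_to_rows(image), registry)
  rows_to_planes(vals, dim(image)[1], dim(image)[2])
}

# project n x 3 RGB rows through a hybrid space -> n x k feature rows
hybrid_feature_rows <- function(space, rgb_rows,
                                registry = component_registry("extended")) {
  check_registry(registry)
  hit <- match(space$component_ids, registry$id)
  if (anyNA(hit))
    stopf("component id(s) not in registry: %s",
          paste(space$component_ids[is.na(hit)], collapse = ", "))
  comp <- registry_values(rgb_rows, registry[hit, , drop = FALSE])
  out <- sweep(comp, 2L, space$means) %*% t(space$loadings)
  colnames(out) <- space$names
  out
}
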