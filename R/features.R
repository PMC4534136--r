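#' Pixel feature matrix construction
#'
#' Every image/mask pair contributes one row per pixel: the registry's
#' component values in registry column order, plus a 0/1 skin label copied
#' from the mask. Rows follow image order, then row-major pixel order
#' (top-left origin). This matrix is the substrate the genetic-algorithm
#' feature search and the PCA reduction operate on.
#'
#' @name pixel-features
NULL

new_pixel_features <- function(values, labels, column_ids) {
  stopifnot(nrow(values) == length(labels), ncol(values) == length(column_ids))
  structure(list(values = values, labels = as.integer(labels),
                 column_ids = column_ids),
            class = "pixel_feature_matrix")
}

#' @export
print.pixel_feature_matrix <- function(x, ...) {
  cat(sprintf("<pixel_feature_matrix> %d pixels x %d components (%d skin, %d non-skin)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Build the labelled pixel feature matrix from image/mask pairs
#'
#' @param pairs A list of `list(image =, mask =)` pairs: `image` an
#'   `H x W x 3` array in `[0, 1]`, `mask` an `H x W` 0/1 matrix (1 = skin)
#'   of identical dimensions.
#' @param registry Component registry fixing the columns (default: the
#'   printed 32-component list).
#' @return A `pixel_feature_matrix` with `values` (`n x m`), `labels`
#'   (length `n`, 0/1) and `column_ids` (length `m`). `n` is the total pixel
#'   count over all pairs.
#' @export
build_feature_matrix <- function(pairs, registry = component_registry()) {
  check_registry(registry)
  if (!is.list(pairs) || length(pairs) == 0L)
    stopf("pairs must be a non-empty list of image/mask pairs")
  blocks <- vector("list", length(pairs))
  labels <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    img <- p$image %||% p[[1]]
    msk <- p$mask %||% p[[2]]
    check_rgb_image(img, what = sprintf("image of pair %d", i))
    ok <- tryCatch({check_mask(msk, img); TRUE}, error = function(e) e)
    if (!isTRUE(ok))
      stopf("pair %d: %s", i, conditionMessage(ok))
    blocks[[i]] <- registry_values(planes_to_rows(img), registry)
    labels[[i]] <- as.integer(as.vector(t(msk)))
  }
  new_pixel_features(do.call(rbind, blocks), unlist(labels), registry$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Select columns of a feature matrix by a logical subset mask
subset_features <- function(feats, mask) {
  stopifnot(inherits(feats, "pixel_feature_matrix"),
            length(mask) == ncol(feats$values))
  feats$values[, mask, drop = FALSE]
}
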