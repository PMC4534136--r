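#' Image, mask and artifact input/output
#'
#' Images are read into `H x W x 3` arrays on the `[0, 1]` scale (8-bit
#' files are divided by 255 by the decoders). PNG is always available;
#' JPEG and binary/ASCII PPM are supported when the optional `jpeg` and
#' `pixmap` packages are installed. Masks are single-channel PNGs whose
#' pixels must be exactly 0 or 255 (mapped to 0/1); anything else is
#' rejected. Derived artifacts — component subsets, hybrid spaces,
#' evaluation reports — serialize to JSON.
#'
#' @name artifact-io
NULL

#' Read an RGB image
#'
#' @param path PNG, JPEG (`.jpg`/`.jpeg`) or PPM file.
#' @return `H x W x 3` array in `[0, 1]`. Grayscale input is replicated
#'   across channels; an alpha channel is dropped.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("no such image file: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stopf("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    ppm = , pnm = , pgm = {
      if (!requireNamespace("pixmap", quietly = TRUE))
        stopf("reading PPM requires the 'pixmap' package")
      pm <- pixmap::read.pnm(path)
      if (methods::is(pm, "pixmapRGB"))
        array(c(pm@red, pm@green, pm@blue), c(pm@size, 3))
      else array(rep(pm@grey, 3), c(pm@size, 3))
    },
    stopf("unsupported image format '.%s' (use png/jpeg/ppm)", ext))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  check_rgb_image(px, what = path)
  px
}

#' Write an RGB image as PNG
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  check_rgb_image(image)
  png::writePNG(image, path)
  invisible(path)
}

#' Read a binary skin mask
#'
#' @param path Single-channel PNG with pixel values 0 (non-skin) or 255
#'   (skin) only.
#' @return `H x W` 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("no such mask file: %s", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L &&
        (max(abs(px[, , 1] - px[, , 2])) > 0 ||
         max(abs(px[, , 1] - px[, , 3])) > 0))
      stopf("mask %s is not single-channel", path)
    px <- px[, , 1]
  }
  if (!all(px %in% c(0, 1)))
    stopf("mask %s contains values other than 0 and 255", path)
  matrix(as.integer(px), nrow(px), ncol(px))
}

#' Write a binary skin mask as PNG (0/255)
#' @param mask `H x W` 0/1 matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write transform planes to a directory
#'
#' One file per component plane: `txt` (plain full-precision text matrix,
#' the default) or `pgm` (16-bit binary P5, min/max-normalized with the
#' affine range recorded in a JSON sidecar).
#'
#' @param planes `H x W x k` array with named third dimension.
#' @param dir Output directory.
#' @param format `"txt"` or `"pgm"`.
#' @return Character vector of files written.
#' @export
write_planes <- function(planes, dir, format = c("txt", "pgm")) {
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create directory '%s'", dir)
  nm <- dimnames(planes)[[3]] %||% paste0("plane", seq_len(dim(planes)[3]))
  out <- character(0)
  for (j in seq_len(dim(planes)[3])) {
    plane <- planes[, , j]
    if (format == "txt") {
      f <- file.path(dir, paste0(nm[j], ".txt"))
      utils::write.table(format(plane, digits = 17), f, row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    } else {
      f <- file.path(dir, paste0(nm[j], ".pgm"))
      rng <- range(plane)
      scl <- if (diff(rng) > 0) (plane - rng[1]) / diff(rng) else plane * 0
      q <- t(round(scl * 65535))
      con <- file(f, "wb")
      writeLines(c("P5", sprintf("%d %d", ncol(plane), nrow(plane)),
                   "65535"), con)
      writeBin(as.integer(q), con, size = 2, endian = "big")
      close(con)
      jsonlite::write_json(list(min = rng[1], max = rng[2]),
                           paste0(f, ".json"), auto_unbox = TRUE)
    }
    out <- c(out, f)
  }
  invisible(out)
}

#' Read or write a dataset manifest
#'
#' A manifest is a CSV with columns `image` and `mask` (paths, resolved
#' relative to the manifest's directory when not absolute) and optionally
#' `split` (`train`/`test`).
#'
#' @param path CSV file.
#' @return Data frame with resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("no such manifest: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "mask") %in% names(m)))
    stopf("manifest must have 'image' and 'mask' columns")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  m$image <- resolve(m$image)
  m$mask <- resolve(m$mask)
  missing <- c(m$image[!file.exists(m$image)], m$mask[!file.exists(m$mask)])
  if (length(missing))
    stopf("manifest references missing files: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  if ("split" %in% names(m) && !all(m$split %in% c("train", "test")))
    stopf("split tags must be 'train' or 'test'")
  m
}

#' @rdname read_manifest
#' @param manifest Data frame with `image`, `mask` (and optionally `split`).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

# load manifest rows into in-memory (image, mask) pairs
load_pairs <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i)
    list(image = read_image(manifest$image[i]),
         mask = read_mask(manifest$mask[i])))
}

#' Serialize / deserialize a hybrid space as JSON
#'
#' @param space A [hybrid_space()].
#' @param path JSON file path.
#' @return `read_space` returns the reconstructed `hybrid_space`.
#' @export
write_space <- function(space, path) {
  stopifnot(inherits(space, "hybrid_space"))
  jsonlite::write_json(
    list(component_ids = space$component_ids, means = space$means,
         loadings = unname(as.matrix(space$loadings)), names = space$names,
         eigenvalues = space$eigenvalues),
    path, digits = NA, auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  hybrid_space(j$component_ids, j$means, j$loadings, j$names,
               eigenvalues = j$eigenvalues)
}

#' Serialize / deserialize a component subset as JSON
#'
#' @param subset Logical genome over the registry.
#' @param column_ids Component identifiers, one per genome bit.
#' @param path JSON file path.
#' @export
write_subset <- function(subset, column_ids, path) {
  stopifnot(length(subset) == length(column_ids))
  jsonlite::write_json(
    list(column_ids = column_ids, mask = as.logical(subset),
         selected = column_ids[as.logical(subset)]),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_subset
#' @export
read_subset <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(column_ids = j$column_ids, mask = as.logical(j$mask),
       selected = j$selected)
}
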