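# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the Mersenne-Twister stream seeded to `seed`, then
#' restores the caller's RNG state, so library functions never clobber a
#' user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results independent across named substreams (ga, split, synth, ...).
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483399) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

#' Validate an RGB image array
#' @noRd
check_rgb_image <- function(pixels, what = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("%s must be an H x W x 3 array", what)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stopf("%s must have positive dimensions", what)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 1))
    stopf("%s channel values must lie in [0, 1]", what)
  invisible(pixels)
}

check_mask <- function(mask, image = NULL, what = "mask") {
  if (!is.matrix(mask)) stopf("%s must be an H x W matrix", what)
  if (!all(mask %in% c(0, 1))) stopf("%s values must be 0 or 1", what)
  if (!is.null(image)) {
    d <- dim(image)
    if (d[1] != nrow(mask) || d[2] != ncol(mask))
      stopf("%s dimensions (%d x %d) do not match image (%d x %d)",
            what, nrow(mask), ncol(mask), d[1], d[2])
  }
  invisible(mask)
}

# Flatten H x W x k planes to a (H*W) x k matrix in row-major pixel order
# (top-left origin, scan rows left to right). R arrays are column-major, so
# transpose each plane before unrolling.
planes_to_rows <- function(planes) {
  d <- dim(planes)
  out <- matrix(0, d[1] * d[2], d[3])
  for (j in seq_len(d[3])) out[, j] <- as.vector(t(planes[, , j]))
  colnames(out) <- dimnames(planes)[[3]]
  out
}

rows_to_planes <- function(rows, h, w) {
  k <- ncol(rows)
  out <- array(0, c(h, w, k))
  for (j in seq_len(k)) out[, , j] <- matrix(rows[, j], h, w, byrow = TRUE)
  dimnames(out) <- list(NULL, NULL, colnames(rows))
  out
}
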