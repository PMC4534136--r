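#' Synthetic scenes and planted feature matrices
#'
#' Seeded generators that emulate the structure of skin-detection
#' benchmarks: images contain elliptical "skin" regions whose colors are
#' drawn from a compact Gaussian cluster in the (Cb, Cr) chroma plane —
#' the classic skin locus — over heterogeneous backgrounds, with exact
#' (hard-rasterized, never anti-aliased) ground-truth masks. Three
#' background regimes are provided: `textured` (smooth non-skin-hued
#' gradients, the default separable world), `uniform_noise` (iid random
#' colors) and `skin_like_distractor` (textured plus patches of near-skin
#' colors that exercise false-positive behavior). A companion generator
#' plants class-informative columns in an otherwise label-independent
#' feature matrix for testing wrapper feature selection.
#'
#' @name synthetic-data
NULL

#' Scene generator configuration
#'
#' @param height,width Scene dimensions in pixels (>= 16).
#' @param n_regions Number of elliptical skin regions (0 for none).
#' @param skin_chroma List with `mean` (length-2, Cb and Cr on the
#'   full-range `[0, 1]` scale) and `cov` (2 x 2 covariance) of skin colors
#'   in the chroma plane.
#' @param background_mode One of `"textured"`, `"uniform_noise"`,
#'   `"skin_like_distractor"`.
#' @param skin_fraction_target Target fraction of skin pixels, in (0, 0.9).
#' @param seed Integer seed.
#' @return A validated `scene_config`.
#' @export
scene_config <- function(height = 128L, width = 128L, n_regions = 3L,
                         skin_chroma = list(mean = c(0.42, 0.58),
                                            cov = diag(4e-4, 2)),
                         background_mode = c("textured", "uniform_noise",
                                             "skin_like_distractor"),
                         skin_fraction_target = 0.25, seed = 1L) {
  background_mode <- match.arg(background_mode)
  if (!is_count(height, 16) || !is_count(width, 16))
    stopf("scene dimensions must be integers >= 16")
  if (!is_count(n_regions, 0)) stopf("n_regions must be a non-negative integer")
  if (!is.numeric(skin_fraction_target) || skin_fraction_target <= 0 ||
      skin_fraction_target >= 0.9)
    stopf("skin_fraction_target must lie in (0, 0.9)")
  if (length(skin_chroma$mean) != 2L || !all(dim(skin_chroma$cov) == 2L))
    stopf("skin_chroma needs a length-2 mean and 2 x 2 cov")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_regions = as.integer(n_regions), skin_chroma = skin_chroma,
                 background_mode = background_mode,
                 skin_fraction_target = skin_fraction_target,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# full-range BT.601 inverse: (Y, Cb, Cr) rows -> RGB rows, clipped to [0,1]
ycbcr_to_rgb <- function(y, cb, cr) {
  R <- y + (cr - 0.5) * (1 - 0.299) / 0.5
  B <- y + (cb - 0.5) * (1 - 0.114) / 0.5
  G <- (y - 0.299 * R - 0.114 * B) / 0.587
  cbind(pmin(pmax(R, 0), 1), pmin(pmax(G, 0), 1), pmin(pmax(B, 0), 1))
}

# sample n skin colors from the configured chroma cluster (current stream)
sample_skin_colors <- function(n, chroma) {
  z <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(chroma$cov)
  cb <- z[, 1] + chroma$mean[1]
  cr <- z[, 2] + chroma$mean[2]
  y <- stats::runif(n, 0.35, 0.75)
  ycbcr_to_rgb(y, cb, cr)
}

# smooth low-frequency scalar field in [0,1], current stream
smooth_field <- function(h, w, waves = 3L) {
  xs <- matrix(rep(seq_len(w), each = h), h, w) / w
  ys <- matrix(rep(seq_len(h), w), h, w) / h
  f <- matrix(0, h, w)
  for (i in seq_len(waves)) {
    fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + sin(2 * pi * fx * xs + ph[1]) * cos(2 * pi * fy * ys + ph[2])
  }
  (f - min(f)) / max(1e-12, diff(range(f)))
}

# paint an ellipse mask; hard rasterization of pixel centers
ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

scene_background <- function(config) {
  h <- config$height; w <- config$width
  mode <- config$background_mode
  if (mode == "uniform_noise") {
    return(array(stats::runif(h * w * 3), c(h, w, 3)))
  }
  # textured: smooth luma field colorized with a non-skin chroma; hues are
  # drawn away from the skin locus so the default world stays separable
  img <- array(0, c(h, w, 3))
  base <- 0.2 + 0.6 * smooth_field(h, w)
  repeat {
    cb <- stats::runif(1, 0.2, 0.8)
    cr <- stats::runif(1, 0.2, 0.8)
    if (sqrt(sum((c(cb, cr) - config$skin_chroma$mean)^2)) > 0.15) break
  }
  rgb <- ycbcr_to_rgb(as.vector(base), rep(cb, h * w), rep(cr, h * w))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], h, w)
  if (mode == "skin_like_distractor") {
    for (i in seq_len(2L)) {
      m <- ellipse_mask(h, w, stats::runif(1, 1, w), stats::runif(1, 1, h),
                        stats::runif(1, w / 12, w / 6),
                        stats::runif(1, h / 12, h / 6),
                        stats::runif(1, 0, pi))
      near <- config$skin_chroma
      near$mean <- near$mean + stats::runif(2, -0.05, 0.05)
      cols <- sample_skin_colors(sum(m), near)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- cols[, ch]
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Generate one synthetic scene with its exact mask
#'
#' Elliptical skin regions are placed at random and re-placed (bounded
#' retries) until the achieved skin fraction is within 0.1 of the target;
#' region colors are per-pixel draws from the configured chroma cluster.
#' Bit-identical for identical `config` (including its seed).
#'
#' @param config A [scene_config()].
#' @return List with `image` (`H x W x 3` in `[0, 1]`) and `mask`
#'   (`H x W` 0/1 integer matrix, 1 = skin).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$height; w <- config$width
  with_seed(config$seed, {
    img <- scene_background(config)
    mask <- matrix(0L, h, w)
    if (config$n_regions > 0L) {
      target <- config$skin_fraction_target
      got <- FALSE
      for (try in seq_len(25L)) {
        cand <- matrix(FALSE, h, w)
        area_per <- target * h * w / config$n_regions
        for (r in seq_len(config$n_regions)) {
          aspect <- stats::runif(1, 0.5, 2)
          a <- sqrt(area_per * aspect / pi)
          b <- area_per / (pi * a)
          # keep regions inside the canvas when they fit; center otherwise
          cx <- stats::runif(1, min(a, (w + 1) / 2), max(w - a + 1, (w + 1) / 2))
          cy <- stats::runif(1, min(b, (h + 1) / 2), max(h - b + 1, (h + 1) / 2))
          cand <- cand | ellipse_mask(h, w, cx, cy, a, b,
                                      stats::runif(1, 0, pi))
        }
        if (abs(mean(cand) - target) <= 0.1) {
          mask <- matrix(as.integer(cand), h, w)
          got <- TRUE
          break
        }
      }
      if (!got)
        stopf("could not achieve skin fraction %.2f with %d regions",
              target, config$n_regions)
      skin <- mask == 1L
      cols <- sample_skin_colors(sum(skin), config$skin_chroma)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[skin] <- cols[, ch]
        img[, , ch] <- plane
      }
    }
    list(image = img, mask = mask)
  })
}

#' Generate a dataset of scenes on disk
#'
#' Writes `scene_###.png` / `mask_###.png` under `out_dir` plus a
#' `manifest.csv` pairing them; per-image seeds are derived from the master
#' seed, so any image can be regenerated independently.
#'
#' @param n_images Number of scenes (>= 1).
#' @param config A [scene_config()] template (its seed is replaced per
#'   image).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @return The manifest data frame (`image`, `mask` paths), invisibly
#'   written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_images, config = scene_config(),
                             out_dir = tempfile("scenes"), seed = 1L) {
  if (!is_count(n_images)) stopf("n_images must be a positive integer")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("scene", i))
    sc <- generate_scene(cfg)
    img_path <- file.path(out_dir, sprintf("scene_%03d.png", i))
    msk_path <- file.path(out_dir, sprintf("mask_%03d.png", i))
    write_image(sc$image, img_path)
    write_mask(sc$mask, msk_path)
    rows[[i]] <- data.frame(image = img_path, mask = msk_path,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Planted-feature matrix configuration
#'
#' @param n Number of rows (pixels).
#' @param m Number of columns (default 32, matching the registry).
#' @param informative Column indices carrying class signal.
#' @param separation Standardized mean difference between classes in the
#'   informative columns (> 0).
#' @param noise_sd Common within-class standard deviation.
#' @param class_balance Probability of the skin class.
#' @param seed Integer seed.
#' @return A validated `planted_config`.
#' @export
planted_config <- function(n = 2000L, m = 32L, informative = 1:3,
                           separation = 6, noise_sd = 1,
                           class_balance = 0.5, seed = 1L) {
  if (!is_count(n, 2) || !is_count(m)) stopf("n and m must be positive integers")
  if (length(informative) && (any(informative < 1) || any(informative > m)))
    stopf("informative indices must lie in 1..%d", m)
  if (!is.numeric(separation) || separation < 0)
    stopf("separation must be >= 0")
  if (!is_prob(class_balance) || class_balance <= 0 || class_balance >= 1)
    stopf("class_balance must lie in (0, 1)")
  structure(list(n = as.integer(n), m = as.integer(m),
                 informative = as.integer(informative),
                 separation = separation, noise_sd = noise_sd,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "planted_config")
}

#' Generate a planted feature matrix
#'
#' Informative columns are class-conditional normals whose means differ by
#' `separation` standard deviations; all other columns are label-independent
#' noise. The result is a `pixel_feature_matrix`, directly usable by
#' [run_ga()].
#'
#' @param config A [planted_config()].
#' @return A `pixel_feature_matrix` with columns `col01..colmm`.
#' @export
planted_matrix <- function(config = planted_config()) {
  stopifnot(inherits(config, "planted_config"))
  with_seed(config$seed, {
    labels <- stats::rbinom(config$n, 1L, config$class_balance)
    # degenerate single-class draws would break CV; flip one row
    if (length(unique(labels)) < 2L) labels[1] <- 1L - labels[1]
    X <- matrix(stats::rnorm(config$n * config$m, sd = config$noise_sd),
                config$n, config$m)
    for (j in config$informative)
      X[, j] <- X[, j] + labels * config$separation * config$noise_sd
    colnames(X) <- sprintf("col%02d", seq_len(config$m))
    new_pixel_features(X, labels, colnames(X))
  })
}
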