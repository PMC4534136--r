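# Independent scalar reference implementations used as oracles.
# Straight-line per-pixel formula evaluation, no vectorization, written
# directly from the dialect definitions (BT.601 / CIE D65 / Terrillon /
# Xerox / Ohta). Kept deliberately separate from the package code paths.

ref_luma <- function(R, G, B) 0.299 * R + 0.587 * G + 0.114 * B

ref_xyz <- function(R, G, B) {
  c(0.4124564 * R + 0.3575761 * G + 0.1804375 * B,
    0.2126729 * R + 0.7151522 * G + 0.0721750 * B,
    0.0193339 * R + 0.1191920 * G + 0.9503041 * B)
}

ref_lab_f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29

# one pixel -> named component vector for a given space
ref_transform_pixel <- function(R, G, B, space) {
  Y <- ref_luma(R, G, B)
  switch(space,
    RGB = c(R, G, B),
    nRGB = {
      s <- R + G + B
      if (s == 0) c(1, 1, 1) / 3 else c(R, G, B) / s
    },
    HSI = {
      I <- (R + G + B) / 3
      S <- if (I > 0) 1 - min(R, G, B) / I else 0
      den <- sqrt((R - G)^2 + (R - B) * (G - B))
      H <- if (den > 0) {
        th <- acos(max(-1, min(1, 0.5 * ((R - G) + (R - B)) / den)))
        (if (B <= G) th else 2 * pi - th) / (2 * pi)
      } else 0
      c(H, S, I)
    },
    HSV = {
      V <- max(R, G, B); mn <- min(R, G, B); d <- V - mn
      S <- if (V > 0) d / V else 0
      H <- if (d == 0) 0
      else if (V == R) (((G - B) / d) %% 6) / 6
      else if (V == G) ((B - R) / d + 2) / 6
      else ((R - G) / d + 4) / 6
      c(H, S, V)
    },
    XYZ = ref_xyz(R, G, B),
    LAB = {
      xyz <- ref_xyz(R, G, B)
      fx <- ref_lab_f(xyz[1] / 0.95047)
      fy <- ref_lab_f(xyz[2])
      fz <- ref_lab_f(xyz[3] / 1.08883)
      c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
    },
    LUV = {
      xyz <- ref_xyz(R, G, B)
      L <- 116 * ref_lab_f(xyz[2]) - 16
      den <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
      up <- if (den > 0) 4 * xyz[1] / den else 0
      vp <- if (den > 0) 9 * xyz[2] / den else 0
      upn <- 4 * 0.95047 / (0.95047 + 15 + 3 * 1.08883)
      vpn <- 9 / (0.95047 + 15 + 3 * 1.08883)
      c(L, 13 * L * (up - upn), 13 * L * (vp - vpn))
    },
    TSL = {
      s <- R + G + B
      r <- if (s == 0) 1 / 3 else R / s
      g <- if (s == 0) 1 / 3 else G / s
      rp <- r - 1 / 3; gp <- g - 1 / 3
      T <- if (gp > 0) atan(rp / gp) / (2 * pi) + 1 / 4
      else if (gp < 0) atan(rp / gp) / (2 * pi) + 3 / 4
      else 0
      c(T, sqrt(9 / 5 * (rp^2 + gp^2)), Y)
    },
    YCbCr = c(Y, 0.5 + 0.5 * (B - Y) / (1 - 0.114), 0.5 + 0.5 * (R - Y) / (1 - 0.299)),
    YCgCr = c(Y, 0.5 + 0.5 * (G - Y) / (1 - 0.587), 0.5 + 0.5 * (R - Y) / (1 - 0.299)),
    YES = c(0.253 * R + 0.684 * G + 0.063 * B,
            (R - G) / 2, (R + G) / 4 - B / 2),
    YIQ = c(Y, 0.5 + 0.595716 * R - 0.274453 * G - 0.321263 * B,
            0.5 + 0.211456 * R - 0.522591 * G + 0.311135 * B),
    YPbPr = c(Y, 0.5 - 0.168736 * R - 0.331264 * G + 0.5 * B,
              0.5 + 0.5 * R - 0.418688 * G - 0.081312 * B),
    YUV = c(Y, 0.5 + 0.492 * (B - Y), 0.5 + 0.877 * (R - Y)),
    i1i2i3 = c((R + G + B) / 3, (R - B) / 2, (2 * G - R - B) / 4),
    RIQ = c(R, ref_transform_pixel(R, G, B, "YIQ")[2:3]),
    YQCr = c(Y, ref_transform_pixel(R, G, B, "YIQ")[3],
             ref_transform_pixel(R, G, B, "YCbCr")[3]),
    stop("no reference for ", space))
}

# coefficients (ascending powers) of det(C - lambda I) for d in {2, 3},
# expanded by hand: the characteristic-polynomial oracle for eigenvalues
charpoly_coefs <- function(cov) {
  d <- nrow(cov)
  if (d == 2) {
    c(cov[1, 1] * cov[2, 2] - cov[1, 2] * cov[2, 1],
      -(cov[1, 1] + cov[2, 2]), 1)
  } else {
    c(-det(cov),
      (cov[1, 1] * cov[2, 2] - cov[1, 2]^2) +
        (cov[1, 1] * cov[3, 3] - cov[1, 3]^2) +
        (cov[2, 2] * cov[3, 3] - cov[2, 3]^2),
      -(cov[1, 1] + cov[2, 2] + cov[3, 3]), 1)
  }
}

# scalar SKN reference, direct arithmetic from the defining equations
ref_skn_pixel <- function(R, G, B) {
  s <- R + G + B
  g <- if (s == 0) 1 / 3 else G / s
  c(S = 0.088 * g - 58.89 * G - 30.014 * R - 11.952 * B - 7.24,
    K = 2.122 * B + 14.859 * G + 6.921 * R + 0.62 * g + 1.744,
    N = 0.342 * g - 3.698 * G - 2.25 * R - 0.103 * B - 0.464)
}

# tiny RGB test image with fixed values
toy_image <- function(h = 4, w = 5, seed = 1) {
  withr_seed <- function(expr) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(array(runif(h * w * 3), c(h, w, 3)))
}

# an easily separable pair: skin pixels from a tight chroma cluster
toy_pair <- function(seed = 1, h = 24, w = 24) {
  generate_scene(scene_config(height = h, width = w, n_regions = 2,
                              skin_fraction_target = 0.3, seed = seed))
}

# two well-separated 2-D Gaussian blobs
blob_data <- function(n = 200, gap = 6, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(rnorm(n) + gap * y, rnorm(n) - gap * y)
  colnames(X) <- c("f1", "f2")
  list(X = X, y = y)
}
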