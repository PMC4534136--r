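#' Color space transforms
#'
#' All transforms operate on RGB with channels in `[0, 1]` (8-bit input is
#' divided by 255 at load time, see [read_image()]). Dialects, where several
#' exist in the literature, are fixed as follows and noted per space below:
#' BT.601 luma with full-range chroma centered at 0.5 for the YCbCr family;
#' CIE XYZ/LAB/LUV with sRGB primaries and D65 white applied directly to the
#' (nonlinear) RGB channels; Terrillon TSL; Xerox YES; Ohta i1i2i3. Hue is in
#' turns (range `[0, 1)`) and set to 0 on achromatic pixels. Chromaticities
#' use the black-pixel convention `R/(R+G+B) := 1/3` when `R+G+B = 0`.
#'
#' @name color-transforms
NULL

.SPACES <- c("HSI", "HSV", "LAB", "LUV", "nRGB", "RGB", "TSL", "XYZ",
             "YCbCr", "YCgCr", "YES", "YIQ", "YPbPr", "YUV", "i1i2i3",
             "RIQ", "YQCr")

# BT.601 luma weights, shared by the Y* family
.luma601 <- function(R, G, B) 0.299 * R + 0.587 * G + 0.114 * B

#' List supported color spaces
#' @return Character vector of the seventeen space identifiers.
#' @export
color_spaces <- function() .SPACES

#' Component (plane) names of a color space
#' @param space One of [color_spaces()].
#' @return Character vector of plane names in output order.
#' @export
space_components <- function(space) {
  space <- match_space(space)
  switch(space,
    HSI = c("H", "S", "I"), HSV = c("H", "S", "V"),
    LAB = c("L", "A", "B"), LUV = c("L", "U", "V"),
    nRGB = c("R", "G", "B"), RGB = c("R", "G", "B"),
    TSL = c("T", "S", "L"), XYZ = c("X", "Y", "Z"),
    YCbCr = c("Y", "CB", "CR"), YCgCr = c("Y", "CG", "CR"),
    YES = c("Y", "E", "S"), YIQ = c("Y", "I", "Q"),
    YPbPr = c("Y", "PB", "PR"), YUV = c("Y", "U", "V"),
    i1i2i3 = c("i1", "i2", "i3"), RIQ = c("R", "I", "Q"),
    YQCr = c("Y", "Q", "CR"))
}

match_space <- function(space) {
  if (!is.character(space) || length(space) != 1L)
    stopf("space must be a single character string")
  hit <- match(toupper(space), toupper(.SPACES))
  if (is.na(hit))
    stopf("unknown color space '%s'; valid names: %s",
          space, paste(.SPACES, collapse = ", "))
  .SPACES[hit]
}

#' Normalized-RGB chromaticities
#'
#' Divides each channel by `R+G+B`; the black pixel maps to `(1/3, 1/3, 1/3)`
#' (the achromatic limit), so the planes always sum to exactly 1.
#'
#' @param rgb An `n x 3` matrix of RGB rows in `[0, 1]`.
#' @return An `n x 3` matrix of chromaticities.
#' @export
rgb_chromaticity <- function(rgb) {
  s <- rgb[, 1] + rgb[, 2] + rgb[, 3]
  zero <- s == 0
  s[zero] <- 1
  out <- rgb / s
  out[zero, ] <- 1 / 3
  colnames(out) <- c("R", "G", "B")
  out
}

# per-space implementations; input n x 3 matrix, output n x k named matrix
transform_rows <- function(rgb, space, chroma_center = 0.5) {
  space <- match_space(space)
  R <- rgb[, 1]; G <- rgb[, 2]; B <- rgb[, 3]
  Y601 <- .luma601(R, G, B)
  out <- switch(space,
    RGB = rgb,
    nRGB = rgb_chromaticity(rgb),
    HSI = {
      I <- (R + G + B) / 3
      mn <- pmin(R, G, B)
      S <- ifelse(I > 0, 1 - mn / I, 0)
      num <- 0.5 * ((R - G) + (R - B))
      den <- sqrt((R - G)^2 + (R - B) * (G - B))
      theta <- acos(pmin(1, pmax(-1, ifelse(den > 0, num / den, 1))))
      H <- ifelse(den > 0, ifelse(B <= G, theta, 2 * pi - theta) / (2 * pi), 0)
      cbind(H, S, I)
    },
    HSV = {
      V <- pmax(R, G, B)
      mn <- pmin(R, G, B)
      d <- V - mn
      S <- ifelse(V > 0, d / V, 0)
      H <- numeric(length(V))
      nz <- d > 0
      hr <- nz & V == R
      hg <- nz & V == G & !hr
      hb <- nz & !hr & !hg
      H[hr] <- ((G[hr] - B[hr]) / d[hr]) %% 6
      H[hg] <- (B[hg] - R[hg]) / d[hg] + 2
      H[hb] <- (R[hb] - G[hb]) / d[hb] + 4
      cbind(H = H / 6, S = S, V = V)
    },
    XYZ = xyz_rows(R, G, B),
    LAB = {
      xyz <- xyz_rows(R, G, B)
      fx <- lab_f(xyz[, 1] / 0.95047)
      fy <- lab_f(xyz[, 2])
      fz <- lab_f(xyz[, 3] / 1.08883)
      cbind(L = 116 * fy - 16, A = 500 * (fx - fy), B = 200 * (fy - fz))
    },
    LUV = {
      xyz <- xyz_rows(R, G, B)
      L <- 116 * lab_f(xyz[, 2]) - 16
      den <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
      up <- ifelse(den > 0, 4 * xyz[, 1] / den, 0)
      vp <- ifelse(den > 0, 9 * xyz[, 2] / den, 0)
      upn <- 4 * 0.95047 / (0.95047 + 15 + 3 * 1.08883)
      vpn <- 9 / (0.95047 + 15 + 3 * 1.08883)
      cbind(L = L, U = 13 * L * (up - upn), V = 13 * L * (vp - vpn))
    },
    TSL = {
      chr <- rgb_chromaticity(rgb)
      rp <- chr[, 1] - 1 / 3
      gp <- chr[, 2] - 1 / 3
      T <- ifelse(gp > 0, atan(rp / gp) / (2 * pi) + 0.25,
             ifelse(gp < 0, atan(rp / gp) / (2 * pi) + 0.75, 0))
      cbind(T = T, S = sqrt(9 / 5 * (rp^2 + gp^2)), L = Y601)
    },
    YCbCr = cbind(Y = Y601,
                  CB = chroma_center + 0.5 / (1 - 0.114) * (B - Y601),
                  CR = chroma_center + 0.5 / (1 - 0.299) * (R - Y601)),
    YCgCr = cbind(Y = Y601,
                  CG = chroma_center + 0.5 / (1 - 0.587) * (G - Y601),
                  CR = chroma_center + 0.5 / (1 - 0.299) * (R - Y601)),
    YES = cbind(Y = 0.253 * R + 0.684 * G + 0.063 * B,
                E = 0.5 * (R - G),
                S = 0.25 * (R + G) - 0.5 * B),
    YIQ = cbind(Y = Y601,
                I = chroma_center + 0.595716 * R - 0.274453 * G - 0.321263 * B,
                Q = chroma_center + 0.211456 * R - 0.522591 * G + 0.311135 * B),
    YPbPr = cbind(Y = Y601,
                  PB = chroma_center - 0.168736 * R - 0.331264 * G + 0.5 * B,
                  PR = chroma_center + 0.5 * R - 0.418688 * G - 0.081312 * B),
    YUV = cbind(Y = Y601,
                U = chroma_center + 0.492 * (B - Y601),
                V = chroma_center + 0.877 * (R - Y601)),
    i1i2i3 = cbind(i1 = (R + G + B) / 3,
                   i2 = (R - B) / 2,
                   i3 = (2 * G - R - B) / 4),
    RIQ = {
      yiq <- transform_rows(rgb, "YIQ", chroma_center)
      cbind(R = R, I = yiq[, "I"], Q = yiq[, "Q"])
    },
    YQCr = {
      yiq <- transform_rows(rgb, "YIQ", chroma_center)
      ycc <- transform_rows(rgb, "YCbCr", chroma_center)
      cbind(Y = Y601, Q = yiq[, "Q"], CR = ycc[, "CR"])
    })
  colnames(out) <- space_components(space)
  out
}

xyz_rows <- function(R, G, B) {
  cbind(X = 0.4124564 * R + 0.3575761 * G + 0.1804375 * B,
        Y = 0.2126729 * R + 0.7151522 * G + 0.0721750 * B,
        Z = 0.0193339 * R + 0.1191920 * G + 0.9503041 * B)
}

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' Transform an RGB image to another color space
#'
#' @param image An `H x W x 3` array with channels in `[0, 1]` (see
#'   [read_image()]), channel order R, G, B.
#' @param space One of [color_spaces()]; matching is case-insensitive.
#' @param chroma_center Offset added to the chroma planes of the YCbCr /
#'   YCgCr / YUV / YIQ / YPbPr dialects (default 0.5, full-range chroma).
#' @return An `H x W x k` array, one plane per component of the target
#'   space, named along the third dimension.
#' @examples
#' img <- array(runif(2 * 2 * 3), c(2, 2, 3))
#' dim(color_transform(img, "YCbCr"))
#' @export
color_transform <- function(image, space, chroma_center = 0.5) {
  check_rgb_image(image)
  space <- match_space(space)
  rows <- transform_rows(planes_to_rows(image), space, chroma_center)
  rows_to_planes(rows, dim(image)[1], dim(image)[2])
}

#' Normalized-RGB image transform
#'
#' Convenience wrapper over [rgb_chromaticity()]: the three output planes sum
#' to 1 at every pixel, including black pixels (mapped to 1/3 each).
#'
#' @inheritParams color_transform
#' @return An `H x W x 3` array of r, g, b chromaticity planes.
#' @export
to_normalized_rgb <- function(image) {
  check_rgb_image(image)
  rows_to_planes(rgb_chromaticity(planes_to_rows(image)),
                 dim(image)[1], dim(image)[2])
}
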