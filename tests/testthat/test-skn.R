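test_that("SKN anchor pixels match direct arithmetic evaluation", {
  expect_equal(unname(rgb_to_skn(c(0, 0, 0))),
               c(-7.2107, 1.9507, -0.3500), tolerance = 1e-4)
  expect_equal(unname(rgb_to_skn(c(1, 1, 1))),
               c(-108.0667, 25.8527, -6.4010), tolerance = 1e-4)
  expect_equal(unname(rgb_to_skn(c(0, 1, 0))),
               c(-66.0420, 17.2230, -3.8200), tolerance = 1e-4)
})

test_that("vectorized image path matches the scalar reference", {
  set.seed(11)
  rgb <- matrix(runif(300), ncol = 3)
  vec <- rgb_to_skn(rgb)
  ref <- t(apply(rgb, 1, function(p) ref_skn_pixel(p[1], p[2], p[3])))
  expect_lt(max(abs(vec - ref)), 1e-12)

  img <- array(0, c(10, 10, 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], 10, 10, byrow = TRUE)
  planes <- rgb_image_to_skn(img)
  expect_equal(sknspace:::planes_to_rows(planes), vec)
})

test_that("1x1 black image and constant images behave pixel-wise", {
  black <- rgb_image_to_skn(array(0, c(1, 1, 3)))
  expect_equal(as.vector(black), c(-7.2107, 1.9507, -0.3500),
               tolerance = 1e-4)
  const <- rgb_image_to_skn(array(rep(c(0.3, 0.6, 0.2), each = 12),
                                  c(3, 4, 3)))
  for (p in 1:3) expect_equal(var(as.vector(const[, , p])), 0)
})

test_that("out-of-range input is rejected", {
  expect_error(rgb_to_skn(c(1.2, 0, 0)), "\\[0, 1\\]")
  expect_error(rgb_to_skn(c(-0.1, 0.5, 0.5)), "\\[0, 1\\]")
})

test_that("pixel independence: permuting pixels permutes outputs", {
  set.seed(2)
  rgb <- matrix(runif(150), ncol = 3)
  perm <- sample(nrow(rgb))
  expect_equal(rgb_to_skn(rgb)[perm, ], rgb_to_skn(rgb[perm, ]))
})

test_that("each SKN coordinate is affine in RGB at fixed chromaticity", {
  # scaling (R,G,B) jointly keeps g fixed; finite differences must be linear
  base <- c(0.2, 0.3, 0.1)
  f <- function(t) rgb_to_skn(t * base)
  d1 <- f(0.6) - f(0.4)
  d2 <- f(0.8) - f(0.6)
  expect_equal(unname(d1), unname(d2), tolerance = 1e-9)
})

test_that("rgb_to_skn equals the hybrid-space composition", {
  set.seed(9)
  img <- array(runif(12 * 5 * 3), c(12, 5, 3))
  direct <- rgb_image_to_skn(img)
  via_space <- apply_hybrid(skn_space(), img)
  expect_lt(max(abs(direct - via_space)), 1e-9)
})

test_that("apply_hybrid handles identity and one-hot loadings", {
  img <- toy_image(3, 4)
  idspace <- hybrid_space(c("R_RGB", "G_RGB", "B_RGB"), means = rep(0, 3),
                          loadings = diag(3), names = c("R", "G", "B"))
  expect_equal(unname(apply_hybrid(idspace, img)), unname(img))

  onehot <- hybrid_space(c("R_RGB", "G_RGB", "B_RGB"), means = c(0.25, 0, 0),
                         loadings = matrix(c(1, 0, 0), 1), names = "R")
  expect_equal(apply_hybrid(onehot, img)[, , 1], img[, , 1] - 0.25)
})

test_that("apply_hybrid matches a per-pixel dot-product oracle", {
  set.seed(4)
  ids <- component_registry()$id[c(1, 5, 9, 12, 17, 20, 25, 30)]
  L <- matrix(rnorm(24), 3, 8)
  mu <- rnorm(8)
  space <- hybrid_space(ids, mu, L)
  img <- toy_image(6, 6, seed = 13)
  got <- apply_hybrid(space, img)
  reg <- component_registry()
  comp <- sknspace:::registry_values(sknspace:::planes_to_rows(img), reg)
  for (q in c(1, 17, 36)) {  # spot-check pixels with an explicit loop
    x <- comp[q, ids]
    want <- numeric(3)
    for (k in 1:3) {
      acc <- 0
      for (j in 1:8) acc <- acc + L[k, j] * (x[j] - mu[j])
      want[k] <- acc
    }
    r <- (q - 1) %/% 6 + 1; cidx <- (q - 1) %% 6 + 1
    expect_lt(max(abs(got[r, cidx, ] - want)), 1e-9)
  }
})

test_that("unresolvable component ids are rejected", {
  sp <- hybrid_space("NOPE_SPACE", 0, matrix(1, 1, 1))
  expect_error(apply_hybrid(sp, toy_image()), "NOPE_SPACE")
})

test_that("PCA-derived spaces pass the unit-norm check; SKN does not", {
  set.seed(1)
  model <- fit_pca(matrix(rnorm(200), 50, 4))
  expect_true(validate_unit_loadings(make_space(model, 2)))
  expect_error(validate_unit_loadings(skn_space()), "norm")
})
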