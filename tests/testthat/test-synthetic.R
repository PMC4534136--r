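test_that("scenes are bit-identical under a fixed config", {
  cfg <- scene_config(height = 32, width = 32, seed = 21)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a, b)
  d <- generate_scene(scene_config(height = 32, width = 32, seed = 22))
  expect_false(identical(a$image, d$image))
})

test_that("zero regions yield an all-zero mask", {
  sc <- generate_scene(scene_config(height = 32, width = 32, n_regions = 0,
                                    seed = 1))
  expect_true(all(sc$mask == 0L))
  expect_equal(dim(sc$image), c(32L, 32L, 3L))
})

test_that("achieved skin fraction tracks the target across seeds", {
  fr <- vapply(1:20, function(s)
    mean(generate_scene(scene_config(seed = s))$mask), numeric(1))
  expect_true(all(abs(fr - 0.25) <= 0.1))
  expect_lt(abs(mean(fr) - 0.25), 0.1)
})

test_that("masked pixels carry skin-cluster chroma, background does not", {
  cfg <- scene_config(height = 48, width = 48, seed = 30)
  sc <- generate_scene(cfg)
  rows <- sknspace:::planes_to_rows(sc$image)
  ycc <- sknspace:::transform_rows(rows, "YCbCr")
  lab <- as.vector(t(sc$mask)) == 1L
  mu <- cfg$skin_chroma$mean
  dist <- sqrt((ycc[, "CB"] - mu[1])^2 + (ycc[, "CR"] - mu[2])^2)
  expect_gt(mean(dist[lab] < 0.1), 0.95)   # skin lies in the cluster
  expect_gt(mean(dist[!lab] > 0.1), 0.95)  # textured background avoids it
})

test_that("background modes differ and distractors approach the cluster", {
  mk <- function(mode) generate_scene(
    scene_config(height = 48, width = 48, background_mode = mode,
                 seed = 33))
  tex <- mk("textured"); noise <- mk("uniform_noise")
  dis <- mk("skin_like_distractor")
  expect_false(identical(tex$image, noise$image))
  ch <- function(sc) {
    rows <- sknspace:::planes_to_rows(sc$image)
    bg <- as.vector(t(sc$mask)) == 0L
    ycc <- sknspace:::transform_rows(rows, "YCbCr")[bg, ]
    mu <- scene_config()$skin_chroma$mean
    mean(sqrt((ycc[, "CB"] - mu[1])^2 + (ycc[, "CR"] - mu[2])^2) < 0.1)
  }
  expect_gt(ch(dis), ch(tex))  # distractor background has skin-like pixels
})

test_that("datasets land on disk with a usable manifest", {
  out <- withr::local_tempdir()
  cfg <- scene_config(height = 24, width = 24)
  man <- generate_dataset(10, cfg, out, seed = 5)
  expect_equal(nrow(man), 10L)
  expect_true(all(file.exists(man$image)))
  expect_true(all(file.exists(man$mask)))
  reread <- read_manifest(file.path(out, "manifest.csv"))
  expect_equal(nrow(reread), 10L)
  # 75/25 split arithmetic under round-half-up
  split <- split_manifest(man, 0.75, seed = 1)
  expect_equal(sum(split$split == "train"), 8L)
  expect_equal(sum(split$split == "test"), 2L)
  # regeneration matches the files (per-image derived seeds, order-free)
  cfg2 <- cfg
  cfg2$seed <- sknspace:::derive_seed(5, "scene3")
  sc3 <- generate_scene(cfg2)
  expect_lt(max(abs(read_image(man$image[3]) - sc3$image)), 1 / 254)
  expect_identical(read_mask(man$mask[3]), sc3$mask)
})

test_that("different master seeds give different datasets", {
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  cfg <- scene_config(height = 16, width = 16)
  m1 <- generate_dataset(2, cfg, o1, seed = 1)
  m2 <- generate_dataset(2, cfg, o2, seed = 2)
  expect_false(identical(read_image(m1$image[1]), read_image(m2$image[1])))
})

test_that("planted matrices respect their construction", {
  pm <- planted_matrix(planted_config(n = 1000, informative = 2L,
                                      separation = 6, seed = 8))
  expect_equal(ncol(pm$values), 32L)
  # a depth-1 threshold on the informative column separates almost perfectly
  thr <- 3
  acc <- mean((pm$values[, 2] > thr) == (pm$labels == 1L))
  expect_gte(acc, 0.99)
  # null construction: no column separates
  null <- planted_matrix(planted_config(n = 1000, informative = integer(0),
                                        separation = 0, seed = 9))
  accs <- apply(null$values, 2, function(v)
    max(mean((v > median(v)) == (null$labels == 1L)),
        mean((v <= median(v)) == (null$labels == 1L))))
  expect_lt(max(accs), 0.6)
})

test_that("scene config validation rejects bad worlds", {
  expect_error(scene_config(height = 8), ">= 16")
  expect_error(scene_config(skin_fraction_target = 0.95), "0, 0.9")
  # 20 tiny random ellipses cannot cover 89% of a small canvas
  infeasible <- scene_config(height = 16, width = 16, n_regions = 20,
                             skin_fraction_target = 0.89, seed = 1)
  expect_error(generate_scene(infeasible), "fraction")
})
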