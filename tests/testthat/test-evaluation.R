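mk <- function(v, h = 3, w = 3) matrix(as.integer(v), h, w, byrow = TRUE)

test_that("confusion counts partition the pixels", {
  truth <- mk(c(1, 1, 1, 1, 1, 0, 0, 0, 0))
  pred <- mk(c(1, 1, 1, 1, 0, 1, 1, 0, 0))
  cc <- confusion(pred, truth)
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 4, FN = 1, FP = 2, TN = 2))
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 9)

  same <- confusion(truth, truth)
  expect_equal(same$FP + same$FN, 0)
  comp <- confusion(mk(1 - c(1, 1, 1, 1, 1, 0, 0, 0, 0)), truth)
  expect_equal(comp$TP + comp$TN, 0)
  expect_error(confusion(mk(rep(0, 9)), matrix(0L, 2, 2)), "differ")
})

test_that("pixel-count conservation holds for random mask pairs", {
  set.seed(14)
  for (i in 1:1000) {
    h <- sample(1:6, 1); w <- sample(1:6, 1)
    a <- matrix(sample(0:1, h * w, TRUE), h, w)
    b <- matrix(sample(0:1, h * w, TRUE), h, w)
    cc <- confusion(a, b)
    if (cc$TP + cc$FP + cc$FN + cc$TN != h * w)
      fail(sprintf("conservation violated at iteration %d", i))
  }
  succeed()
})

test_that("metric formulas reproduce hand-computed examples exactly", {
  m1 <- metrics(list(TP = 90, FN = 10, FP = 0, TN = 0))
  expect_equal(m1$TPR, 0.9)
  m2 <- metrics(list(TP = 0, FN = 0, FP = 5, TN = 45))
  expect_equal(m2$FPR, 0.1)
  m3 <- metrics(list(TP = 8, FP = 2, FN = 2, TN = 0))
  expect_equal(m3$f_score, 0.8)
  expect_equal(m3$precision, 0.8)
  # zero-denominator policy
  m4 <- metrics(list(TP = 0, FP = 0, FN = 3, TN = 7))
  expect_equal(m4$precision, 0)
  m5 <- metrics(list(TP = 0, FP = 2, FN = 0, TN = 8))
  expect_true(is.na(m5$TPR))
})

test_that("F-score equals the harmonic mean of precision and recall", {
  set.seed(15)
  for (i in 1:200) {
    cc <- as.list(rmultinom(1, 100, rep(0.25, 4))[, 1])
    names(cc) <- c("TP", "FP", "FN", "TN")
    m <- metrics(cc)
    if (!is.na(m$TPR) && (m$precision + m$TPR) > 0) {
      hm <- 2 * m$precision * m$TPR / (m$precision + m$TPR)
      expect_equal(m$f_score, hm, tolerance = 1e-12)
    }
  }
})

test_that("per-image averaging is the unweighted arithmetic mean", {
  a <- metrics(list(TP = 8, FP = 2, FN = 2, TN = 88))
  b <- metrics(list(TP = 10, FP = 0, FN = 0, TN = 90))
  avg <- average_over_images(list(a, b))
  expect_equal(avg$TPR, (a$TPR + b$TPR) / 2, tolerance = 1e-12)
  expect_equal(avg$f_score, (a$f_score + b$f_score) / 2, tolerance = 1e-12)
  expect_equal(average_over_images(list(a, a, a))$precision, a$precision)
  # degenerate images are excluded, not fabricated
  noskin <- metrics(list(TP = 0, FP = 1, FN = 0, TN = 9))
  avg2 <- average_over_images(list(a, noskin))
  expect_equal(avg2$TPR, a$TPR)
  expect_equal(attr(avg2, "n_used")[["TPR"]], 1L)
  expect_error(average_over_images(list()), "non-empty")
})

test_that("ROC sanity: perfect, constant and inverted scorers", {
  # build masks/posteriors directly and exercise the threshold sweep via
  # the internal trapezoid + a hand loop equivalent to roc_curve's core
  set.seed(16)
  truth <- matrix(sample(0:1, 400, TRUE), 20, 20)
  thresholds <- seq(1, 0, length.out = 50)
  sweep_auc <- function(post) {
    tpr <- fpr <- numeric(50)
    for (t in seq_along(thresholds)) {
      hit <- post >= thresholds[t]
      tpr[t] <- sum(hit & truth == 1) / sum(truth == 1)
      fpr[t] <- sum(hit & truth == 0) / sum(truth == 0)
    }
    sknspace:::trapezoid_auc(fpr, tpr)
  }
  perfect <- ifelse(truth == 1, 0.9, 0.1)
  expect_equal(sweep_auc(perfect), 1.0)
  constant <- matrix(0.4, 20, 20)
  expect_equal(sweep_auc(constant), 0.5)
  flipped <- 1 - perfect
  expect_lte(sweep_auc(flipped), 0.05)
  # complement identity
  set.seed(17)
  s <- matrix(runif(400), 20, 20)
  expect_equal(sweep_auc(s) + sweep_auc(1 - s), 1, tolerance = 1e-9)
})

test_that("roc_curve on a trained model is monotone with sane AUC", {
  pairs <- lapply(1:3, function(s) toy_pair(seed = s))
  tr <- sknspace:::training_rows(pairs[1:2], "skn", 3000, seed = 1)
  m <- train_classifier(classifier_spec("random_forest", seed = 1),
                        tr$X, tr$y)
  roc <- roc_curve(m, pairs[3], "skn")
  expect_length(roc$thresholds, 50L)
  expect_equal(roc$thresholds[c(1, 50)], c(1, 0))
  expect_false(is.unsorted(roc$tpr))
  expect_false(is.unsorted(roc$fpr))
  expect_gte(roc$auc, 0.95)  # separable scenes
  expect_lte(roc$auc, 1)
  expect_error(roc_curve(m, list(), "skn"), "empty")
})

test_that("error overlays follow the documented color coding", {
  img <- toy_image(2, 2, seed = 18)
  truth <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  pred <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  out <- annotate_errors(img, pred, truth)
  expect_equal(out[1, 1, ], img[1, 1, ])      # TP keeps color
  expect_equal(out[2, 1, ], c(1, 0, 0))       # FN red
  expect_equal(out[1, 2, ], c(0, 0, 1))       # FP blue
  expect_equal(out[2, 2, ], c(1, 1, 1))       # TN white
  # all-skin, perfect prediction: untouched image
  ones <- matrix(1L, 2, 2)
  expect_equal(annotate_errors(img, ones, ones), img)
  # all-missed: fully red
  allred <- annotate_errors(img, matrix(0L, 2, 2), ones)
  expect_true(all(allred[, , 1] == 1) && all(allred[, , 2:3] == 0))
})
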