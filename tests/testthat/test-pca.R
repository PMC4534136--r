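test_that("centering subtracts column means and records them", {
  ctr <- center_matrix(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(unname(ctr$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(ctr$values[, 2]), c(0, 0, 0))
  expect_equal(unname(ctr$column_means), c(2, 5))
  expect_error(center_matrix(matrix(1, 1, 2)), "at least 2 rows")
})

test_that("centered column sums vanish on random matrices", {
  set.seed(8)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 6), 40, 6)
    ctr <- center_matrix(x)
    expect_lt(max(abs(colSums(ctr$values))), 1e-6 * nrow(x))
  }
})

test_that("covariance uses the n-1 denominator", {
  x <- cbind(x = c(1, 2, 3), y = c(2, 4, 6))
  cov <- covariance_matrix(center_matrix(x))
  expect_equal(unname(cov), rbind(c(1, 2), c(2, 4)))
  expect_equal(unname(covariance_matrix(center_matrix(cbind(c(1, 2, 3))))),
               matrix(1, 1, 1))
  # symmetry on random input
  set.seed(2)
  cc <- covariance_matrix(center_matrix(matrix(rnorm(100), 20, 5)))
  expect_equal(cc, t(cc))
})

test_that("eigendecomposition matches hand-solved spectra", {
  m3 <- eigendecompose(diag(3))
  expect_equal(m3$eigenvalues, rep(1, 3))

  m2 <- eigendecompose(diag(c(4, 1)))
  expect_equal(m2$eigenvalues, c(4, 1))
  expect_equal(abs(m2$eigenvectors), diag(2))

  # characteristic polynomial of [[1,2],[2,4]]: lambda^2 - 5 lambda = 0
  r1 <- eigendecompose(rbind(c(1, 2), c(2, 4)))
  expect_equal(r1$eigenvalues, c(5, 0), tolerance = 1e-9)
  expect_error(eigendecompose(rbind(c(1, 2), c(0, 1))), "symmetric")
})

test_that("eigenvalues match characteristic-polynomial roots (oracle)", {
  set.seed(21)
  for (i in 1:10) {
    d <- sample(2:3, 1)
    A <- matrix(rnorm(d * d), d)
    cov <- crossprod(A)  # random SPD
    model <- eigendecompose(cov)
    # oracle: roots of the explicitly expanded characteristic polynomial
    roots <- if (d == 2) {
      tr <- cov[1, 1] + cov[2, 2]
      det2 <- cov[1, 1] * cov[2, 2] - cov[1, 2] * cov[2, 1]
      sort(Re(polyroot(c(det2, -tr, 1))), decreasing = TRUE)
    } else {
      c0 <- -det(cov)
      c1 <- (cov[1, 1] * cov[2, 2] - cov[1, 2]^2) +
        (cov[1, 1] * cov[3, 3] - cov[1, 3]^2) +
        (cov[2, 2] * cov[3, 3] - cov[2, 3]^2)
      c2 <- -(cov[1, 1] + cov[2, 2] + cov[3, 3])
      sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
    }
    expect_equal(model$eigenvalues, roots, tolerance = 1e-6)
    # residual and normalization
    for (j in seq_len(d)) {
      v <- model$eigenvectors[, j]
      expect_lt(max(abs(cov %*% v - model$eigenvalues[j] * v)), 1e-8)
      expect_equal(sum(v^2), 1)
    }
    # variance conservation
    expect_lt(abs(sum(model$eigenvalues) - sum(diag(cov))),
              1e-6 * sum(diag(cov)))
  }
})

test_that("sign convention makes the largest-magnitude entry positive", {
  set.seed(5)
  cov <- crossprod(matrix(rnorm(25), 5))
  model <- eigendecompose(cov)
  for (j in 1:5)
    expect_gt(model$eigenvectors[which.max(abs(model$eigenvectors[, j])), j], 0)
})

test_that("explained_variance is a cumulative ratio with guarded edges", {
  model <- structure(list(eigenvalues = c(3, 1)), class = "pca_model")
  expect_equal(explained_variance(model, 1), 0.75)
  expect_equal(explained_variance(model, 2), 1)
  r1 <- eigendecompose(rbind(c(1, 2), c(2, 4)))
  expect_equal(explained_variance(r1, 1), 1)
  zero <- structure(list(eigenvalues = c(0, 0)), class = "pca_model")
  expect_equal(explained_variance(zero, 1), 0)
  expect_error(explained_variance(model, 3), "k must be")
  expect_error(explained_variance(model, 0), "k must be")
})

test_that("explained_variance is non-decreasing and ends at 1", {
  set.seed(6)
  model <- fit_pca(matrix(rnorm(400), 50, 8))
  ev <- vapply(1:8, function(k) explained_variance(model, k), numeric(1))
  expect_false(is.unsorted(ev))
  expect_equal(ev[8], 1)
})

test_that("full-rank make_space reconstructs the centered data", {
  set.seed(7)
  x <- matrix(rnorm(200), 50, 4)
  colnames(x) <- c("R_RGB", "G_RGB", "B_RGB", "G_nRGB")
  model <- fit_pca(x)
  space <- make_space(model, k = 4)
  scores <- sweep(x, 2, model$column_means) %*% t(space$loadings)
  recon <- scores %*% space$loadings
  expect_lt(max(abs(recon - sweep(x, 2, model$column_means))), 1e-8)
  # projected columns are uncorrelated
  sc_cov <- covariance_matrix(center_matrix(scores))
  off <- sc_cov - diag(diag(sc_cov))
  expect_lt(max(abs(off)), 1e-6 * max(model$eigenvalues))
})

test_that("rank-1 data is fully captured by one component", {
  set.seed(9)
  u <- rnorm(30)
  x <- cbind(u, 2 * u, -u)
  model <- fit_pca(x)
  expect_equal(explained_variance(model, 1), 1, tolerance = 1e-9)
})

test_that("make_space defaults to three loading rows", {
  set.seed(10)
  model <- fit_pca(matrix(rnorm(50 * 8), 50, 8))
  expect_equal(nrow(make_space(model)$loadings), 3L)
  expect_equal(make_space(model)$names, c("PC1", "PC2", "PC3"))
})
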