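#' Pixel classifiers
#'
#' Four pluggable pixel classifiers produce skin posteriors from a small
#' number of color-space features: a random forest (15 trees by default,
#' bootstrap bagging, Gini trees with sqrt(k) features per split), a naive
#' Bayes with per-feature kernel-smoothed densities (skin color is not
#' Gaussian), a polynomial-kernel SVM (degree up to 3, complexity C = 1,
#' tolerance 0.001, round-off epsilon 1e-12) with optional Platt-calibrated
#' posteriors, and a five-layer perceptron (input, three hidden layers whose
#' width is the rounded mean of input and output sizes, and a two-class
#' output layer).
#'
#' @name skin-classifiers
NULL

.CLASSIFIER_KINDS <- c("random_forest", "naive_bayes", "svm", "mlp")

classifier_defaults <- function(kind) {
  switch(kind,
    random_forest = list(ntree = 15L, mtry = NULL, max_depth = 0L,
                         min_node = 1L, nbins = 64L),
    naive_bayes = list(max_per_class = 5000L, grid_n = 512L),
    svm = list(degree = 3L, cost = 1, tol = 1e-3, eps = 1e-12,
               max_per_class = 500L, calibrate = TRUE),
    mlp = list(hidden_width = NULL, n_hidden = 3L, epochs = 300L,
               learn_rate = 0.01, max_train = 20000L,
               val_fraction = 0.15, patience = 30L))
}

#' Describe a classifier configuration
#'
#' @param kind One of `"random_forest"`, `"naive_bayes"`, `"svm"`, `"mlp"`.
#' @param params Named list overriding the kind's defaults (see Details of
#'   [skin-classifiers]).
#' @param seed Integer seed controlling all stochastic parts of the fit.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = .CLASSIFIER_KINDS, params = list(),
                            seed = 1L) {
  kind <- match.arg(kind)
  defaults <- classifier_defaults(kind)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stopf("unknown %s parameter(s): %s", kind, paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(kind = kind, params = defaults, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a pixel classifier
#'
#' @param spec A [classifier_spec()].
#' @param features `n x k` numeric feature matrix.
#' @param labels Length-`n` 0/1 vector (1 = skin); both classes required.
#' @param feature_ids Identifiers of the feature columns; predictions are
#'   refused when ids differ from these (guards against silent column
#'   permutation). Defaults to `colnames(features)`.
#' @return A `skin_model`.
#' @export
train_classifier <- function(spec, features, labels,
                             feature_ids = colnames(features)) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (ncol(features) < 1L) stopf("need at least one feature column")
  if (length(labels) != nrow(features))
    stopf("labels must match feature rows")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stopf("training data must contain both classes")
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(features)))
  fit <- switch(spec$kind,
    random_forest = fit_rf(spec, features, labels),
    naive_bayes = fit_nb(spec, features, labels),
    svm = fit_svm(spec, features, labels),
    mlp = fit_mlp(spec, features, labels))
  structure(list(spec = spec, fit = fit, feature_ids = feature_ids),
            class = "skin_model")
}

#' @export
print.skin_model <- function(x, ...) {
  cat(sprintf("<skin_model> %s on features: %s\n", x$spec$kind,
              paste(x$feature_ids, collapse = ", ")))
  invisible(x)
}

#' Skin posterior probabilities
#'
#' @param model A `skin_model`.
#' @param features `n x k` feature matrix whose column names (when present)
#'   must equal the model's `feature_ids`, in order.
#' @return Numeric vector of posteriors in `[0, 1]`; for the random forest,
#'   the fraction of trees voting skin.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "skin_model"))
  features <- as.matrix(features)
  if (ncol(features) != length(model$feature_ids))
    stopf("expected %d features (%s)", length(model$feature_ids),
          paste(model$feature_ids, collapse = ", "))
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), model$feature_ids))
    stopf("feature ids mismatch: model was trained on (%s), got (%s)",
          paste(model$feature_ids, collapse = ", "),
          paste(colnames(features), collapse = ", "))
  switch(model$spec$kind,
    random_forest = .rf_vote_cpp(model$fit$forest, features),
    naive_bayes = predict_nb(model$fit, features),
    svm = predict_svm(model$fit, features),
    mlp = predict_mlp(model$fit, features))
}

#' Predict a binary skin mask for an image
#'
#' Transforms the image into the model's feature space and thresholds the
#' pixel posteriors.
#'
#' @param model A `skin_model`.
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param space A [hybrid_space()] or a color-space name from
#'   [color_spaces()]; must produce the features the model was trained on.
#' @param threshold Posterior threshold in `[0, 1]`; a pixel is skin when
#'   its posterior is `>= threshold`.
#' @return An `H x W` 0/1 integer matrix.
#' @export
predict_mask <- function(model, image, space, threshold = 0.5) {
  if (!is_prob(threshold)) stopf("threshold must be in [0, 1]")
  p <- posterior_map(model, image, space)
  matrix(as.integer(p >= threshold), nrow(p), ncol(p))
}

# H x W posterior matrix for an image under a feature space
posterior_map <- function(model, image, space) {
  check_rgb_image(image)
  rows <- space_feature_rows(planes_to_rows(image), space)
  p <- predict_proba(model, rows)
  matrix(p, dim(image)[1], dim(image)[2], byrow = TRUE)
}

# n x k named feature rows for RGB rows under a hybrid space or space name
space_feature_rows <- function(rgb_rows, space) {
  if (inherits(space, "hybrid_space")) {
    hybrid_feature_rows(space, rgb_rows)
  } else if (is.character(space) && length(space) == 1L &&
             toupper(space) %in% c("SKN", "skn")) {
    rgb_to_skn(rgb_rows)
  } else {
    sp <- match_space(space)
    out <- transform_rows(rgb_rows, sp)
    colnames(out) <- paste0(space_components(sp), "_", toupper(sp))
    out
  }
}

## ---- random forest ---------------------------------------------------

fit_rf <- function(spec, X, y) {
  p <- spec$params
  mtry <- p$mtry %||% max(1L, floor(sqrt(ncol(X))))
  forest <- .rf_fit_cpp(X, y, as.integer(p$ntree),
                        as.integer(min(mtry, ncol(X))),
                        as.integer(p$max_depth), as.integer(p$min_node),
                        as.integer(p$nbins), as.double(spec$seed))
  list(forest = forest, ntree = p$ntree)
}

## ---- kernel naive Bayes ----------------------------------------------

# Per class and feature, an FFT kernel density (Gaussian kernel, Silverman's
# rule) evaluated on a grid; prediction interpolates the grid in log space.
fit_nb <- function(spec, X, y) {
  p <- spec$params
  classes <- c(0L, 1L)
  dens <- vector("list", 2L)
  priors <- numeric(2L)
  with_seed(spec$seed, {
    for (ci in 1:2) {
      rows <- which(y == classes[ci])
      priors[ci] <- length(rows) / length(y)
      if (length(rows) > p$max_per_class)
        rows <- sample(rows, p$max_per_class)
      dens[[ci]] <- lapply(seq_len(ncol(X)), function(j) {
        v <- X[rows, j]
        if (stats::sd(v) == 0) v <- v + stats::rnorm(length(v), 0, 1e-9)
        d <- stats::density(v, bw = "nrd0", n = p$grid_n,
                            from = min(v) - 3 * stats::bw.nrd0(v),
                            to = max(v) + 3 * stats::bw.nrd0(v))
        list(x = d$x, y = pmax(d$y, 1e-12))
      })
    }
  })
  list(dens = dens, priors = priors)
}

predict_nb <- function(fit, X) {
  logp <- matrix(log(fit$priors), nrow(X), 2L, byrow = TRUE)
  for (ci in 1:2) {
    for (j in seq_len(ncol(X))) {
      d <- fit$dens[[ci]][[j]]
      f <- stats::approx(d$x, d$y, xout = X[, j], yleft = 1e-12,
                         yright = 1e-12)$y
      logp[, ci] <- logp[, ci] + log(f)
    }
  }
  m <- pmax(logp[, 1], logp[, 2])
  exp(logp[, 2] - m) / (exp(logp[, 1] - m) + exp(logp[, 2] - m))
}

## ---- polynomial-kernel SVM -------------------------------------------

# Soft-margin dual solved with quadprog on a stratified subsample
# (kernel matrices are dense; the cubic solver bounds the sample size).
# Features are standardized so the polynomial kernel is well-conditioned.
poly_kernel <- function(A, B, degree) (tcrossprod(A, B) + 1)^degree

fit_svm <- function(spec, X, y) {
  p <- spec$params
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  with_seed(spec$seed, {
    keep <- unlist(lapply(c(0L, 1L), function(cl) {
      rows <- which(y == cl)
      if (length(rows) > p$max_per_class) sample(rows, p$max_per_class)
      else rows
    }))
    keep <- sort(keep)
    calib_rows <- integer(0)
    if (isTRUE(p$calibrate) && length(keep) >= 40) {
      calib_rows <- unlist(lapply(c(0L, 1L), function(cl) {
        rows <- keep[y[keep] == cl]
        sample(rows, max(5L, round(0.25 * length(rows))))
      }))
      keep <- setdiff(keep, calib_rows)
    }
  })
  Xtr <- Xs[keep, , drop = FALSE]
  ytr <- ifelse(y[keep] == 1L, 1, -1)
  n <- length(ytr)
  K <- poly_kernel(Xtr, Xtr, p$degree)
  D <- (ytr %o% ytr) * K
  D <- D + diag(p$eps * max(1, max(abs(diag(D)))) + 1e-8, n)
  A <- cbind(ytr, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-p$cost, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), p$cost)
  sv <- alpha > p$tol * p$cost
  margin <- sv & alpha < p$cost * (1 - p$tol)
  f_tr <- drop(K %*% (alpha * ytr))
  b <- if (any(margin)) mean(ytr[margin] - f_tr[margin]) else
    mean(ytr[sv] - f_tr[sv])
  fit <- list(X = Xtr[sv, , drop = FALSE], coef = (alpha * ytr)[sv], b = b,
              degree = p$degree, center = ctr, scale = scl,
              platt = c(-1.5, 0))
  if (length(calib_rows) >= 10 && length(unique(y[calib_rows])) == 2L) {
    f_cal <- svm_decision(fit, X[calib_rows, , drop = FALSE])
    # separable calibration folds legitimately drive the logistic fit to
    # its bounds; the clipped coefficients are still a usable sigmoid
    cal <- suppressWarnings(
      stats::glm(y[calib_rows] ~ f_cal, family = stats::binomial()))
    co <- stats::coef(cal)
    if (all(is.finite(co))) fit$platt <- c(co[2], co[1])
  }
  fit
}

svm_decision <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$center), 2, fit$scale, "/")
  drop(poly_kernel(Xs, fit$X, fit$degree) %*% fit$coef) + fit$b
}

predict_svm <- function(fit, X) {
  f <- svm_decision(fit, X)
  stats::plogis(fit$platt[1] * f + fit$platt[2])
}

## ---- multilayer perceptron -------------------------------------------

# Five layers: input(k) -> three tanh hidden layers -> softmax(2). Hidden
# width defaults to round((k + 2) / 2), the rounded-up mean of input and
# output sizes. Full-batch Adam with early stopping on validation loss.
fit_mlp <- function(spec, X, y) {
  p <- spec$params
  k <- ncol(X)
  h <- p$hidden_width %||% max(2L, floor((k + 2) / 2 + 0.5))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  with_seed(spec$seed, {
    if (nrow(Xs) > p$max_train) {
      keep <- stratified_sample(y, p$max_train)
      Xs <- Xs[keep, , drop = FALSE]
      y <- y[keep]
    }
    n <- nrow(Xs)
    val <- sample(n, max(2L, round(p$val_fraction * n)))
    sizes <- c(k, rep(h, p$n_hidden), 2L)
    W <- lapply(seq_len(length(sizes) - 1L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                          sd = sqrt(2 / (sizes[l] + sizes[l + 1L]))),
             sizes[l], sizes[l + 1L]))
    B <- lapply(sizes[-1], function(s) rep(0, s))
    fit <- train_mlp_loop(Xs, y, val, W, B, p)
    fit$center <- ctr
    fit$scale <- scl
    fit
  })
}

mlp_forward <- function(X, W, B) {
  acts <- list(X)
  L <- length(W)
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% W[[l]], 2, B[[l]], "+")
    acts[[l + 1L]] <- if (l < L) tanh(z) else z
  }
  z <- acts[[L + 1L]]
  m <- pmax(z[, 1], z[, 2])
  p1 <- exp(z[, 2] - m) / (exp(z[, 1] - m) + exp(z[, 2] - m))
  list(acts = acts, p1 = p1)
}

train_mlp_loop <- function(Xs, y, val, W, B, p) {
  n <- nrow(Xs)
  tr <- setdiff(seq_len(n), val)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(B, function(b) b * 0); vB <- mB
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  best <- list(W = W, B = B, loss = Inf)
  stall <- 0L
  for (epoch in seq_len(p$epochs)) {
    fw <- mlp_forward(Xs[tr, , drop = FALSE], W, B)
    # softmax cross-entropy gradient at the output layer
    delta <- cbind(1 - fw$p1, fw$p1)
    delta[cbind(seq_along(tr), y[tr] + 1L)] <-
      delta[cbind(seq_along(tr), y[tr] + 1L)] - 1
    delta <- delta / length(tr)
    L <- length(W)
    for (l in rev(seq_len(L))) {
      gW <- crossprod(fw$acts[[l]], delta)
      gB <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(W[[l]])) * (1 - fw$acts[[l]]^2)
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
      vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
      corr1 <- 1 - b1^epoch; corr2 <- 1 - b2^epoch
      W[[l]] <- W[[l]] - p$learn_rate * (mW[[l]] / corr1) /
        (sqrt(vW[[l]] / corr2) + epsa)
      B[[l]] <- B[[l]] - p$learn_rate * (mB[[l]] / corr1) /
        (sqrt(vB[[l]] / corr2) + epsa)
    }
    pv <- mlp_forward(Xs[val, , drop = FALSE], W, B)$p1
    pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
    loss <- -mean(ifelse(y[val] == 1L, log(pv), log(1 - pv)))
    if (loss < best$loss - 1e-6) {
      best <- list(W = W, B = B, loss = loss)
      stall <- 0L
    } else if ((stall <- stall + 1L) >= p$patience) break
  }
  list(W = best$W, B = best$B)
}

predict_mlp <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$center), 2, fit$scale, "/")
  mlp_forward(Xs, fit$W, fit$B)$p1
}

# Stratified subsample of at most `size` indices preserving class balance.
stratified_sample <- function(y, size) {
  idx0 <- which(y == 0L); idx1 <- which(y == 1L)
  n <- length(y)
  size <- as.numeric(size)  # avoid integer overflow in size * length
  k0 <- round(size * length(idx0) / n)
  k1 <- size - k0
  c(if (length(idx0) > k0) sample(idx0, k0) else idx0,
    if (length(idx1) > k1) sample(idx1, k1) else idx1)
}
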