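#' Pipeline orchestration
#'
#' Ties the stages together in their canonical order: scene/manifest
#' preparation, color transforms and feature-matrix construction, GA
#' component selection, PCA reduction to a hybrid space, classifier
#' training, and per-image evaluation. Every stage persists its artifact
#' (JSON/CSV where the artifact is portable), and a re-run with `resume =
#' TRUE` picks up from whatever is already on disk. All randomness flows
#' from one master seed through named substreams, so stages are
#' independently reproducible.
#'
#' @name pipeline
NULL

run_defaults <- function() {
  list(
    seed = 1L,
    log_level = "info",
    synth = list(n_images = 30L, height = 128L, width = 128L,
                 n_regions = 3L, background_mode = "textured",
                 skin_fraction_target = 0.25),
    split = list(train_fraction = 0.75),
    features = list(registry = "printed", max_pixels = 60000L),
    ga = list(population_size = 25L, mutation_prob = 0.035,
              crossover_prob = 0.55, max_generations = 500L,
              elite_fraction = 0.4, model_sample_fraction = 0.5,
              random_fraction = 0.2, cv_folds = 10L,
              fitness_subsample = 20000L, stall_window = 100L),
    pca = list(k = 3L),
    classifier = list(kind = "random_forest", params = list(),
                      max_train = 200000L),
    evaluation = list(threshold = 0.5, n_thresholds = 50L, roc = FALSE))
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s)%s: %s",
          if (nzchar(path)) paste0(" in ", path) else "",
          paste(unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         k != "params")
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "/"))
    else user[[k]]
  }
  defaults
}

#' Build a validated run configuration
#'
#' Unknown keys anywhere in the nested structure are rejected before any
#' computation. See `run_defaults()` in the package source for the full
#' default tree (sections: `synth`, `split`, `features`, `ga`, `pca`,
#' `classifier`, `evaluation`, plus global `seed` and `log_level`).
#'
#' @param config Named list of overrides (possibly nested), e.g. parsed
#'   from a YAML file.
#' @return The fully resolved configuration list.
#' @export
run_config <- function(config = list()) {
  merge_config(run_defaults(), config)
}

pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Tag manifest rows with a random train/test split
#'
#' The split is at image level (never pixel level). The train count is
#' `round(n * train_fraction)` (round half up); both sides must end up
#' non-empty.
#'
#' @param manifest Data frame with at least `image` and `mask` columns and
#'   two or more rows.
#' @param train_fraction Fraction of images tagged `train` (default 0.75).
#' @param seed Integer seed.
#' @return The manifest with a `split` column of `"train"`/`"test"` tags.
#' @export
split_manifest <- function(manifest, train_fraction = 0.75, seed = 1L) {
  n <- nrow(manifest)
  if (is.null(n) || n < 2L) stopf("manifest needs at least 2 rows to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stopf("train_fraction must lie strictly between 0 and 1")
  n_train <- floor(n * train_fraction + 0.5)
  if (n_train < 1L || n_train > n - 1L)
    stopf("split leaves an empty side (%d train of %d)", n_train, n)
  tags <- rep("test", n)
  tags[with_seed(derive_seed(seed, "split"), sample.int(n, n_train))] <- "train"
  manifest$split <- tags
  manifest
}

# per-image stratified pixel subsample of the registry feature matrix
sampled_features <- function(pairs, registry, max_pixels, seed) {
  per_image <- ceiling(max_pixels / length(pairs))
  blocks <- vector("list", length(pairs))
  labels <- vector("list", length(pairs))
  with_seed(derive_seed(seed, "features"), {
    for (i in seq_along(pairs)) {
      img <- pairs[[i]]$image
      msk <- pairs[[i]]$mask
      check_mask(msk, img, what = sprintf("mask of pair %d", i))
      rows <- planes_to_rows(img)
      lab <- as.integer(as.vector(t(msk)))
      if (length(lab) > per_image) {
        keep <- stratified_sample(lab, per_image)
        rows <- rows[keep, , drop = FALSE]
        lab <- lab[keep]
      }
      blocks[[i]] <- registry_values(rows, registry)
      labels[[i]] <- lab
    }
  })
  new_pixel_features(do.call(rbind, blocks), unlist(labels), registry$id)
}

#' Labelled classifier features for image/mask pairs under a space
#'
#' Transforms each pair's pixels into the feature space and concatenates
#' them with their 0/1 labels, optionally capping the total via a seeded
#' stratified subsample.
#'
#' @param pairs List of `list(image =, mask =)` pairs.
#' @param space A [hybrid_space()], `"skn"`, or a color-space name.
#' @param max_train Maximum number of pixels kept (stratified).
#' @param seed Seed for the subsample.
#' @return List with `X` (feature matrix, named columns) and `y` (labels).
#' @export
training_features <- function(pairs, space, max_train = Inf, seed = 1L) {
  training_rows(pairs, space, max_train, seed)
}

# classifier training features for a set of pairs under a space
training_rows <- function(pairs, space, max_train, seed) {
  feats <- vector("list", length(pairs))
  labels <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    feats[[i]] <- space_feature_rows(planes_to_rows(pairs[[i]]$image), space)
    labels[[i]] <- as.integer(as.vector(t(pairs[[i]]$mask)))
  }
  X <- do.call(rbind, feats)
  y <- unlist(labels)
  if (nrow(X) > max_train) {
    keep <- with_seed(derive_seed(seed, "train"),
                      stratified_sample(y, max_train))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  list(X = X, y = y)
}

#' Run the full derivation pipeline
#'
#' Executes transform, feature-matrix, GA selection, PCA reduction,
#' training and evaluation, persisting stage artifacts under `out_dir`
#' (`manifest.csv`, `subset.json`, `ga_history.csv`, `space.json`,
#' `model.rds`, `report.json`). When no manifest is supplied, a synthetic
#' dataset is generated per the `synth` section.
#'
#' @param config A [run_config()] (or override list passed through it).
#' @param manifest Optional manifest data frame or CSV path; rows may
#'   already carry split tags.
#' @param out_dir Artifact directory.
#' @param resume Reuse artifacts already present in `out_dir`.
#' @return List with `manifest`, `subset`, `space`, `model`, `report`,
#'   and file `paths`.
#' @export
run_pipeline <- function(config = list(), manifest = NULL,
                         out_dir = tempfile("sknrun"), resume = FALSE) {
  config <- run_config(config)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  paths <- list(manifest = file.path(out_dir, "manifest.csv"),
                subset = file.path(out_dir, "subset.json"),
                history = file.path(out_dir, "ga_history.csv"),
                space = file.path(out_dir, "space.json"),
                model = file.path(out_dir, "model.rds"),
                report = file.path(out_dir, "report.json"))
  stage <- function(name, artifact, reader, producer) {
    if (resume && file.exists(artifact)) {
      pipe_log(config, "stage %s: reusing %s", name, artifact)
      return(reader(artifact))
    }
    t0 <- Sys.time()
    out <- tryCatch(producer(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    pipe_log(config, "stage %s: done in %.1fs (seed %d)", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")),
             config$seed)
    out
  }

  manifest <- stage("data", paths$manifest, read_manifest, function() {
    if (is.null(manifest)) {
      sc <- config$synth
      cfg <- scene_config(height = sc$height, width = sc$width,
                          n_regions = sc$n_regions,
                          background_mode = sc$background_mode,
                          skin_fraction_target = sc$skin_fraction_target)
      manifest <- generate_dataset(sc$n_images, cfg,
                                   file.path(out_dir, "data"),
                                   seed = derive_seed(config$seed, "synth"))
    } else if (is.character(manifest)) {
      manifest <- read_manifest(manifest)
    }
    if (is.null(manifest$split))
      manifest <- split_manifest(manifest, config$split$train_fraction,
                                 seed = config$seed)
    write_manifest(manifest, paths$manifest)
    manifest
  })

  registry <- component_registry(config$features$registry)
  train_pairs <- load_pairs(manifest[manifest$split == "train", ])
  test_pairs <- load_pairs(manifest[manifest$split == "test", ])

  subset <- stage("select", paths$subset,
                  function(p) read_subset(p)$mask, function() {
    feats <- sampled_features(train_pairs, registry,
                              config$features$max_pixels, config$seed)
    ga_cfg <- do.call(ga_config,
                      c(config$ga, list(seed = derive_seed(config$seed, "ga"))))
    res <- run_ga(feats, ga_cfg)
    write_subset(res$subset, registry$id, paths$subset)
    utils::write.csv(res$history, paths$history, row.names = FALSE)
    res$subset
  })

  space <- stage("reduce", paths$space, read_space, function() {
    feats <- sampled_features(train_pairs, registry,
                              config$features$max_pixels, config$seed)
    model <- fit_pca(feats, subset)
    sp <- make_space(model, k = config$pca$k)
    write_space(sp, paths$space)
    sp
  })

  model <- stage("train", paths$model, readRDS, function() {
    tr <- training_rows(train_pairs, space, config$classifier$max_train,
                        config$seed)
    spec <- classifier_spec(config$classifier$kind, config$classifier$params,
                            seed = derive_seed(config$seed, "classifier"))
    m <- train_classifier(spec, tr$X, tr$y)
    saveRDS(m, paths$model)
    m
  })

  report <- stage("evaluate", paths$report,
                  function(p) jsonlite::read_json(p, simplifyVector = TRUE),
                  function() {
    ev <- evaluate_pairs(model, test_pairs, space,
                         config$evaluation$threshold)
    rep <- list(metrics = list(FPR = ev$average$FPR,
                               Precision = ev$average$precision,
                               TPR = ev$average$TPR,
                               F1 = ev$average$f_score),
                n_train = length(train_pairs), n_test = length(test_pairs),
                selected = registry$id[subset],
                config = config)
    if (isTRUE(config$evaluation$roc)) {
      roc <- roc_curve(model, test_pairs, space,
                       config$evaluation$n_thresholds)
      rep$auc <- roc$auc
      utils::write.csv(
        data.frame(threshold = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr),
        file.path(out_dir, "roc.csv"), row.names = FALSE)
    }
    jsonlite::write_json(rep, paths$report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    rep
  })

  list(manifest = manifest, subset = subset, space = space, model = model,
       report = report, paths = paths)
}
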