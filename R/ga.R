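#' Genetic-algorithm wrapper feature selection
#'
#' Searches the space of component subsets (binary genomes over the
#' registry) for the combination that maximizes cross-validated pixel
#' classification F-score. Fitness is the skin-class F-score of a
#' 15-tree random forest under stratified k-fold cross-validation on a
#' stratified pixel subsample that is drawn once per run, so every candidate
#' is scored on identical data. Successive generations combine elitism, an
#' estimation-of-distribution step — new genomes sampled from a univariate
#' marginal model fit to the elite fraction, the minimal reading of a
#' "Bayesian network over the fittest individuals" — fresh random
#' immigrants, and classic fitness-proportional parent selection with
#' uniform crossover and per-bit mutation.
#'
#' @name ga-selection
NULL

#' Genetic algorithm configuration
#'
#' Defaults follow the published search setup: population of 25, per-bit
#' mutation probability 0.035, crossover probability 0.55, at most 500
#' generations. The stall window stops a run whose best fitness has not
#' improved for that many generations (the published run plateaued well
#' before the generation cap).
#'
#' @param population_size Number of genomes per generation (>= 2).
#' @param mutation_prob Per-bit mutation probability.
#' @param crossover_prob Probability that an offspring pair undergoes
#'   uniform crossover rather than cloning.
#' @param max_generations Hard generation cap.
#' @param elite_fraction Top fraction of the population used to fit the
#'   marginal reproduction model.
#' @param model_sample_fraction Fraction of the next generation drawn from
#'   the marginal model.
#' @param random_fraction Fraction of the next generation drawn uniformly
#'   at random (immigrants).
#' @param cv_folds Stratified cross-validation folds for fitness.
#' @param fitness_subsample Maximum number of pixels (stratified) used for
#'   fitness evaluation; drawn once per run.
#' @param stall_window Stop after this many generations without improvement.
#' @param seed Master seed for the run.
#' @return A validated `ga_config`.
#' @export
ga_config <- function(population_size = 25L, mutation_prob = 0.035,
                      crossover_prob = 0.55, max_generations = 500L,
                      elite_fraction = 0.4, model_sample_fraction = 0.5,
                      random_fraction = 0.2, cv_folds = 10L,
                      fitness_subsample = 20000L, stall_window = 100L,
                      seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              mutation_prob = mutation_prob, crossover_prob = crossover_prob,
              max_generations = as.integer(max_generations),
              elite_fraction = elite_fraction,
              model_sample_fraction = model_sample_fraction,
              random_fraction = random_fraction,
              cv_folds = as.integer(cv_folds),
              fitness_subsample = as.integer(fitness_subsample),
              stall_window = as.integer(stall_window),
              seed = as.integer(seed))
  if (!is_count(cfg$population_size, 2)) stopf("population_size must be >= 2")
  for (f in c("mutation_prob", "crossover_prob", "elite_fraction",
              "model_sample_fraction", "random_fraction"))
    if (!is_prob(cfg[[f]])) stopf("%s must be in [0, 1]", f)
  if (cfg$model_sample_fraction + cfg$random_fraction +
      1 / cfg$population_size > 1 + 1e-9)
    stopf("model and random fractions plus the elite slot exceed the population")
  if (!is_count(cfg$max_generations)) stopf("max_generations must be >= 1")
  if (!is_count(cfg$cv_folds, 2)) stopf("cv_folds must be >= 2")
  if (!is_count(cfg$stall_window)) stopf("stall_window must be >= 1")
  structure(cfg, class = "ga_config")
}

# random non-empty genome of length m (uses current RNG stream)
random_genome <- function(m, p = 0.5) {
  repeat {
    g <- stats::runif(m) < p
    if (any(g)) return(g)
  }
}

#' Initial random population
#'
#' Each bit is drawn independently with probability 0.5; all-zero genomes
#' are resampled. Deterministic for a given `config$seed`.
#'
#' @param config A [ga_config()].
#' @param n_components Genome length (registry size; default 32).
#' @return Logical matrix, one genome per row.
#' @export
init_population <- function(config, n_components = 32L) {
  stopifnot(inherits(config, "ga_config"))
  with_seed(derive_seed(config$seed, "init"),
            t(replicate(config$population_size, random_genome(n_components))))
}

# Stratified fold assignment (1..k) for 0/1 labels, current RNG stream.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in c(0L, 1L)) {
    rows <- which(y == cl)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

# Stratified subsample indices for fitness evaluation, current RNG stream.
fitness_rows <- function(labels, cap) {
  if (length(labels) <= cap) return(seq_along(labels))
  sort(stratified_sample(labels, cap))
}

#' Cross-validated fitness of one component subset
#'
#' @param subset Logical genome over the feature columns (>= 1 bit set).
#' @param data A [build_feature_matrix()] result (or compatible list with
#'   `values` and `labels`); both classes must be present.
#' @param config A [ga_config()].
#' @return A `fitness_record`: `subset`, `f_score`, `error_rate`,
#'   `generation` (`NA` outside [run_ga()]).
#' @export
evaluate_fitness <- function(subset, data, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  subset <- as.logical(subset)
  if (!any(subset)) stopf("subset must select at least one component")
  if (length(subset) != ncol(data$values))
    stopf("subset length %d does not match %d feature columns",
          length(subset), ncol(data$values))
  if (length(unique(data$labels)) < 2L)
    stopf("fitness evaluation requires both classes in the data")
  rows <- with_seed(derive_seed(config$seed, "subsample"),
                    fitness_rows(data$labels, config$fitness_subsample))
  y <- data$labels[rows]
  fold <- with_seed(derive_seed(config$seed, "folds"),
                    stratified_folds(y, config$cv_folds))
  eval_subset_cv(subset, data$values[rows, , drop = FALSE], y, fold, config)
}

eval_subset_cv <- function(subset, X, y, fold, config) {
  Xs <- X[, subset, drop = FALSE]
  res <- .rf_cv_cpp(Xs, y, fold, 15L,
                    max(1L, floor(sqrt(ncol(Xs)))), 0L, 1L, 64L,
                    as.double(derive_seed(config$seed, "rf")))
  structure(list(subset = subset, f_score = res[1], error_rate = res[2],
                 generation = NA_integer_),
            class = "fitness_record")
}

#' Produce the next generation
#'
#' Composition (sizes rounded from the config fractions): the single best
#' genome is carried over unchanged; `model_sample_fraction` of the
#' population is sampled bit-wise from the empirical marginal frequencies of
#' the top `elite_fraction` genomes; `random_fraction` are fresh random
#' genomes; the remainder are offspring of fitness-proportional parents with
#' uniform crossover (probability `crossover_prob`) followed by per-bit
#' mutation (probability `mutation_prob`). All-zero results are resampled.
#' Uses the current RNG stream; [run_ga()] provides the seeding.
#'
#' @param population Logical genome matrix (one row per individual).
#' @param fitness Numeric fitness vector, one value per row.
#' @param config A [ga_config()].
#' @return Logical matrix of the same dimensions.
#' @export
next_generation <- function(population, fitness, config) {
  stopifnot(inherits(config, "ga_config"))
  population <- as.matrix(population)
  P <- nrow(population)
  m <- ncol(population)
  if (length(fitness) != P)
    stopf("fitness length %d does not match population size %d",
          length(fitness), P)
  n_model <- round(config$model_sample_fraction * P)
  n_rand <- round(config$random_fraction * P)
  n_cross <- P - 1L - n_model - n_rand
  out <- matrix(FALSE, P, m)
  out[1, ] <- population[which.max(fitness), ]            # elitism
  row <- 2L
  if (n_model > 0) {
    n_elite <- max(1L, ceiling(config$elite_fraction * P))
    elite <- population[order(-fitness)[seq_len(n_elite)], , drop = FALSE]
    freq <- colMeans(elite)
    for (i in seq_len(n_model)) {
      repeat {
        g <- stats::runif(m) < freq
        if (any(g)) break
      }
      out[row, ] <- g
      row <- row + 1L
    }
  }
  for (i in seq_len(n_rand)) {
    out[row, ] <- random_genome(m)
    row <- row + 1L
  }
  if (n_cross > 0) {
    w <- fitness - min(fitness)
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / P, P)
    w <- w + 1e-12
    for (i in seq_len(n_cross)) {
      parents <- sample.int(P, 2L, replace = TRUE, prob = w)
      child <- population[parents[1], ]
      if (stats::runif(1) < config$crossover_prob) {
        take2 <- stats::runif(m) < 0.5
        child[take2] <- population[parents[2], take2]
      }
      flip <- stats::runif(m) < config$mutation_prob
      child <- xor(child, flip)
      if (!any(child)) child <- random_genome(m)
      out[row, ] <- child
      row <- row + 1L
    }
  }
  out
}

#' Run the genetic algorithm
#'
#' Evaluates generations until the generation cap or until the best-ever
#' fitness has not improved within the stall window. Fitness values are
#' memoized per genome (fitness is a pure function of the genome given the
#' per-run fixed subsample), so converged populations re-evaluate cheaply.
#'
#' @param data A [build_feature_matrix()] result.
#' @param config A [ga_config()].
#' @return A `ga_result`: `best` (a `fitness_record` with the generation it
#'   first appeared), `history` (data frame of per-generation best/mean
#'   F-score and best error rate), and `subset` (logical genome of the
#'   best-ever individual).
#' @export
run_ga <- function(data, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  if (length(unique(data$labels)) < 2L)
    stopf("run_ga requires both classes in the data")
  m <- ncol(data$values)
  rows <- with_seed(derive_seed(config$seed, "subsample"),
                    fitness_rows(data$labels, config$fitness_subsample))
  X <- data$values[rows, , drop = FALSE]
  y <- data$labels[rows]
  fold <- with_seed(derive_seed(config$seed, "folds"),
                    stratified_folds(y, config$cv_folds))
  cache <- new.env(parent = emptyenv())
  score <- function(genome) {
    key <- rawToChar(as.raw(c(genome + 65L)))
    hit <- get0(key, cache)
    if (!is.null(hit)) return(hit)
    rec <- eval_subset_cv(genome, X, y, fold, config)
    assign(key, rec, cache)
    rec
  }
  best <- NULL
  history <- vector("list", config$max_generations)
  with_seed(derive_seed(config$seed, "ga"), {
    pop <- t(replicate(config$population_size, random_genome(m)))
    stall <- 0L
    for (gen in seq_len(config$max_generations)) {
      recs <- apply(pop, 1L, score)
      fit <- vapply(recs, `[[`, numeric(1), "f_score")
      gi <- which.max(fit)
      improved <- is.null(best) || fit[gi] > best$f_score
      if (improved) {
        best <- recs[[gi]]
        best$generation <- gen
        stall <- 0L
      } else stall <- stall + 1L
      history[[gen]] <- data.frame(
        generation = gen, best_f = best$f_score,
        mean_f = mean(fit), best_error = best$error_rate)
      if (stall >= config$stall_window || gen >= config$max_generations)
        break
      pop <- next_generation(pop, fit, config)
    }
  })
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  structure(list(best = best, history = history, subset = best$subset,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best F = %.4f (error %.4f) at generation %d; %d components: %s\n",
              x$best$f_score, x$best$error_rate, x$best$generation,
              sum(x$subset), paste(which(x$subset), collapse = ", ")))
  invisible(x)
}
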