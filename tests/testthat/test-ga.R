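quick_ga <- function(seed = 1, ...) {
  ga_config(max_generations = 5L, stall_window = 3L, cv_folds = 3L,
            fitness_subsample = 600L, seed = seed, ...)
}

test_that("config validation enforces the documented invariants", {
  cfg <- ga_config()
  expect_equal(cfg$population_size, 25L)
  expect_equal(cfg$mutation_prob, 0.035)
  expect_equal(cfg$crossover_prob, 0.55)
  expect_equal(cfg$max_generations, 500L)
  expect_error(ga_config(population_size = 1), "population_size")
  expect_error(ga_config(mutation_prob = 1.2), "mutation_prob")
  expect_error(ga_config(model_sample_fraction = 0.7, random_fraction = 0.4),
               "exceed")
})

test_that("initial population is sized, non-empty and seed-deterministic", {
  cfg <- ga_config(seed = 7)
  pop <- init_population(cfg, 32L)
  expect_equal(dim(pop), c(25L, 32L))
  expect_true(all(rowSums(pop) >= 1))
  expect_identical(pop, init_population(cfg, 32L))
  expect_false(identical(pop, init_population(ga_config(seed = 8), 32L)))
})

test_that("a perfect separator column reaches F-score 1", {
  set.seed(1)
  n <- 400
  labels <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 4] <- labels  # column equals the label
  colnames(X) <- paste0("c", 1:6)
  fm <- sknspace:::new_pixel_features(X, labels, colnames(X))
  sub <- rep(FALSE, 6); sub[4] <- TRUE
  rec <- evaluate_fitness(sub, fm, quick_ga())
  expect_equal(rec$f_score, 1.0)
  expect_equal(rec$error_rate, 0.0)
})

test_that("pure-noise subsets score at chance level across seeds", {
  fs <- vapply(1:10, function(s) {
    pm <- planted_matrix(planted_config(n = 400, m = 8, informative = 1L,
                                        separation = 6, seed = s))
    sub <- c(FALSE, rep(TRUE, 3), rep(FALSE, 4))  # noise-only columns
    evaluate_fitness(sub, pm, quick_ga(seed = s))$f_score
  }, numeric(1))
  expect_true(all(fs >= 0.35 & fs <= 0.65))
})

test_that("degenerate fitness inputs are rejected", {
  pm <- planted_matrix(planted_config(n = 200, m = 4, seed = 1))
  expect_error(evaluate_fitness(rep(FALSE, 4), pm, quick_ga()),
               "at least one")
  single <- pm
  single$labels <- rep(1L, length(pm$labels))
  expect_error(evaluate_fitness(c(TRUE, rep(FALSE, 3)), single, quick_ga()),
               "both classes")
})

test_that("next_generation preserves size, elitism and the marginal model", {
  set.seed(3)
  cfg <- ga_config(seed = 3)
  pop <- init_population(cfg, 16L)
  fit <- runif(25)
  nxt <- next_generation(pop, fit, cfg)
  expect_equal(dim(nxt), dim(pop))
  expect_equal(nxt[1, ], pop[which.max(fit), ])
  expect_true(all(rowSums(nxt) >= 1))
  expect_error(next_generation(pop, fit[-1], cfg), "does not match")

  # pure elitism config: only elite + crossover-with-no-ops remain
  cfg0 <- ga_config(mutation_prob = 0, crossover_prob = 0,
                    model_sample_fraction = 0, random_fraction = 0, seed = 1)
  pop0 <- init_population(cfg0, 8L)
  best <- rep(0, 25); best[4] <- 1
  nxt0 <- next_generation(pop0, best, cfg0)
  expect_equal(nxt0[1, ], pop0[4, ])

  # elites all sharing a set bit propagate it through the marginal model
  cfg1 <- ga_config(mutation_prob = 0, model_sample_fraction = 0.5,
                    random_fraction = 0, seed = 2)
  pop1 <- init_population(cfg1, 8L)
  pop1[, 3] <- TRUE
  nxt1 <- next_generation(pop1, runif(25), cfg1)
  expect_true(all(nxt1[2:13, 3]))  # rows 2..(1+round(0.5*25)) are model draws
})

test_that("a short planted run recovers signal with non-decreasing history", {
  pm <- planted_matrix(planted_config(n = 600, m = 10, informative = 1:2,
                                      separation = 6, seed = 4))
  cfg <- ga_config(max_generations = 8L, stall_window = 8L, cv_folds = 3L,
                   fitness_subsample = 600L, seed = 4)
  res <- run_ga(pm, cfg)
  expect_false(is.unsorted(res$history$best_f))
  expect_gt(res$best$f_score, 0.9)
  expect_true(any(res$subset[1:2]))
  expect_equal(ncol(res$history), 4L)
})

test_that("stall window and generation cap bound the history", {
  pm <- planted_matrix(planted_config(n = 300, m = 6, seed = 2))
  cfg <- ga_config(max_generations = 1L, stall_window = 1L, cv_folds = 2L,
                   fitness_subsample = 300L, seed = 2)
  res <- run_ga(pm, cfg)
  expect_equal(nrow(res$history), 1L)
})

test_that("identical seed, data and config reproduce the run exactly", {
  pm <- planted_matrix(planted_config(n = 400, m = 8, seed = 6))
  a <- run_ga(pm, quick_ga(seed = 9))
  b <- run_ga(pm, quick_ga(seed = 9))
  expect_identical(a$subset, b$subset)
  expect_identical(a$history, b$history)
  expect_identical(a$best$f_score, b$best$f_score)
})

test_that("planted optimum dominates pure-noise subsets (10-seed median)", {
  diffs <- vapply(1:10, function(s) {
    pm <- planted_matrix(planted_config(n = 400, m = 8, informative = 1:2,
                                        separation = 6, seed = s))
    cfg <- quick_ga(seed = s)
    opt <- c(TRUE, TRUE, rep(FALSE, 6))
    noise <- c(FALSE, FALSE, TRUE, TRUE, TRUE, rep(FALSE, 3))
    evaluate_fitness(opt, pm, cfg)$f_score -
      evaluate_fitness(noise, pm, cfg)$f_score
  }, numeric(1))
  expect_gt(median(diffs), 0.3)
})
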