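test_that("initial populations are uniform within bounds and seed-reproducible", {
  b <- parameter_bounds()
  set.seed(11)
  pop <- init_population(b, 1000)
  expect_equal(dim(pop), c(1000, 10))
  for (nm in param_names()) {
    expect_true(all(pop[, nm] >= b[[nm]][1] & pop[, nm] <= b[[nm]][2]))
  }
  expect_true(all(pop[, "C_m"] >= 0.1 & pop[, "C_m"] <= 5.0))
  set.seed(11)
  expect_identical(init_population(b, 1000), pop)
  # degenerate narrow interval
  bn <- parameter_bounds(tau_w = c(100, 100 + 1e-9))
  popn <- init_population(bn, 50)
  expect_true(all(abs(popn[, "tau_w"] - 100) <= 1e-9))
})

test_that("one-point crossover swaps suffixes and conserves loci", {
  set.seed(3)
  p_lo <- rep(0, 10)
  p_hi <- rep(1, 10)
  ch <- one_point_crossover(p_lo, p_hi)
  k <- sum(ch$child1 == 0)
  expect_true(k >= 1 && k <= 9)
  expect_equal(ch$child1, c(rep(0, k), rep(1, 10 - k)))
  expect_equal(ch$child2, c(rep(1, k), rep(0, 10 - k)))
  # identical parents reproduce themselves
  ch2 <- one_point_crossover(p_lo, p_lo)
  expect_equal(ch2$child1, p_lo)
  expect_equal(ch2$child2, p_lo)
  # per-locus multiset conservation on random parents
  a <- stats::runif(10)
  b2 <- stats::runif(10)
  ch3 <- one_point_crossover(a, b2)
  for (i in 1:10) {
    expect_setequal(c(ch3$child1[i], ch3$child2[i]), c(a[i], b2[i]))
  }
})

test_that("uniform mutation redraws genes at the configured rate", {
  b <- parameter_bounds()
  g <- params_to_genes(published_individual("FF1"))
  expect_identical(uniform_mutation(g, b, p_gene = 0), g)
  set.seed(5)
  g1 <- uniform_mutation(g, b, p_gene = 1)
  expect_true(all(g1 != g))
  expect_true(params_within_bounds(genes_to_params(g1)))
  # empirical redraw fraction over 10,000 genes at p = 0.15
  set.seed(99)
  changed <- 0L
  for (i in 1:1000) {
    changed <- changed + sum(uniform_mutation(g, b, p_gene = 0.15) != g)
  }
  expect_equal(changed / 10000, 0.15, tolerance = 0.01 / 0.15)
})

test_that("tournaments return the minimum-score entrant", {
  pop <- init_population(parameter_bounds(), 10)
  # degenerate: single winner dominates every tournament it enters
  scores <- c(0, rep(100, 9))
  set.seed(2)
  sel <- tournament_select(pop, scores, k = 3, n_winners = 4000)
  expect_length(sel, 4000)
  # expected selection frequency of the best: 1 - (1 - 1/N)^k
  p_best <- 1 - (1 - 1 / 10)^3
  expect_equal(mean(sel == 1), p_best, tolerance = 0.1)
  # uniform-population degenerate case
  sel1 <- tournament_select(pop[1, , drop = FALSE], 5, k = 3, n_winners = 7)
  expect_true(all(sel1 == 1))
  expect_error(tournament_select(pop, c(NA, 1:9), k = 3), "score")
})

test_that("the EA minimizes a quadratic surrogate and respects its contracts", {
  target <- params_to_genes(published_individual("FF1"))
  bounds <- parameter_bounds()
  violations <- 0L
  evaluator <- function(g) {
    if (!params_within_bounds(genes_to_params(g), bounds)) {
      violations <<- violations + 1L
    }
    sum((g - target)^2)
  }
  cfg <- ea_config(pop_size = 50, generations = 20, seeds = 1:5)
  res <- run_ea(config = cfg, evaluator = evaluator)
  expect_identical(violations, 0L)  # bounds hold for every evaluated genome
  # convergence: the best score found falls below 1% of the typical
  # (median) generation-0 score, and below every generation-0 minimum
  gen0_scores <- unlist(lapply(cfg$seeds, function(s) {
    set.seed(s)
    apply(init_population(bounds, cfg$pop_size), 1, evaluator)
  }))
  expect_lt(res$best_score, 0.01 * stats::median(gen0_scores))
  expect_lt(res$best_score,
            min(res$history$min_score[res$history$generation == 0]))
  for (s in cfg$seeds) {
    h <- res$history[res$history$seed == s, ]
    # best-so-far is non-increasing within each run
    expect_true(all(diff(h$best_so_far) <= 1e-12))
    # one history row per generation, every generation present
    expect_equal(h$generation, 0:20)
  }
})

test_that("zero generations return the best of the initial population", {
  evaluator <- function(g) sum(g^2)
  res <- run_ea(config = ea_config(pop_size = 40, generations = 0, seeds = 8),
                evaluator = evaluator)
  set.seed(8)
  pop <- init_population(parameter_bounds(), 40)
  scores <- apply(pop, 1, evaluator)
  expect_equal(res$best_score, min(scores))
  expect_equal(unname(res$best_genes), unname(pop[which.min(scores), ]))
})

test_that("identical seeds give identical optimization results", {
  evaluator <- function(g) sum(abs(g))
  cfg <- ea_config(pop_size = 30, generations = 5, seeds = c(1, 2))
  r1 <- run_ea(config = cfg, evaluator = evaluator)
  r2 <- run_ea(config = cfg, evaluator = evaluator)
  expect_identical(r1$best_genes, r2$best_genes)
  expect_identical(r1$history, r2$history)
})

test_that("the score history exports to CSV", {
  res <- run_ea(config = ea_config(pop_size = 20, generations = 3, seeds = 1),
                evaluator = function(g) sum(g^2))
  path <- tempfile(fileext = ".csv")
  write_ea_history(res, path)
  hist <- utils::read.csv(path)
  expect_named(hist, c("seed", "generation", "min_score", "best_so_far"))
  expect_equal(nrow(hist), 4)
})
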