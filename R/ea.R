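#' Evolutionary-algorithm configuration
#'
#' Settings of the generational evolutionary search over the bounded
#' 10-parameter space. Defaults match the published optimization protocol:
#' 1000 individuals evolved for 50 generations; one-point crossover with
#' probability 0.60 per consecutive pair; uniform mutation selecting
#' individuals with probability 0.10 and redrawing each gene of a selected
#' individual with probability 0.15; selection by 1000 three-individual
#' tournaments (minimum score wins); five independently seeded runs.
#'
#' @param pop_size population size.
#' @param generations number of generations after the initial one.
#' @param p_crossover per-pair one-point crossover probability.
#' @param p_mut_individual probability an individual is selected for
#'   mutation.
#' @param p_mut_gene per-gene redraw probability within a mutating
#'   individual.
#' @param tournament_k tournament size.
#' @param seeds integer vector of RNG seeds, one independent run each.
#' @return A list of class `ea_config`.
#' @export
ea_config <- function(pop_size = 1000, generations = 50, p_crossover = 0.6,
                      p_mut_individual = 0.1, p_mut_gene = 0.15,
                      tournament_k = 3, seeds = 1:5) {
  stopifnot(pop_size >= 1, generations >= 0, tournament_k >= 1,
            length(seeds) >= 1)
  for (p in c(p_crossover, p_mut_individual, p_mut_gene)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover,
                 p_mut_individual = p_mut_individual,
                 p_mut_gene = p_mut_gene, tournament_k = tournament_k,
                 seeds = as.integer(seeds)),
            class = "ea_config")
}

#' Initialize a population uniformly within bounds
#'
#' @param bounds a [parameter_bounds()] box.
#' @param n population size.
#' @return An `n x 10` numeric matrix, columns named by [param_names()];
#'   each gene i.i.d. uniform within its interval.
#' @export
init_population <- function(bounds, n) {
  stopifnot(n >= 1)
  nms <- param_names()
  pop <- vapply(nms, function(nm) {
    stats::runif(n, bounds[[nm]][1], bounds[[nm]][2])
  }, numeric(n))
  if (n == 1) pop <- matrix(pop, nrow = 1, dimnames = list(NULL, nms))
  pop
}

#' One-point crossover
#'
#' Draws a cut point uniformly in 1..9 and swaps the gene suffixes of the
#' two parents; the multiset of genes at each locus is conserved across
#' the pair.
#'
#' @param parent1,parent2 numeric gene vectors of length 10.
#' @return A list with `child1` and `child2`.
#' @export
one_point_crossover <- function(parent1, parent2) {
  stopifnot(length(parent1) == 10, length(parent2) == 10)
  k <- sample.int(9, 1)
  c1 <- c(parent1[1:k], parent2[(k + 1):10])
  c2 <- c(parent2[1:k], parent1[(k + 1):10])
  list(child1 = c1, child2 = c2)
}

#' Uniform bounded mutation
#'
#' Each gene is independently redrawn uniformly within its bounds with
#' probability `p_gene`; other genes are untouched.
#'
#' @param genes numeric gene vector of length 10.
#' @param bounds a [parameter_bounds()] box.
#' @param p_gene per-gene redraw probability.
#' @return Mutated gene vector.
#' @export
uniform_mutation <- function(genes, bounds, p_gene = 0.15) {
  stopifnot(length(genes) == 10)
  nms <- param_names()
  hit <- stats::runif(10) < p_gene
  for (i in which(hit)) {
    genes[i] <- stats::runif(1, bounds[[nms[i]]][1], bounds[[nms[i]]][2])
  }
  genes
}

#' Tournament selection
#'
#' Runs `n_winners` independent tournaments; each draws `k` individuals
#' uniformly with replacement and returns the one with the minimum score
#' (ties broken by draw order).
#'
#' @param population gene matrix (rows = individuals).
#' @param scores numeric score vector, one per row.
#' @param k tournament size.
#' @param n_winners number of tournaments (default: population size).
#' @return Integer vector of selected row indices, length `n_winners`.
#' @export
tournament_select <- function(population, scores, k = 3,
                              n_winners = nrow(population)) {
  n <- nrow(population)
  if (n == 0) stop("population is empty", call. = FALSE)
  if (anyNA(scores) || length(scores) != n) {
    stop("every individual must carry a score", call. = FALSE)
  }
  vapply(seq_len(n_winners), function(i) {
    entrants <- sample.int(n, k, replace = TRUE)
    entrants[which.min(scores[entrants])]
  }, integer(1))
}

#' Run the evolutionary search
#'
#' Generational loop: tournament selection into a full new population,
#' one-point crossover applied to consecutive pairs with probability
#' `p_crossover`, uniform mutation applied to individuals with probability
#' `p_mut_individual` (genes redrawn with probability `p_mut_gene`), then
#' evaluation. There is no elitism; the best individual ever evaluated is
#' tracked outside the population, and the best over all seeded runs is
#' returned. Within a seeded run all randomness flows from `set.seed` on
#' that seed, so runs are exactly reproducible.
#'
#' @param spec a [fitness_spec()]; ignored when `evaluator` is given.
#' @param config an [ea_config()].
#' @param bounds a [parameter_bounds()] box.
#' @param evaluator optional function(genes) -> scalar score, replacing
#'   the feature-based fitness (used for surrogate and recovery tests).
#' @param solver a [solver_config()] for feature evaluation.
#' @param keep_populations logical; retain each seed's final population.
#' @param verbose print one line per generation.
#' @return A list of class `ea_result`: `best_genes`, `best_score`,
#'   `best_params`, `best_seed`, `history` (data.frame `seed`, `generation`,
#'   `min_score`, `best_so_far`), and optionally `final_populations`.
#' @export
#' @examples
#' # quadratic surrogate: recover a known gene vector
#' target <- params_to_genes(published_individual("FF1"))
#' res <- run_ea(config = ea_config(pop_size = 60, generations = 10,
#'                                  seeds = 1),
#'               evaluator = function(g) sum((g - target)^2))
#' res$best_score
run_ea <- function(spec = NULL, config = ea_config(),
                   bounds = parameter_bounds(), evaluator = NULL,
                   solver = solver_config(), keep_populations = FALSE,
                   verbose = FALSE) {
  if (is.null(evaluator)) {
    if (is.null(spec)) stop("either 'spec' or 'evaluator' is required",
                            call. = FALSE)
    evaluator <- function(genes) {
      evaluate_individual(genes, spec, solver = solver, bounds = bounds)$score
    }
  }
  evaluate_pop <- function(pop) {
    apply(pop, 1, function(g) as.numeric(evaluator(g)))
  }

  best <- list(score = Inf, genes = NULL, seed = NA_integer_)
  history <- vector("list", 0)
  finals <- list()

  for (seed in config$seeds) {
    set.seed(seed)
    pop <- init_population(bounds, config$pop_size)
    scores <- evaluate_pop(pop)
    run_best <- min(scores)
    if (run_best < best$score) {
      best <- list(score = run_best, genes = pop[which.min(scores), ],
                   seed = seed)
    }
    history[[length(history) + 1]] <- data.frame(
      seed = seed, generation = 0L, min_score = min(scores),
      best_so_far = run_best)
    if (verbose) {
      message(sprintf("seed %d gen %3d: min %.4f", seed, 0L, min(scores)))
    }

    gen <- 0L
    while (gen < config$generations) {
      gen <- gen + 1L
      idx <- tournament_select(pop, scores, k = config$tournament_k,
                               n_winners = config$pop_size)
      new_pop <- pop[idx, , drop = FALSE]
      # crossover over consecutive pairs
      i <- 1L
      while (i + 1L <= config$pop_size) {
        if (stats::runif(1) < config$p_crossover) {
          ch <- one_point_crossover(new_pop[i, ], new_pop[i + 1L, ])
          new_pop[i, ] <- ch$child1
          new_pop[i + 1L, ] <- ch$child2
        }
        i <- i + 2L
      }
      # mutation (clones and crossed offspring alike)
      for (j in seq_len(config$pop_size)) {
        if (stats::runif(1) < config$p_mut_individual) {
          new_pop[j, ] <- uniform_mutation(new_pop[j, ], bounds,
                                           config$p_mut_gene)
        }
      }
      pop <- new_pop
      scores <- evaluate_pop(pop)
      gen_min <- min(scores)
      if (gen_min < run_best) run_best <- gen_min
      if (gen_min < best$score) {
        best <- list(score = gen_min, genes = pop[which.min(scores), ],
                     seed = seed)
      }
      history[[length(history) + 1]] <- data.frame(
        seed = seed, generation = gen, min_score = gen_min,
        best_so_far = run_best)
      if (verbose) {
        message(sprintf("seed %d gen %3d: min %.4f (best %.4f)", seed, gen,
                        gen_min, run_best))
      }
    }
    if (keep_populations) {
      finals[[as.character(seed)]] <- list(population = pop, scores = scores)
    }
  }

  out <- list(best_genes = best$genes, best_score = best$score,
              best_params = genes_to_params(best$genes),
              best_seed = best$seed,
              history = do.call(rbind, history))
  if (keep_populations) out$final_populations <- finals
  class(out) <- "ea_result"
  out
}

#' @export
print.ea_result <- function(x, ...) {
  cat(sprintf("EA result: best score %.4f (seed %d, %d seeds, %d generations)\n",
              x$best_score, x$best_seed, length(unique(x$history$seed)),
              max(x$history$generation)))
  invisible(x)
}

#' Write the per-generation score history to CSV
#'
#' One row per (seed, generation) with the generation's minimum score and
#' the running best, reproducing the optimization-progress curves.
#'
#' @param result an `ea_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ea_history <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
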