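#' Configuration for the interpolation search
#'
#' Defaults follow the reference protocol: a population of 1000 bridge
#' interpolations, the best 50% allowed to mate, a 20% chance per generation
#' that one randomly chosen candidate is replaced by a fresh random-Hurst
#' interpolation, termination when the population mean loss stalls for 10
#' consecutive generations, and a hard cap of 1000 generations. Fitness is
#' evaluated on the full assembled series with embedding dimension 3 and
#' delay 1.
#'
#' @param population_size Number of candidates (default 1000).
#' @param mating_fraction Fraction of the population allowed to mate
#'   (default 0.5).
#' @param mutation_probability Probability per generation that one random
#'   candidate is replaced by a fresh interpolation (default 0.2).
#' @param stall_generations Consecutive stagnant generations that trigger
#'   termination (default 10).
#' @param max_generations Hard cap on generations (default 1000).
#' @param seed Integer master seed threading all randomness of a run.
#' @param dimension,delay Embedding parameters used by the loss.
#' @param loss_mode `"norm"` or `"squared_norm"`, see [trajectory_loss()].
#' @param scale Amplitude multiplier for the fBm fluctuation (default 1).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 1000, mating_fraction = 0.5,
                      mutation_probability = 0.2, stall_generations = 10,
                      max_generations = 1000, seed = 1,
                      dimension = 3, delay = 1,
                      loss_mode = c("norm", "squared_norm"), scale = 1) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(population_size >= 1,
            mating_fraction > 0, mating_fraction <= 1,
            mutation_probability >= 0, mutation_probability <= 1,
            stall_generations >= 1, max_generations >= 1, scale > 0)
  structure(list(population_size = as.integer(population_size),
                 mating_fraction = mating_fraction,
                 mutation_probability = mutation_probability,
                 stall_generations = as.integer(stall_generations),
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed),
                 dimension = as.integer(dimension),
                 delay = as.integer(delay),
                 loss_mode = loss_mode,
                 scale = scale),
            class = "ga_config")
}

# Shared immutable geometry of one run: observed anchors and refined grid.
ga_meta <- function(observed, points_per_gap, config) {
  n <- nrow(observed)
  K <- as.integer(points_per_gap)
  stopifnot(n >= 2, K >= 1)
  M <- n + (n - 1L) * K
  anchor_idx <- seq(1L, M, by = K + 1L)
  list(observed = observed, K = K, M = M, n_genes = n - 1L,
       anchor_idx = anchor_idx,
       t_out = refined_times(observed$t, K),
       config = config)
}

candidate_loss <- function(values, meta) {
  cfg <- meta$config
  trajectory_loss(values, dimension = cfg$dimension, delay = cfg$delay,
                  mode = cfg$loss_mode)
}

# Split a full refined series into per-gap genes (interior points only).
series_to_genes <- function(values, meta) {
  lapply(seq_len(meta$n_genes), function(g) {
    a <- meta$anchor_idx[g]
    values[(a + 1L):(a + meta$K)]
  })
}

# Reassemble a full series from genes between the observed anchors.
genes_to_series <- function(genes, meta) {
  values <- numeric(meta$M)
  values[meta$anchor_idx] <- meta$observed$value
  for (g in seq_len(meta$n_genes)) {
    a <- meta$anchor_idx[g]
    values[(a + 1L):(a + meta$K)] <- genes[[g]]
  }
  values
}

# Create one candidate with a fresh uniform Hurst exponent, using the
# current RNG state. If the covariance factorization fails numerically
# (H extremely close to 1 on a large grid), a new H is drawn.
new_candidate <- function(meta, max_tries = 20L) {
  for (i in seq_len(max_tries)) {
    h <- stats::runif(1)
    series <- tryCatch(
      bridge_interpolate(meta$observed$t, meta$observed$value, meta$K, h,
                         scale = meta$config$scale),
      error = function(e) NULL)
    if (!is.null(series)) {
      values <- series$value
      genes <- series_to_genes(values, meta)
      return(list(values = values, genes = genes,
                  hurst = rep(h, meta$n_genes),
                  loss = candidate_loss(values, meta)))
    }
  }
  stop("could not sample a bridge interpolation after ", max_tries, " Hurst draws")
}

sort_population <- function(candidates) {
  candidates[order(vapply(candidates, function(c) c$loss, numeric(1)))]
}

#' Initialize a population of bridge interpolations
#'
#' Draws `population_size` candidates, each a full-series multi-point
#' bridge with one Hurst exponent sampled uniformly on (0, 1), evaluates
#' their trajectory loss and sorts ascending by loss.
#'
#' @param observed A time series `data.frame` (>= 2 points).
#' @param points_per_gap New samples per gap (>= 1).
#' @param config A [ga_config()].
#' @return A list of class `ga_population` with elements `candidates`
#'   (sorted) and `meta`.
#' @export
init_population <- function(observed, points_per_gap, config) {
  meta <- ga_meta(observed, points_per_gap, config)
  candidates <- with_seed(config$seed, {
    lapply(seq_len(config$population_size), function(i) new_candidate(meta))
  })
  structure(list(candidates = sort_population(candidates), meta = meta),
            class = "ga_population")
}

#' Uniform per-gene crossover of two candidates
#'
#' The child inherits each gene (the interpolated points strictly between
#' two consecutive observed anchors) from either parent with probability
#' 1/2, independently per gene. Both parents pass exactly through the
#' anchors, so the child series is continuous at the anchors by
#' construction; its loss is recomputed on the assembled series.
#'
#' @param parent_a,parent_b Candidates sharing observed anchors and gene
#'   count.
#' @param meta Shared run geometry (internal; taken from a population).
#' @param take_from_a Optional logical vector forcing the per-gene coin
#'   (used for testing); `NULL` draws fair coins from the current RNG.
#' @return A new candidate list.
#' @export
crossover <- function(parent_a, parent_b, meta, take_from_a = NULL) {
  if (length(parent_a$genes) != length(parent_b$genes)) {
    stop("parents have mismatched gene structure")
  }
  ng <- length(parent_a$genes)
  if (is.null(take_from_a)) take_from_a <- stats::runif(ng) < 0.5
  genes <- vector("list", ng)
  hurst <- numeric(ng)
  for (g in seq_len(ng)) {
    src <- if (take_from_a[g]) parent_a else parent_b
    genes[[g]] <- src$genes[[g]]
    hurst[g] <- src$hurst[g]
  }
  values <- genes_to_series(genes, meta)
  list(values = values, genes = genes, hurst = hurst,
       loss = candidate_loss(values, meta))
}

#' Advance the population by one generation
#'
#' Generational elitism: the top `ceiling(mating_fraction * N)` candidates
#' are retained unchanged; the remaining slots are refilled by per-gene
#' crossover of parent pairs drawn uniformly at random (with replacement
#' across pairs, distinct within a pair) from the retained set. Then, with
#' probability `mutation_probability`, one uniformly chosen candidate of any
#' rank is replaced by a fresh random-Hurst interpolation. The population is
#' re-evaluated and re-sorted. Uses the current RNG state (seeding is
#' handled by [run_ga()]).
#'
#' @param pop A `ga_population`.
#' @return The next `ga_population`.
#' @export
step_generation <- function(pop) {
  meta <- pop$meta
  cfg <- meta$config
  N <- cfg$population_size
  n_elite <- min(N, as.integer(ceiling(cfg$mating_fraction * N)))
  elite <- pop$candidates[seq_len(n_elite)]
  offspring <- list()
  n_off <- N - n_elite
  if (n_off > 0) {
    offspring <- lapply(seq_len(n_off), function(i) {
      if (n_elite >= 2) {
        pair <- sample.int(n_elite, 2, replace = FALSE)
        crossover(elite[[pair[1]]], elite[[pair[2]]], meta)
      } else {
        elite[[1]]
      }
    })
  }
  candidates <- c(elite, offspring)
  if (cfg$mutation_probability > 0 && stats::runif(1) < cfg$mutation_probability) {
    slot <- sample.int(N, 1)
    candidates[[slot]] <- new_candidate(meta)
  }
  structure(list(candidates = sort_population(candidates), meta = meta),
            class = "ga_population")
}

#' Run the interpolation search
#'
#' Iterates [step_generation()] until the population mean loss is unchanged
#' (relative change below 1e-10) for `stall_generations` consecutive
#' generations, or `max_generations` is reached. The returned optimum is the
#' best candidate ever seen across all generations, tracked separately from
#' the mutable population so that mutation of the incumbent cannot lose the
#' result.
#'
#' @param observed A time series `data.frame` (>= 2 points).
#' @param points_per_gap New samples per gap (>= 1).
#' @param config A [ga_config()].
#' @param population Optional pre-built initial `ga_population` (e.g. from
#'   [init_population()]); when supplied its geometry and config are reused
#'   and only the generational loop is seeded.
#' @param trace If `TRUE`, log one line per generation to standard error.
#' @return A list of class `ga_result`: `best` (candidate), `best_series`
#'   (time series `data.frame`), `generations_run`, and `history` (data
#'   frame with per-generation best, mean and best-ever loss; generation 0
#'   is the initial population).
#' @export
run_ga <- function(observed, points_per_gap, config, population = NULL,
                   trace = FALSE) {
  pop <- if (is.null(population)) {
    init_population(observed, points_per_gap, config)
  } else {
    population
  }
  meta <- pop$meta
  cfg <- meta$config
  losses <- vapply(pop$candidates, function(c) c$loss, numeric(1))
  best_ever <- pop$candidates[[1]]
  history <- data.frame(generation = 0L, best_loss = losses[1],
                        mean_loss = mean(losses), best_ever_loss = best_ever$loss)
  prev_mean <- mean(losses)
  stall <- 0L
  gens <- 0L
  with_seed(cfg$seed + 1L, {
    while (gens < cfg$max_generations) {
      pop <- step_generation(pop)
      gens <- gens + 1L
      losses <- vapply(pop$candidates, function(c) c$loss, numeric(1))
      if (losses[1] < best_ever$loss) best_ever <- pop$candidates[[1]]
      m <- mean(losses)
      history <- rbind(history,
                       data.frame(generation = gens, best_loss = losses[1],
                                  mean_loss = m, best_ever_loss = best_ever$loss))
      if (trace) {
        message(sprintf("gen %d: best loss %.6g, mean loss %.6g", gens, losses[1], m))
      }
      rel <- abs(m - prev_mean) / max(abs(prev_mean), .Machine$double.xmin)
      stall <- if (rel < 1e-10) stall + 1L else 0L
      prev_mean <- m
      if (stall >= cfg$stall_generations) break
    }
  })
  structure(list(best = best_ever,
                 best_series = time_series(meta$t_out, best_ever$values),
                 generations_run = gens,
                 history = history,
                 population = pop),
            class = "ga_result")
}
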