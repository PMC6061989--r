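#' Differential evolution configuration
#'
#' Integer-coded differential evolution over candidate miRNA index vectors.
#' Defaults follow the study design this package implements: population
#' `I = 50`, `phi = 50` generations, mutation factor `F = 1`, crossover rate
#' `Cr = 0.8`, panel length `n = 10`, and `theta = 50` independent runs
#' feeding the majority-voting finisher.
#'
#' @param n panel-vector length.
#' @param pop_size population size I (>= 4; mutation draws three donors
#'   distinct from the target).
#' @param generations number of generations phi (>= 0).
#' @param mutation_factor F in `[0, 2]`.
#' @param crossover_rate Cr in `[0, 1]`.
#' @param runs number of independent DE runs theta.
#' @param seed master seed; per-run sub-seeds are derived from it.
#' @return An object of class `de_config`.
#' @export
de_config <- function(n = 10L, pop_size = 50L, generations = 50L,
                      mutation_factor = 1.0, crossover_rate = 0.8,
                      runs = 50L, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  if (pop_size < 4) stopf("population size must be >= 4")
  if (generations < 0) stopf("generations must be >= 0")
  if (mutation_factor < 0 || mutation_factor > 2)
    stopf("mutation_factor must be in [0, 2]")
  if (crossover_rate < 0 || crossover_rate > 1)
    stopf("crossover_rate must be in [0, 1]")
  if (runs < 1) stopf("runs must be >= 1")
  structure(list(n = as.integer(n), pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_factor = mutation_factor,
                 crossover_rate = crossover_rate,
                 runs = as.integer(runs), seed = as.integer(seed)),
            class = "de_config")
}

check_candidate <- function(v, n, d) {
  length(v) == n && !anyDuplicated(v) && all(v >= 1L & v <= d)
}

#' Initialize a DE population
#'
#' Each of the `pop_size` candidate vectors is `n` distinct indices drawn
#' uniformly from the miRNA table `[1, d]`.
#'
#' @param d number of miRNAs.
#' @param cfg a [de_config()].
#' @param seed optional seed (defaults to `cfg$seed`); `NULL` uses the
#'   ambient RNG, as [run_de()] does internally.
#' @return list of integer vectors of length `cfg$n`.
#' @export
init_population <- function(d, cfg, seed = cfg$seed) {
  if (d < cfg$n) stopf("panel length n = %d exceeds miRNA count d = %d", cfg$n, d)
  with_seed(seed,
            lapply(seq_len(cfg$pop_size), function(i) sample.int(d, cfg$n)))
}

# Wrap an index into [1, d] by iterating the single-step +/- d correction
# (the printed correction is the one-step case; iterating guarantees the
# range for any |F * difference|).
wrap_index <- function(x, d) {
  while (any(bad <- x < 1L)) x[bad] <- x[bad] + d
  while (any(bad <- x > d)) x[bad] <- x[bad] - d
  x
}

# Restore distinctness after mutation/crossover: scanning left to right,
# each repeated index is replaced by a uniform draw from the unused ones.
repair_duplicates <- function(v, d) {
  seen <- logical(d)
  for (k in seq_along(v)) {
    if (seen[v[k]]) {
      free <- which(!seen)
      v[k] <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
    }
    seen[v[k]] <- TRUE
  }
  v
}

#' DE mutation with scaling (range wrap) and duplicate repair
#'
#' For a target slot `j`, three mutually distinct donor slots `a`, `b`, `c`
#' (all != j) are drawn and the trial vector is
#' `v_c[k] + floor(F * (v_a[k] - v_b[k]))` per element, wrapped back into
#' `[1, d]` by repeatedly adding/subtracting `d`, then repaired to restore
#' index distinctness. Uses the ambient RNG (seeded by [run_de()]).
#'
#' @param pop list of candidate vectors.
#' @param j target slot in `[1, length(pop)]`.
#' @param F mutation factor.
#' @param d number of miRNAs.
#' @param donors optional `c(a, b, c)` slot override (for deterministic
#'   study of the operator); normally drawn uniformly.
#' @return integer trial vector satisfying the candidate invariants.
#' @export
mutate_scale <- function(pop, j, F, d, donors = NULL) {
  I <- length(pop)
  if (I < 4) stopf("mutation needs a population of >= 4")
  if (is.null(donors)) {
    donors <- sample(setdiff(seq_len(I), j), 3L)
  }
  a <- donors[1]; b <- donors[2]; c <- donors[3]
  trial <- pop[[c]] + as.integer(floor(F * (pop[[a]] - pop[[b]])))
  repair_duplicates(as.integer(wrap_index(trial, d)), d)
}

#' DE crossover
#'
#' Element `k` keeps the trial value when the `k`-th uniform draw is
#' `<= Cr`, otherwise the target's value is restored; duplicate repair is
#' re-applied afterwards. Uses the ambient RNG.
#'
#' @param trial integer trial vector (from [mutate_scale()]).
#' @param target integer target vector of the same length.
#' @param Cr crossover rate in `[0, 1]`.
#' @param d number of miRNAs.
#' @return integer vector satisfying the candidate invariants.
#' @export
crossover <- function(trial, target, Cr, d) {
  if (length(trial) != length(target)) stopf("trial/target length mismatch")
  keep <- stats::runif(length(trial)) <= Cr
  out <- ifelse(keep, trial, target)
  repair_duplicates(as.integer(out), d)
}

#' DE selection: strict-improvement survivor rule
#'
#' The trial replaces the target only when its fitness is strictly greater;
#' ties keep the target.
#'
#' @param trial,target lists with elements `indices` and `fitness`.
#' @return The surviving list.
#' @export
select_survivor <- function(trial, target) {
  if (is.null(trial$fitness) || is.null(target$fitness))
    stopf("both fitnesses must be computed before selection")
  if (trial$fitness > target$fitness) trial else target
}

#' DE elitism
#'
#' If the best candidate of the previous generation beats the worst of the
#' next one (strictly), that worst slot is replaced by a copy of the
#' previous best; otherwise the population is unchanged.
#'
#' @param prev_best list with `indices` and `fitness`.
#' @param next_pop list of such lists (all fitnesses computed).
#' @return The (possibly modified) population.
#' @export
apply_elitism <- function(prev_best, next_pop) {
  fits <- vapply(next_pop, `[[`, numeric(1), "fitness")
  worst <- which.min(fits)
  if (prev_best$fitness > fits[worst]) next_pop[[worst]] <- prev_best
  next_pop
}

#' Run one differential-evolution feature-selection search
#'
#' Initializes a population of candidate index vectors, evaluates their
#' fitness (cross-validated SVM accuracy on the component-enhanced columns),
#' and iterates mutation, crossover, strict selection, and elitism for
#' `cfg$generations` generations. Trial fitness is evaluated exactly once
#' per target per generation, so the number of trial evaluations is
#' `pop_size * generations` (plus `pop_size` for the initial population,
#' counted separately).
#'
#' @param E an [expression_matrix()].
#' @param enc a `component_encoder` fitted on `E` with `n == cfg$n`.
#' @param cfg a [de_config()].
#' @param clf a [classifier_config()].
#' @param seed run seed (defaults to `cfg$seed`).
#' @param fitness_fn fitness oracle `function(E, v, enc, clf, cache)`;
#'   defaults to [fitness()]. Injectable for operator studies with a stub.
#' @return list with `best` (`indices`, `fitness`), `history` (best fitness
#'   per generation, length `generations + 1` including the initial one,
#'   non-decreasing), `population`, `n_trial_evals`, `n_init_evals`, `seed`.
#' @export
run_de <- function(E, enc, cfg = de_config(), clf = classifier_config(),
                   seed = cfg$seed, fitness_fn = fitness) {
  d <- length(E$feature_names)
  cache <- new.env(parent = emptyenv())
  n_trial <- 0L
  with_seed(seed, {
    pop <- lapply(init_population(d, cfg, seed = NULL), function(v)
      list(indices = v, fitness = fitness_fn(E, v, enc, clf, cache)))
    history <- max(vapply(pop, `[[`, numeric(1), "fitness"))
    for (g in seq_len(cfg$generations)) {
      prev_best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "fitness"))]]
      raw <- lapply(pop, `[[`, "indices")
      nxt <- vector("list", cfg$pop_size)
      for (j in seq_len(cfg$pop_size)) {
        tr <- mutate_scale(raw, j, cfg$mutation_factor, d)
        tr <- crossover(tr, raw[[j]], cfg$crossover_rate, d)
        trial <- list(indices = tr, fitness = fitness_fn(E, tr, enc, clf, cache))
        n_trial <- n_trial + 1L
        nxt[[j]] <- select_survivor(trial, pop[[j]])
      }
      pop <- apply_elitism(prev_best, nxt)
      history <- c(history, max(vapply(pop, `[[`, numeric(1), "fitness")))
    }
    best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "fitness"))]]
    list(best = best, history = history, population = pop,
         n_trial_evals = n_trial, n_init_evals = cfg$pop_size, seed = seed)
  })
}
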