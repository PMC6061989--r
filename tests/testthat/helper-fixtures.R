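# Fixtures built in code, shared across test files.

# Tiny deterministic expression matrix with an obvious two-class structure.
toy_expression <- function(s_per_class = 10, d = 6, shift = 3, seed = 42) {
  set.seed(seed)
  s <- 2 * s_per_class
  vals <- matrix(rnorm(s * d, mean = 8, sd = 1), s, d)
  labels <- rep(c("tumor", "control"), each = s_per_class)
  vals[labels == "tumor", 1:2] <- vals[labels == "tumor", 1:2] + shift
  expression_matrix(vals, sprintf("S%02d", 1:s), sprintf("mir-%04d", 1:d),
                    labels)
}

# Deterministic stub fitness for DE operator studies: a fixed, non-trivial
# landscape over index sets that needs no classifier.
stub_fitness <- function(E, v, enc, clf, cache) {
  (mean(sin(sort(v))) + 1) / 2
}

# Rank-based empirical AUC oracle (independent of the package's rank_auc).
empirical_auc <- function(x, positive) {
  pos <- x[positive]; neg <- x[!positive]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Memoised heavyweight fixture: the planted-recovery pipeline runs used by
# the recovery and stability acceptance checks. Computed once per session.
recovery_runs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    res <- lapply(c(11L, 12L, 13L), function(data_seed) {
      sim <- generate_synthetic(synthetic_spec(seed = data_seed))
      E <- as_expression_matrix(sim)
      run <- select_panel(
        E,
        de_config(n = 10, pop_size = 12, generations = 20, runs = 10,
                  seed = data_seed + 100L),
        classifier_config(), encoder = "kpca", kernel_width = 0.02)
      list(sim = sim, run = run,
           recovery = planted_recovery(run$report$panel, sim$truth))
    })
    cache <<- res
    res
  }
})
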