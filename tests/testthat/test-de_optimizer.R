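test_that("initial populations are uniform draws of distinct indices", {
  cfg <- de_config(n = 5, pop_size = 10, seed = 3)
  pop <- init_population(20, cfg)
  expect_length(pop, 10)
  for (v in pop) {
    expect_length(v, 5)
    expect_false(anyDuplicated(v) > 0)
    expect_true(all(v >= 1 & v <= 20))
  }
  expect_identical(pop, init_population(20, cfg))
  # pigeonhole: d == n forces every vector to be a permutation of 1..n
  cfg2 <- de_config(n = 4, pop_size = 6, seed = 1)
  for (v in init_population(4, cfg2)) expect_setequal(v, 1:4)
  expect_error(init_population(3, cfg2), "exceeds")
})

test_that("mutation follows base + floor(F * difference) with range wrapping", {
  # single-element vectors with fixed donor slots: 5 + floor(1*(9-3)) = 11 -> 1
  pop <- lapply(c(1, 2, 3, 4, 9, 5), function(x) x)  # slots hold values
  pop <- list(7L, 2L, 3L, 4L, 9L, 5L)
  # donors c(a, b, c): values a=9 (slot 5), b=3 (slot 3), c=5 (slot 6)
  out <- mutate_scale(pop, j = 1, F = 1, d = 10, donors = c(5L, 3L, 6L))
  expect_identical(out, 1L)  # 5 + floor(6) = 11, wraps to 1
  out2 <- mutate_scale(list(7L, 2L, 4L, 10L, 9L, 5L), j = 5, F = 0.5, d = 10,
                       donors = c(2L, 3L, 1L))  # 7 + floor(0.5*(2-4)) = 6
  expect_identical(out2, 6L)
  # F = 0 degenerates to v_c (already valid, so repair is a no-op)
  pop3 <- init_population(15, de_config(n = 4, pop_size = 6, seed = 8))
  out3 <- mutate_scale(pop3, j = 2, F = 0, d = 15, donors = c(1L, 3L, 5L))
  expect_identical(out3, pop3[[5]])
  # wrapping iterates when the offset exceeds d
  expect_identical(panelDE:::wrap_index(-7L, 5L), 3L)
  expect_identical(panelDE:::wrap_index(13L, 5L), 3L)
})

test_that("mutation output always satisfies the candidate invariants", {
  set.seed(5)
  for (rep in 1:50) {
    d <- sample(6:30, 1)
    cfg <- de_config(n = sample(2:min(6, d), 1), pop_size = 8, seed = rep)
    pop <- init_population(d, cfg)
    out <- mutate_scale(pop, sample(8, 1), runif(1, 0, 2), d)
    expect_length(out, cfg$n)
    expect_false(anyDuplicated(out) > 0)
    expect_true(all(out >= 1 & out <= d))
  }
})

test_that("crossover keeps trial elements with probability Cr", {
  set.seed(7)
  trial <- 1:10; target <- 11:20
  expect_identical(crossover(trial, target, Cr = 1, d = 20), trial)
  expect_identical(crossover(trial, target, Cr = 0, d = 20), target)
  # Monte-Carlo over many positions: kept fraction ~ Cr
  n <- 10000L
  kept <- sum(crossover(seq_len(n), seq_len(n) + n, Cr = 0.8, d = 2L * n)
              <= n)
  expect_lt(abs(kept / n - 0.8), 0.02)
  expect_error(crossover(1:3, 1:4, 0.5, 10), "mismatch")
})

test_that("selection applies the strict-improvement rule; ties keep the target", {
  t90 <- list(indices = 1:3, fitness = 0.90)
  t80 <- list(indices = 4:6, fitness = 0.80)
  expect_identical(select_survivor(t90, t80), t90)
  expect_identical(select_survivor(t80, t90), t90)
  tie <- list(indices = 7:9, fitness = 0.80)
  expect_identical(select_survivor(tie, t80), t80)
  expect_error(select_survivor(list(indices = 1:3), t80), "fitness")
})

test_that("elitism replaces the worst slot only on strict improvement", {
  pop <- list(list(indices = 1:2, fitness = 0.60),
              list(indices = 3:4, fitness = 0.70),
              list(indices = 5:6, fitness = 0.80))
  best <- list(indices = 7:8, fitness = 0.95)
  out <- apply_elitism(best, pop)
  expect_identical(out[[1]], best)
  expect_identical(out[2:3], pop[2:3])
  weak <- list(indices = 7:8, fitness = 0.50)
  expect_identical(apply_elitism(weak, pop), pop)
  tie <- list(indices = 7:8, fitness = 0.60)
  expect_identical(apply_elitism(tie, pop), pop)
  # re-inserting a vector already present changes no fitness values
  again <- apply_elitism(pop[[3]], pop)
  expect_equal(sort(vapply(again, `[[`, numeric(1), "fitness")),
               c(0.70, 0.80, 0.80))
})

test_that("run_de keeps its contracts across seeds (stub fitness)", {
  E <- toy_expression(s_per_class = 5, d = 12)
  enc <- fit_pca(E, 4)
  cfg <- de_config(n = 4, pop_size = 6, generations = 8, seed = 1)
  for (seed in 1:20) {
    res <- run_de(E, enc, cfg, classifier_config(), seed = seed,
                  fitness_fn = stub_fitness)
    expect_length(res$history, cfg$generations + 1)
    expect_true(all(diff(res$history) >= 0))
    expect_length(res$population, cfg$pop_size)
    for (m in res$population) {
      expect_length(m$indices, 4)
      expect_false(anyDuplicated(m$indices) > 0)
      expect_true(all(m$indices >= 1 & m$indices <= 12))
    }
    expect_equal(res$n_trial_evals, cfg$pop_size * cfg$generations)
  }
})

test_that("run_de is deterministic given a seed and degenerates at phi = 0", {
  E <- toy_expression(s_per_class = 5, d = 12)
  enc <- fit_pca(E, 4)
  cfg <- de_config(n = 4, pop_size = 6, generations = 5, seed = 2)
  a <- run_de(E, enc, cfg, classifier_config(), seed = 9,
              fitness_fn = stub_fitness)
  b <- run_de(E, enc, cfg, classifier_config(), seed = 9,
              fitness_fn = stub_fitness)
  expect_identical(a$best, b$best)
  expect_identical(a$history, b$history)

  cfg0 <- de_config(n = 4, pop_size = 6, generations = 0, seed = 2)
  r0 <- run_de(E, enc, cfg0, classifier_config(), seed = 9,
               fitness_fn = stub_fitness)
  expect_length(r0$history, 1)
  expect_equal(r0$n_trial_evals, 0)
  fits <- vapply(r0$population, `[[`, numeric(1), "fitness")
  expect_equal(r0$best$fitness, max(fits))
})
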