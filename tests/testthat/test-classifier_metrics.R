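test_that("well-separated blobs classify nearly perfectly; permuted labels do not", {
  set.seed(8)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- rep(c("tumor", "control"), each = 50)
  X[y == "tumor", ] <- X[y == "tumor", ] + 6
  clf <- classifier_config(seed = 3)
  expect_gt(cv_accuracy(X, y, clf), 0.95)
  yperm <- sample(y)
  acc0 <- cv_accuracy(matrix(rnorm(100 * 4), 100, 4), yperm, clf)
  expect_lt(abs(acc0 - 0.5), 0.1)
})

test_that("cross-validation is deterministic and column-permutation invariant", {
  set.seed(1)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- rep(c("tumor", "control"), 30)
  X[y == "tumor", 1] <- X[y == "tumor", 1] + 1
  clf <- classifier_config(seed = 11)
  expect_identical(cv_accuracy(X, y, clf), cv_accuracy(X, y, clf))
  expect_equal(cv_accuracy(X[, c(4, 2, 5, 1, 3)], y, clf),
               cv_accuracy(X, y, clf))
})

test_that("stratified folds keep both classes; unstratified can be refused", {
  y <- c(rep("tumor", 55), rep("control", 5))
  X <- matrix(rnorm(60 * 3), 60, 3)
  acc <- cv_accuracy(X, y, classifier_config(folds = 5, seed = 1))
  expect_true(acc >= 0 && acc <= 1)
  # with folds == minority count, some unstratified splits starve a class
  bad <- classifier_config(folds = 10, stratified = FALSE, seed = 4)
  err <- tryCatch(cv_accuracy(matrix(rnorm(12 * 2), 12, 2),
                              c(rep("tumor", 11), "control"), bad),
                  error = conditionMessage)
  expect_match(err, "stratification")
})

test_that("fitness is a set function of the indices and memoises by set", {
  E <- toy_expression(s_per_class = 10, d = 6)
  enc <- fit_pca(E, 3)
  clf <- classifier_config(seed = 5)
  cache <- new.env()
  f1 <- fitness(E, c(1, 5, 3), enc, clf, cache)
  f2 <- fitness(E, c(3, 1, 5), enc, clf, cache)
  expect_identical(f1, f2)
  expect_length(ls(cache), 1L)
  expect_true(f1 >= 0 && f1 <= 1)
})

test_that("panels of discriminative features out-score random panels", {
  # needs enough null features that the encoder scores stay class-diluted;
  # at small d the leading components absorb the planted shift and the
  # enhanced view of any panel classifies well (see the methods vignette)
  sim <- generate_synthetic(synthetic_spec(seed = 19))
  E <- as_expression_matrix(sim)
  enc <- fit_kpca(E, 10, kernel_width = 0.02)
  clf <- classifier_config(seed = 9)
  f_planted <- fitness(E, sim$truth$planted, enc, clf)
  set.seed(4)
  f_random <- mean(replicate(3, fitness(
    E, sample(setdiff(1:200, sim$truth$planted), 10), enc, clf)))
  expect_gt(f_planted, f_random)
})

test_that("metrics match brute-force confusion-matrix formulas", {
  # perfect prediction attains the AS upper bound
  y <- rep(c("tumor", "control"), each = 5)
  m <- compute_metrics(y, y, c(rep(1, 5), rep(-1, 5)))
  expect_equal(m$accuracy, 1); expect_equal(m$f_measure, 1)
  expect_equal(m$mcc, 1); expect_equal(m$auc, 1)
  expect_equal(m$aggregated_score, 4.0)

  # all-tumor prediction on a balanced set: MCC takes the 0 convention
  pred <- rep("tumor", 10)
  m2 <- compute_metrics(y, pred, seq(0.1, 1, 0.1))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$mcc, 0)
  expect_equal(m2$f_measure, 2 * 5 / (2 * 5 + 5 + 0))
  expect_equal(m2$aggregated_score,
               m2$accuracy + m2$f_measure + 0.5 + m2$auc)

  # a mixed confusion table, against the raw formulas
  tp <- 50; tn <- 40; fp <- 10; fn <- 5
  yt <- c(rep("tumor", tp + fn), rep("control", tn + fp))
  yp <- c(rep("tumor", tp), rep("control", fn),
          rep("control", tn), rep("tumor", fp))
  sc <- ifelse(yp == "tumor", 1, -1)
  m3 <- compute_metrics(yt, yp, sc)
  expect_equal(m3$accuracy, (tp + tn) / 105)
  expect_equal(m3$f_measure, 2 * tp / (2 * tp + fp + fn))
  expect_equal(m3$mcc,
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  expect_equal(m3$mcc, 0.7156, tolerance = 1e-4)
})

test_that("MCC is symmetric under a simultaneous class swap", {
  set.seed(6)
  yt <- sample(c("tumor", "control"), 40, replace = TRUE, prob = c(0.6, 0.4))
  yp <- sample(c("tumor", "control"), 40, replace = TRUE)
  if (length(unique(yt)) < 2) yt[1:2] <- c("tumor", "control")
  swap <- function(z) ifelse(z == "tumor", "control", "tumor")
  m <- compute_metrics(yt, yp, rnorm(40))
  ms <- compute_metrics(swap(yt), swap(yp), rnorm(40))
  expect_equal(m$mcc, ms$mcc)
})

test_that("AUC equals the trapezoidal ROC area (pROC cross-check)", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (rep in 1:3) {
    y <- sample(c("tumor", "control"), 50, replace = TRUE)
    if (length(unique(y)) < 2) next
    sc <- rnorm(50) + (y == "tumor")
    m <- compute_metrics(y, y, sc)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = sc, levels = c("control", "tumor"),
      direction = "<", quiet = TRUE)))
    expect_equal(m$auc, ref, tolerance = 1e-12)
  }
})

test_that("the aggregated score stays in [0, 4] over random confusion tables", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    yt <- sample(c("tumor", "control"), n, replace = TRUE)
    if (length(unique(yt)) < 2) yt[1:2] <- c("tumor", "control")
    yp <- sample(c("tumor", "control"), n, replace = TRUE)
    m <- compute_metrics(yt, yp, rnorm(n))
    expect_gte(m$aggregated_score, 0)
    expect_lte(m$aggregated_score, 4)
  }
  expect_error(compute_metrics(rep("tumor", 4), rep("tumor", 4), rnorm(4)),
               "single class")
})
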