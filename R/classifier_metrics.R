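#' Classifier configuration for the cross-validated SVM fitness
#'
#' An RBF-kernel support vector machine with fixed hyper-parameters
#' (`gamma = 0.5`, `cost = 2.0`) evaluated by 10-fold cross-validation is
#' the fitness oracle of the whole selection procedure. Folds are stratified
#' by class by default because pooled-control designs are imbalanced and
#' unstratified folds can end up single-class.
#'
#' @param gamma RBF kernel width coefficient, > 0.
#' @param cost soft-margin trade-off C, > 0.
#' @param folds number of cross-validation folds, >= 2.
#' @param stratified stratify folds by class (default `TRUE`).
#' @param seed integer seed controlling fold assignment.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(gamma = 0.5, cost = 2.0, folds = 10L,
                              stratified = TRUE, seed = 1L) {
  if (gamma <= 0 || cost <= 0) stopf("gamma and cost must be > 0")
  if (folds < 2) stopf("need at least 2 folds")
  structure(list(gamma = gamma, cost = cost, folds = as.integer(folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "classifier_config")
}

# Deterministic fold assignment. Stratified: shuffle within each class and
# deal round-robin, so every fold's class mix matches the cohort's.
make_folds <- function(labels, clf) {
  s <- length(labels)
  if (clf$folds > s) stopf("more folds (%d) than samples (%d)", clf$folds, s)
  with_seed(clf$seed, {
    fold <- integer(s)
    if (clf$stratified) {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        fold[idx[sample.int(length(idx))]] <-
          rep_len(seq_len(clf$folds), length(idx))
      }
    } else {
      fold[sample.int(s)] <- rep_len(seq_len(clf$folds), s)
    }
    fold
  })
}

# Column standardization from training-fold statistics; constant columns
# are left unscaled (sd guard) so degenerate panels never produce NaNs.
scale_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, `/`),
       test = sweep(sweep(test, 2, mu), 2, sd, `/`))
}

#' Cross-validated RBF-SVM accuracy
#'
#' Mean over folds of the per-fold test accuracy of an RBF-kernel SVM.
#' Features are standardized with training-fold statistics inside each fold
#' (libsvm's recommended practice); fold assignment is deterministic given
#' the config seed.
#'
#' @param X numeric matrix, samples x features.
#' @param labels per-sample factor (or coercible) with both classes present.
#' @param clf a [classifier_config()].
#' @return Mean accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(X, labels, clf = classifier_config()) {
  mean(cv_predict(X, labels, clf)$fold_accuracy)
}

#' Cross-validated predictions of the RBF-SVM
#'
#' Runs the same cross-validation as [cv_accuracy()] but returns the pooled
#' out-of-fold predictions and decision values, as needed to compute the
#' full evaluation metrics of a finished panel.
#'
#' @inheritParams cv_accuracy
#' @return list with `pred` (factor), `score` (decision values oriented so
#'   larger means more tumor-like), `fold` (fold ids) and `fold_accuracy`.
#' @export
cv_predict <- function(X, labels, clf = classifier_config()) {
  X <- as.matrix(X)
  labels <- coerce_labels(labels)
  if (nlevels(droplevels(labels)) < 2) stopf("both classes must be present")
  fold <- make_folds(labels, clf)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  score <- numeric(length(labels))
  facc <- numeric(clf$folds)
  for (f in seq_len(clf$folds)) {
    te <- fold == f
    ytr <- droplevels(labels[!te])
    if (nlevels(ytr) < 2)
      stopf("fold %d has a single training class; enable stratification", f)
    sc <- scale_train_test(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    fit <- e1071::svm(sc$train, factor(labels[!te], levels = levels(labels)),
                      kernel = "radial", gamma = clf$gamma, cost = clf$cost,
                      scale = FALSE)
    pr <- stats::predict(fit, sc$test, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # libsvm's decision value is positive for the first class of the pair
    # named in the column label; flip so that larger always means "tumor"
    if (grepl("^control/", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
    pred[te] <- pr
    score[te] <- dv
    facc[f] <- mean(pr == labels[te])
  }
  list(pred = pred, score = score, fold = fold, fold_accuracy = facc)
}

#' DE fitness of a candidate panel
#'
#' The fitness of a candidate index vector is the cross-validated SVM
#' accuracy of the component-enhanced matrix of its columns. Because the
#' evolutionary search revisits index sets, results may be memoised in an
#' environment keyed by the sorted index set (order within the vector does
#' not change the fitness).
#'
#' @param E an [expression_matrix()].
#' @param v integer panel indices.
#' @param enc a `component_encoder` fitted on `E` with `n == length(v)`.
#' @param clf a [classifier_config()].
#' @param cache optional environment used to memoise fitness by index set.
#' @return Fitness in `[0, 1]`.
#' @export
fitness <- function(E, v, enc, clf = classifier_config(), cache = NULL) {
  key <- paste(sort(as.integer(v)), collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  val <- cv_accuracy(enhance(E, v, enc), E$labels, clf)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Classification metrics and the aggregated score
#'
#' Computes accuracy, F-measure (positive class = tumor), the Matthews
#' correlation coefficient (0 when its denominator vanishes), and the
#' trapezoidal ROC AUC from real-valued decision scores, then combines them
#' into a single aggregated score
#' `AS = accuracy + F + (MCC + 1)/2 + AUC`, bounded in `[0, 4]`. MCC enters
#' rescaled to `[0, 1]` so the bound holds exactly; the raw MCC is reported
#' alongside.
#'
#' @param y_true,y_pred true and predicted classes (factors or 0/1, positive
#'   class `tumor`); `y_true` must contain both classes.
#' @param decision_scores real-valued scores, larger = more tumor-like.
#' @return An object of class `metrics_bundle`: `accuracy`, `f_measure`,
#'   `mcc`, `auc`, `aggregated_score`.
#' @export
compute_metrics <- function(y_true, y_pred, decision_scores) {
  y_true <- coerce_labels(y_true)
  y_pred <- coerce_labels(y_pred)
  if (length(y_true) != length(y_pred) ||
      length(y_true) != length(decision_scores))
    stopf("y_true, y_pred and decision_scores must have equal length")
  if (nlevels(droplevels(y_true)) < 2)
    stopf("y_true has a single class; AUC undefined")
  tp <- sum(y_true == "tumor" & y_pred == "tumor")
  tn <- sum(y_true == "control" & y_pred == "control")
  fp <- sum(y_true == "control" & y_pred == "tumor")
  fn <- sum(y_true == "tumor" & y_pred == "control")
  acc <- (tp + tn) / length(y_true)
  f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  auc <- rank_auc(decision_scores, y_true == "tumor")
  structure(list(accuracy = acc, f_measure = f, mcc = mcc, auc = auc,
                 aggregated_score = acc + f + (mcc + 1) / 2 + auc),
            class = "metrics_bundle")
}

# Mann-Whitney form of the ROC AUC (ties counted 1/2); identical to the
# trapezoidal area under the empirical ROC curve.
rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | F %.4f | MCC %.4f | AUC %.4f | aggregated score %.4f\n",
    x$accuracy, x$f_measure, x$mcc, x$auc, x$aggregated_score))
  invisible(x)
}
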