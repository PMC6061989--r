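#' Component-analysis encoders for expression enhancement
#'
#' The selection fitness is not computed on the raw selected columns
#' `E(v)` but on an enhanced matrix that blends them with an `s x n`
#' component-score matrix of the whole dataset, so that candidate panels are
#' judged in a representation that retains the global covariance structure
#' while emphasising the selected miRNAs. The score matrix is computed once
#' per dataset (PCA or RBF-kernel PCA) and reused across all fitness calls.
#'
#' @name component_encoder
NULL

new_encoder <- function(method, scores, extra = list()) {
  # deterministic sign convention: the largest-|.| entry of each score
  # column is made positive, so results do not depend on the eigen backend
  for (k in seq_len(ncol(scores))) {
    m <- which.max(abs(scores[, k]))
    if (scores[m, k] < 0) {
      scores[, k] <- -scores[, k]
      if (!is.null(extra$rotation)) extra$rotation[, k] <- -extra$rotation[, k]
    }
  }
  colnames(scores) <- sprintf("C%d", seq_len(ncol(scores)))
  structure(c(list(method = method, scores = scores,
                   n_components = ncol(scores)), extra),
            class = "component_encoder")
}

#' @export
print.component_encoder <- function(x, ...) {
  cat(sprintf("component_encoder: %s, %d samples x %d components\n",
              x$method, nrow(x$scores), x$n_components))
  invisible(x)
}

#' Fit a PCA encoder
#'
#' Columns of the expression matrix are centred and the sample projections
#' onto the top `n` principal axes are stored as the score matrix.
#'
#' @param E an [expression_matrix()].
#' @param n number of components, `1 <= n <= rank(centred E)`.
#' @return A `component_encoder` with fields `scores` (s x n),
#'   `explained_variance_ratio` (relative to total variance), `center` and
#'   `rotation` (for re-projection).
#' @export
fit_pca <- function(E, n) {
  stopifnot(inherits(E, "expression_matrix"))
  X <- E$values
  if (n < 1 || n > min(dim(X)))
    stopf("n must be in [1, %d]", min(dim(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-9)
  if (n > rank)
    stopf("n = %d exceeds the rank of the centred matrix (%d)", n, rank)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  new_encoder("pca", pc$x[, seq_len(n), drop = FALSE],
              list(explained_variance_ratio = evr[seq_len(n)],
                   center = pc$center,
                   rotation = pc$rotation[, seq_len(n), drop = FALSE]))
}

#' Fit an RBF kernel-PCA encoder
#'
#' Kernel PCA with the Gaussian kernel
#' `k(x, x') = exp(-kernel_width * ||x - x'||^2)` on the double-centred
#' kernel matrix. `kernel_width` is the inverse-width coefficient; small
#' values give a wide, near-linear kernel (in which regime the scores agree
#' with PCA up to scale), large values a narrow one. The default `1/d` is
#' the usual scale-free choice.
#'
#' @param E an [expression_matrix()].
#' @param n number of components.
#' @param kernel_width RBF coefficient, > 0.
#' @return A `component_encoder` with field `kernel_width`.
#' @export
fit_kpca <- function(E, n, kernel_width = 1 / ncol(E$values)) {
  stopifnot(inherits(E, "expression_matrix"))
  X <- E$values
  if (n < 1 || n > nrow(X)) stopf("n must be in [1, %d]", nrow(X))
  if (kernel_width <= 0) stopf("kernel_width must be > 0")
  if (all(stats::dist(X[seq_len(min(nrow(X), 50L)), , drop = FALSE]) < 1e-12))
    stopf("degenerate kernel: all samples identical")
  kp <- kernlab::kpca(X, kernel = "rbfdot",
                      kpar = list(sigma = kernel_width), features = n)
  sc <- kernlab::rotated(kp)
  if (ncol(sc) < n)
    stopf("kernel matrix supports only %d components (requested %d)", ncol(sc), n)
  new_encoder("kpca", sc[, seq_len(n), drop = FALSE],
              list(kernel_width = kernel_width))
}

#' Choose between the PCA and KPCA encoders empirically
#'
#' Fits both encoders, scores each by the cross-validated SVM accuracy of
#' its own score matrix (same folds, same seed), and returns the
#' higher-accuracy encoder; an exact tie goes to PCA. The two accuracies are
#' attached as the `selection_log` attribute.
#'
#' @param E an [expression_matrix()].
#' @param n number of components.
#' @param clf a [classifier_config()].
#' @param kernel_width passed to [fit_kpca()].
#' @return The chosen `component_encoder`.
#' @export
choose_encoder <- function(E, n, clf = classifier_config(),
                           kernel_width = 1 / ncol(E$values)) {
  pca <- fit_pca(E, n)
  kpca <- fit_kpca(E, n, kernel_width)
  acc_pca <- cv_accuracy(pca$scores, E$labels, clf)
  acc_kpca <- cv_accuracy(kpca$scores, E$labels, clf)
  chosen <- if (acc_kpca > acc_pca) kpca else pca
  attr(chosen, "selection_log") <- list(pca_accuracy = acc_pca,
                                        kpca_accuracy = acc_kpca,
                                        chosen = chosen$method)
  chosen
}

#' Enhance selected expression columns with the component scores
#'
#' Forms the enhanced matrix whose entry `[i, k]` is the product of sample
#' `i`'s expression of the `k`-th selected miRNA and its `k`-th component
#' score (Hadamard product of `E(v)` with the score matrix). This keeps one
#' row per sample — so cross-validation folds remain meaningful — while
#' every entry carries both the global component structure and the selected
#' miRNA's signal. `mode = "gram"` instead returns `E(v) %*% t(scores)`
#' (s x s Gram-like features), provided as a documented alternative reading
#' of the same construction.
#'
#' @param E an [expression_matrix()].
#' @param v integer panel indices, `length(v) == n_components`.
#' @param enc a `component_encoder` fitted on `E`.
#' @param mode `"hadamard"` (default) or `"gram"`.
#' @return numeric matrix with `s` rows.
#' @export
enhance <- function(E, v, enc, mode = c("hadamard", "gram")) {
  mode <- match.arg(mode)
  stopifnot(inherits(enc, "component_encoder"))
  if (length(v) != enc$n_components)
    stopf("panel length %d != encoder components %d", length(v), enc$n_components)
  Ev <- select_columns(E, v)
  if (nrow(Ev) != nrow(enc$scores))
    stopf("encoder was fitted on a different number of samples")
  out <- switch(mode,
                hadamard = Ev * enc$scores,
                gram = Ev %*% t(enc$scores))
  if (any(!is.finite(out))) stopf("non-finite enhanced values")
  out
}

#' Serialize / restore an encoder as JSON
#'
#' @param enc a `component_encoder`.
#' @param path output path.
#' @return `path` (write) or a `component_encoder` (read).
#' @export
write_encoder <- function(enc, path) {
  stopifnot(inherits(enc, "component_encoder"))
  jsonlite::write_json(unclass(enc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scores <- matrix(as.numeric(obj$scores), ncol = obj$n_components)
  extra <- obj[setdiff(names(obj),
                       c("method", "scores", "n_components"))]
  if (!is.null(extra$rotation))
    extra$rotation <- matrix(as.numeric(extra$rotation), ncol = obj$n_components)
  new_encoder(obj$method, scores, extra)
}
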