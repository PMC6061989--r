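#' Cosine-similarity cluster diagnostics for a panel
#'
#' Homogeneity of a class is the mean pairwise cosine similarity over all
#' unordered within-class sample pairs (self-pairs excluded); separation is
#' the mean cosine similarity over all tumor-control pairs. Because these
#' are similarities (not distances), a good class structure shows high
#' homogeneity and low separation; comparable values indicate that the
#' within-class relationships are not simple linear groupings.
#'
#' @name cluster_quality
NULL

cosine_matrix <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm < 1e-12)) stopf("zero-norm sample vector")
  tcrossprod(X / nrm)
}

#' Within-class homogeneity
#'
#' @param X numeric matrix, samples x panel features.
#' @param members indices (or logical mask) of the class members, >= 2.
#' @return Mean within-class cosine similarity in `[-1, 1]`.
#' @export
homogeneity <- function(X, members) {
  Xm <- X[members, , drop = FALSE]
  m <- nrow(Xm)
  if (m < 2) stopf("homogeneity needs >= 2 class members")
  S <- cosine_matrix(Xm)
  sum(S[upper.tri(S)]) / (m * (m - 1) / 2)
}

#' Between-class separation
#'
#' @param X numeric matrix, samples x panel features.
#' @param labels per-sample two-class factor (or coercible).
#' @return Mean inter-class cosine similarity in `[-1, 1]`.
#' @export
separation <- function(X, labels) {
  labels <- coerce_labels(labels)
  a <- which(labels == "tumor"); b <- which(labels == "control")
  if (length(a) == 0 || length(b) == 0) stopf("both classes must be present")
  S <- cosine_matrix(X)
  mean(S[a, b, drop = FALSE])
}

#' Cluster-quality report for a panel
#'
#' @param E an [expression_matrix()].
#' @param panel character vector of miRNA names (or integer indices).
#' @return An object of class `cluster_quality_report`:
#'   `homogeneity_tumor`, `homogeneity_control`, `separation`, `panel`.
#' @export
cluster_quality_report <- function(E, panel) {
  stopifnot(inherits(E, "expression_matrix"))
  idx <- if (is.numeric(panel)) as.integer(panel)
         else match(panel, E$feature_names)
  if (any(is.na(idx))) stopf("panel names a miRNA absent from E")
  X <- select_columns(E, idx)
  structure(list(
    homogeneity_tumor = homogeneity(X, E$labels == "tumor"),
    homogeneity_control = homogeneity(X, E$labels == "control"),
    separation = separation(X, E$labels),
    panel = E$feature_names[idx]),
    class = "cluster_quality_report")
}

#' @export
print.cluster_quality_report <- function(x, ...) {
  cat(sprintf(
    "cluster quality (%d-miRNA panel):\n  tumor homogeneity   %.4f\n  control homogeneity %.4f\n  separation          %.4f\n",
    length(x$panel), x$homogeneity_tumor, x$homogeneity_control, x$separation))
  invisible(x)
}
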