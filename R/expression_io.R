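#' Construct an expression matrix object
#'
#' Container for a two-class expression dataset: an `s x d` numeric matrix of
#' log2-scaled reads-per-million values (samples in rows, miRNAs in columns),
#' per-sample class labels, and the sorted static miRNA table that candidate
#' panels index into. Feature columns are always stored in C-locale
#' lexicographic order of their names so that integer index references are
#' stable across runs and platforms.
#'
#' @param values numeric matrix, samples x features, finite entries.
#' @param sample_ids character vector of unique sample identifiers (rows).
#' @param feature_names character vector of unique miRNA names (columns).
#' @param labels per-sample classes: a factor, or a character/integer vector
#'   coercible to the levels `control` (0) and `tumor` (1).
#' @return An object of class `expression_matrix` with elements `values`
#'   (dimnames set), `sample_ids`, `feature_names` and `labels` (factor with
#'   levels `control`, `tumor`).
#' @export
expression_matrix <- function(values, sample_ids, feature_names, labels) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stopf("expression values must be numeric and finite")
  if (nrow(values) != length(sample_ids) || ncol(values) != length(feature_names))
    stopf("values must be %d samples x %d features", length(sample_ids),
          length(feature_names))
  if (anyDuplicated(sample_ids)) stopf("duplicate sample IDs")
  if (anyDuplicated(feature_names)) stopf("duplicate miRNA names")
  labels <- coerce_labels(labels)
  if (length(labels) != length(sample_ids))
    stopf("labels must have one entry per sample")
  ord <- c_order(feature_names)
  values <- values[, ord, drop = FALSE]
  feature_names <- feature_names[ord]
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         feature_names = feature_names, labels = labels),
    class = "expression_matrix")
}

coerce_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stopf("numeric labels must be 0/1")
    labels <- ifelse(labels == 1, "tumor", "control")
  }
  if (!all(labels %in% c("control", "tumor")))
    stopf("labels must be 'tumor' or 'control' (or 1/0)")
  factor(labels, levels = c("control", "tumor"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d miRNAs (%d tumor, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "control")))
  invisible(x)
}

#' Read a two-class expression dataset from TSV files
#'
#' The matrix file follows the common miRNA-seq export layout: one row per
#' miRNA, one column per sample, a header row of sample IDs, and the miRNA
#' name in the first column. The labels file has two columns
#' (`sample_id<TAB>class`) with class `tumor` or `control`. Samples present
#' in the matrix but absent from the labels file are dropped with a warning.
#' Internally the matrix is transposed to samples x features and features are
#' re-ordered lexicographically.
#'
#' @param matrix_path path to the expression TSV (miRNA rows x sample columns).
#' @param labels_path path to the two-column labels TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, labels_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stopf("matrix file needs a name column plus >=1 sample")
  feats <- as.character(raw[[1]])
  if (anyDuplicated(feats)) stopf("duplicated miRNA name in %s", matrix_path)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric expression cells in %s", matrix_path)
  samples <- colnames(mat)
  if (anyDuplicated(samples)) stopf("duplicated sample ID in %s", matrix_path)

  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stopf("labels file needs columns sample_id, class")
  names(lab)[1:2] <- c("sample_id", "class")
  if (anyDuplicated(lab$sample_id)) stopf("duplicated sample ID in %s", labels_path)

  keep <- samples %in% lab$sample_id
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) absent from the label file: %s",
                    sum(!keep), paste(samples[!keep], collapse = ", ")),
            call. = FALSE)
    samples <- samples[keep]
    mat <- mat[, keep, drop = FALSE]
  }
  if (length(samples) == 0) stopf("no labelled samples remain")
  classes <- lab$class[match(samples, lab$sample_id)]
  em <- expression_matrix(t(mat), samples, feats, classes)
  if (nlevels(droplevels(em$labels)) < 2)
    warning("only one class present; classification operations will fail",
            call. = FALSE)
  em
}

#' Write an expression dataset to the TSV dialect read_expression() reads
#'
#' @param E an [expression_matrix()].
#' @param matrix_path,labels_path output paths.
#' @return `E`, invisibly.
#' @export
write_expression <- function(E, matrix_path, labels_path) {
  stopifnot(inherits(E, "expression_matrix"))
  out <- data.frame(miRNA = E$feature_names,
                    t(E$values), check.names = FALSE)
  colnames(out) <- c("miRNA", E$sample_ids)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = E$sample_ids, class = as.character(E$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(E)
}

#' Library-size normalization: counts to log2 reads-per-million
#'
#' Each count is scaled to reads per million within its sample's library and
#' log2-transformed with a +1 pseudocount, `log2(1 + 1e6 * count / library)`,
#' so zero counts map to 0 and all outputs are finite and non-negative.
#'
#' @param counts non-negative count matrix, miRNA rows x sample columns.
#' @param library_sizes per-sample (per-column) positive totals.
#' @return numeric matrix of the same shape, log2-RPM units.
#' @export
normalize_rpm_log2 <- function(counts, library_sizes) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and non-negative")
  if (length(library_sizes) != ncol(counts))
    stopf("need one library size per sample column")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stopf("library sizes must be strictly positive")
  log2(1 + sweep(counts, 2, 1e6 / library_sizes, `*`))
}

#' Select panel columns from an expression matrix
#'
#' @param E an [expression_matrix()].
#' @param v integer vector of distinct 1-based indices into the sorted miRNA
#'   table.
#' @return numeric matrix `s x length(v)`, columns in the order given by `v`.
#' @export
select_columns <- function(E, v) {
  stopifnot(inherits(E, "expression_matrix"))
  d <- ncol(E$values)
  v <- as.integer(v)
  if (length(v) == 0) stopf("empty index vector")
  if (any(v < 1L | v > d)) stopf("index out of range [1, %d]", d)
  if (anyDuplicated(v)) stopf("duplicate panel index")
  E$values[, v, drop = FALSE]
}
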