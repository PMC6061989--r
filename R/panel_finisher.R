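#' Majority-vote aggregation of independent DE runs
#'
#' Counts how often each miRNA is reported across the best vectors of
#' `theta` independent runs and returns the frequency-ranked list R. Sorting
#' is by count descending with ties broken by miRNA name ascending
#' (C-locale), so the ranking is deterministic.
#'
#' @param best_vectors list of integer index vectors (one per run).
#' @param feature_names the sorted miRNA table the indices refer to.
#' @return data.frame with columns `rank`, `feature`, `index`, `count`;
#'   counts sum to `theta * n`.
#' @export
aggregate_runs <- function(best_vectors, feature_names) {
  if (length(best_vectors) == 0) stopf("no runs to aggregate")
  idx <- unlist(best_vectors)
  if (any(idx < 1L | idx > length(feature_names)))
    stopf("run vector index outside the miRNA table")
  tab <- table(factor(feature_names[idx], levels = feature_names))
  tab <- tab[tab > 0]
  nm <- names(tab)
  ord <- order(-as.integer(tab), nm, method = "radix")
  data.frame(rank = seq_along(ord), feature = nm[ord],
             index = match(nm[ord], feature_names),
             count = as.integer(tab)[ord], row.names = NULL)
}

#' Size the final panel by a prefix-accuracy scan
#'
#' For each prefix of the ranked list R, the 10-fold cross-validated SVM
#' accuracy of the raw expression columns of that prefix is computed; the
#' shortest prefix attaining the maximum accuracy becomes the final panel.
#' Raw (not component-enhanced) columns are used so the finished panel
#' stands alone as a diagnostic, independent of the dataset-specific
#' encoder; `enhanced = TRUE` switches to the encoder view.
#'
#' @param E an [expression_matrix()].
#' @param R ranked data.frame from [aggregate_runs()].
#' @param clf a [classifier_config()].
#' @param enhanced evaluate prefixes on the component-enhanced matrix
#'   (requires `enc`; prefixes longer than `enc$n_components` fall back to
#'   raw columns).
#' @param enc encoder, only used when `enhanced = TRUE`.
#' @param scorer optional override `function(indices) -> accuracy` replacing
#'   the cross-validated SVM (for operator studies).
#' @return An object of class `panel_report`: `entries` (R with a
#'   `prefix_accuracy` column), `prefix_accuracies`, `selected_size`,
#'   `panel` (feature names), `k`.
#' @export
finish_panel <- function(E, R, clf = classifier_config(), enhanced = FALSE,
                         enc = NULL, scorer = NULL) {
  if (nrow(R) == 0) stopf("empty ranked list")
  if (!all(R$feature %in% E$feature_names))
    stopf("ranked list names a miRNA absent from E")
  k <- nrow(R)
  idx <- match(R$feature, E$feature_names)
  if (is.null(scorer)) {
    scorer <- function(v) {
      if (enhanced && !is.null(enc) && length(v) == enc$n_components)
        cv_accuracy(enhance(E, v, enc), E$labels, clf)
      else cv_accuracy(select_columns(E, v), E$labels, clf)
    }
  }
  pref <- vapply(seq_len(k), function(i) scorer(idx[seq_len(i)]), numeric(1))
  selected <- which.max(pref)  # smallest i attaining the maximum
  R$prefix_accuracy <- pref
  structure(list(entries = R, prefix_accuracies = pref,
                 selected_size = selected,
                 panel = R$feature[seq_len(selected)], k = k),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("panel_report: %d of %d reported miRNAs selected (accuracy %.4f)\n",
              x$selected_size, x$k, x$prefix_accuracies[x$selected_size]))
  cat(" ", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Write a panel report as TSV + JSON summary
#'
#' @param report a `panel_report`.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @param extra named list merged into the JSON summary (e.g. analytic
#'   expectations for contrast).
#' @return `report`, invisibly.
#' @export
write_panel_report <- function(report, tsv_path = NULL, json_path = NULL,
                               extra = list()) {
  if (!is.null(tsv_path))
    utils::write.table(report$entries, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    obj <- c(list(panel = report$panel, selected_size = report$selected_size,
                  k = report$k,
                  panel_accuracy = report$prefix_accuracies[report$selected_size]),
             extra)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Random-selection null model: expected number of distinct miRNAs
#'
#' If each of `theta` independent runs drew its `n`-miRNA panel uniformly at
#' random from `d` miRNAs, the expected number reported at least once is
#' `d * (1 - (1 - n/d)^theta)`, and one further run would contribute
#' `d * (1 - n/d)^theta * (n/d)` previously unseen miRNAs in expectation.
#' Observed distinct counts far below this expectation demonstrate that the
#' selection is not a random process.
#'
#' @param d number of miRNAs; `n` panel size per run; `theta` runs.
#' @param n,theta see above.
#' @return An object of class `analytic_expectation`: `d`, `n`, `theta`,
#'   `expected_reported`, `expected_new_next_run`.
#' @export
expected_reported <- function(d, n, theta) {
  if (n < 1 || n > d) stopf("need 1 <= n <= d")
  if (theta < 1) stopf("need theta >= 1")
  q <- (1 - n / d)^theta
  structure(list(d = d, n = n, theta = theta,
                 expected_reported = d * (1 - q),
                 expected_new_next_run = d * q * (n / d)),
            class = "analytic_expectation")
}

#' @export
print.analytic_expectation <- function(x, ...) {
  cat(sprintf(
    "random-selection null (d = %d, n = %d, theta = %d):\n  expected distinct miRNAs reported: %.2f\n  expected new miRNAs in one more run: %.2f\n",
    x$d, x$n, x$theta, x$expected_reported, x$expected_new_next_run))
  invisible(x)
}

#' Monte-Carlo oracle for the random-selection null model
#'
#' Simulates `reps` experiments of `theta` uniform `n`-subsets of `[1, d]`
#' and counts the distinct elements seen, as an independent check of the
#' closed form.
#'
#' @inheritParams expected_reported
#' @param reps number of simulated experiments.
#' @param seed integer seed.
#' @return list with `mean` and `se` (standard error of the mean).
#' @export
monte_carlo_reported <- function(d, n, theta, reps = 500, seed = 1L) {
  if (n < 1 || n > d) stopf("need 1 <= n <= d")
  if (theta < 1 || reps < 1) stopf("need theta >= 1 and reps >= 1")
  counts <- with_seed(seed, vapply(seq_len(reps), function(r) {
    seen <- logical(d)
    for (t in seq_len(theta)) seen[sample.int(d, n)] <- TRUE
    sum(seen)
  }, numeric(1)))
  list(mean = mean(counts),
       se = stats::sd(counts) / sqrt(reps))
}
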