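#' End-to-end biomarker-panel selection
#'
#' Runs the full procedure on an in-memory dataset: choose the component
#' encoder (PCA vs KPCA by cross-validated accuracy, unless forced), run
#' `theta` independent differential-evolution searches with derived
#' sub-seeds, aggregate their best vectors by majority voting, size the
#' final panel by the prefix-accuracy scan, and evaluate the finished panel
#' (full cross-validated metrics plus cosine cluster diagnostics).
#'
#' @param E an [expression_matrix()].
#' @param cfg a [de_config()] (its `runs` and `seed` drive the ensemble).
#' @param clf a [classifier_config()].
#' @param encoder `"auto"`, `"pca"` or `"kpca"`.
#' @param kernel_width passed to [fit_kpca()].
#' @param fitness_fn optional fitness override, see [run_de()].
#' @return An object of class `panel_run` (the run manifest): `config`,
#'   `encoder_method`, `encoder_selection`, `runs` (per-run best vectors,
#'   fitness, seeds), `report` ([finish_panel()] output), `metrics`
#'   ([compute_metrics()] on the pooled cross-validated predictions of the
#'   final panel), `quality` ([cluster_quality_report()]), `expectation`
#'   (the random-selection null for the same `d`, `n`, `theta`),
#'   `n_trial_evals`.
#' @export
select_panel <- function(E, cfg = de_config(), clf = classifier_config(),
                         encoder = c("auto", "pca", "kpca"),
                         kernel_width = 1 / ncol(E$values),
                         fitness_fn = fitness) {
  encoder <- match.arg(encoder)
  enc <- switch(encoder,
                auto = choose_encoder(E, cfg$n, clf, kernel_width),
                pca = fit_pca(E, cfg$n),
                kpca = fit_kpca(E, cfg$n, kernel_width))
  run_seeds <- derive_seeds(cfg$seed, cfg$runs)
  # each independent run is a fully independent stochastic execution: its
  # own DE stream AND its own cross-validation folds. Decorrelating the
  # folds across runs is what lets majority voting cancel features that
  # merely overfit one particular fold split.
  runs <- lapply(seq_len(cfg$runs), function(r) {
    clf_r <- clf; clf_r$seed <- run_seeds[r]
    run_de(E, enc, cfg, clf_r, seed = run_seeds[r], fitness_fn = fitness_fn)
  })
  R <- aggregate_runs(lapply(runs, function(x) x$best$indices),
                      E$feature_names)
  report <- finish_panel(E, R, clf)
  panel_idx <- match(report$panel, E$feature_names)
  cvp <- cv_predict(select_columns(E, panel_idx), E$labels, clf)
  metrics <- compute_metrics(E$labels, cvp$pred, cvp$score)
  quality <- cluster_quality_report(E, report$panel)
  structure(list(
    config = list(de = unclass(cfg), classifier = unclass(clf),
                  encoder = encoder, kernel_width = kernel_width),
    encoder_method = enc$method,
    encoder_selection = attr(enc, "selection_log"),
    runs = lapply(seq_along(runs), function(r) list(
      run = r, seed = run_seeds[r],
      best_indices = runs[[r]]$best$indices,
      best_features = E$feature_names[runs[[r]]$best$indices],
      best_fitness = runs[[r]]$best$fitness,
      history = runs[[r]]$history)),
    report = report, metrics = metrics, quality = quality,
    expectation = expected_reported(length(E$feature_names), cfg$n, cfg$runs),
    n_trial_evals = sum(vapply(runs, `[[`, integer(1), "n_trial_evals"))),
    class = "panel_run")
}

#' @export
print.panel_run <- function(x, ...) {
  cat(sprintf("panel_run: %d DE runs, encoder %s\n",
              length(x$runs), x$encoder_method))
  print(x$report)
  print(x$metrics)
  cat(sprintf("  distinct miRNAs over runs k = %d (random expectation %.2f)\n",
              x$report$k, x$expectation$expected_reported))
  invisible(x)
}

#' File-based pipeline entry point
#'
#' Reads the TSV matrix/labels pair, optionally applies log2-RPM
#' normalization when the matrix holds raw counts, runs [select_panel()],
#' and writes the artifacts (`panel.tsv`, `manifest.json`, `metrics.json`,
#' `quality.json`) to `out_dir`.
#'
#' @param matrix_path,labels_path input TSVs (see [read_expression()]).
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @param normalize treat the matrix as raw counts and normalize columns to
#'   log2 reads-per-million (library size = column sum).
#' @inheritParams select_panel
#' @return The `panel_run` manifest, invisibly.
#' @export
run_pipeline <- function(matrix_path, labels_path, out_dir = NULL,
                         cfg = de_config(), clf = classifier_config(),
                         encoder = c("auto", "pca", "kpca"),
                         normalize = FALSE) {
  E <- read_expression(matrix_path, labels_path)
  if (normalize) {
    counts <- t(E$values)
    E <- expression_matrix(t(normalize_rpm_log2(counts, colSums(counts))),
                           E$sample_ids, E$feature_names,
                           as.character(E$labels))
  }
  manifest <- select_panel(E, cfg, clf, encoder)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_panel_report(manifest$report,
                       tsv_path = file.path(out_dir, "panel.tsv"),
                       json_path = file.path(out_dir, "panel.json"),
                       extra = list(expectation = unclass(manifest$expectation)))
    jsonlite::write_json(serialize_manifest(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(manifest$metrics),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(manifest$quality),
                         file.path(out_dir, "quality.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

serialize_manifest <- function(m) {
  list(config = m$config,
       encoder_method = m$encoder_method,
       encoder_selection = m$encoder_selection,
       runs = m$runs,
       panel = m$report$panel,
       selected_size = m$report$selected_size,
       k = m$report$k,
       prefix_accuracies = m$report$prefix_accuracies,
       metrics = unclass(m$metrics),
       quality = unclass(m$quality),
       expectation = unclass(m$expectation),
       n_trial_evals = m$n_trial_evals,
       timestamp = format(Sys.time(), tz = "UTC"))
}
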