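#' Specification for a synthetic two-class miRNA count dataset
#'
#' Describes a simulated cohort of tumor and control miRNA-seq profiles with
#' a small planted discriminative panel. Counts follow a lognormal-Poisson
#' model: each miRNA has a baseline log2 abundance, per-sample log-scale
#' Gaussian variability is added, planted class effects are injected on the
#' log2 scale, and reads are drawn as overdispersed Poisson counts scaled to
#' a per-sample library size.
#'
#' Effect models:
#' \describe{
#'   \item{shift}{planted miRNAs gain `effect_size` log2 units of mean
#'     abundance in tumors (classic differential expression).}
#'   \item{correlated}{as `shift`, plus a shared per-sample latent factor
#'     (loading 1 log2 unit) coupling the planted miRNAs, mimicking
#'     co-regulated clusters.}
#'   \item{xor}{class is encoded in the sign-product of the first two planted
#'     miRNAs' centred values with amplitude `effect_size / 2` and no
#'     marginal mean shift, so any single-feature test is blind to the
#'     signal while a classifier on the pair can recover it.}
#' }
#'
#' Defaults mirror a mid-sized two-class cohort: 150 tumor and 150 control
#' samples over 200 miRNAs with a 10-miRNA planted panel, a 4 log2-unit
#' shift, and sample-to-sample log-variability of 1.5 log2 units typical of
#' highly variable miRNA profiles.
#'
#' @param s_tumor,s_control positive sample counts per class.
#' @param d number of miRNAs.
#' @param p size of the planted panel (used when `planted` is `NULL`).
#' @param planted optional vector of distinct feature indices in `[1, d]`;
#'   when `NULL`, `p` indices are drawn uniformly from the seed.
#' @param effect_model one of `"shift"`, `"correlated"`, `"xor"`.
#' @param effect_size log2-scale mean shift (shift/correlated) or interaction
#'   amplitude (xor); must be >= 0.
#' @param noise_sd log2-scale Gaussian sample variability (> 0).
#' @param dispersion count overdispersion: gamma-mixing variance multiplier
#'   (> 0) applied to Poisson intensities (negative-binomial-like noise).
#' @param library_size_range length-2 positive range of per-sample library
#'   sizes (reads), drawn uniformly.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec including this seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(s_tumor = 150, s_control = 150, d = 200, p = 10,
                           planted = NULL, effect_model = c("shift", "correlated", "xor"),
                           effect_size = 4, noise_sd = 1.5, dispersion = 0.1,
                           library_size_range = c(1e6, 5e6), seed = 1L) {
  effect_model <- match.arg(effect_model)
  if (s_tumor < 1 || s_control < 1 || s_tumor + s_control < 4)
    stopf("need s_tumor + s_control >= 4")
  if (d < 1) stopf("d must be positive")
  if (is.null(planted)) {
    if (p < 1 || p > d) stopf("p must be in [1, d]")
    planted <- with_seed(seed, sort(sample.int(d, p)))
  }
  planted <- as.integer(planted)
  if (anyDuplicated(planted) || any(planted < 1L | planted > d))
    stopf("planted indices must be distinct and within [1, d]")
  if (effect_model == "xor" && length(planted) < 2)
    stopf("xor effect model needs at least 2 planted features")
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (noise_sd <= 0 || dispersion <= 0) stopf("noise_sd and dispersion must be > 0")
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    stopf("library_size_range must be an increasing positive pair")
  structure(list(s_tumor = as.integer(s_tumor), s_control = as.integer(s_control),
                 d = as.integer(d), planted = planted,
                 effect_model = effect_model, effect_size = effect_size,
                 noise_sd = noise_sd, dispersion = dispersion,
                 library_size_range = library_size_range, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-class count dataset
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `counts` (d miRNAs x s samples integer matrix,
#'   dimnames set), `library_sizes` (per-sample totals actually used for
#'   scaling), `labels` (factor, `control`/`tumor`), and `truth` (planted
#'   indices and names plus the spec echo). Sample order is all tumors then
#'   all controls; feature names `mir-0001 ... mir-<d>` are already in
#'   lexicographic order.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    s <- spec$s_tumor + spec$s_control
    d <- spec$d
    labels <- factor(rep(c("tumor", "control"), c(spec$s_tumor, spec$s_control)),
                     levels = c("control", "tumor"))
    feature_names <- sprintf("mir-%04d", seq_len(d))
    sample_ids <- sprintf("S%03d-%s", seq_len(s),
                          ifelse(labels == "tumor", "T", "N"))

    mu <- stats::runif(d, 2, 12)              # baseline log2 abundance
    logex <- matrix(mu, nrow = d, ncol = s) +
      matrix(stats::rnorm(d * s, 0, spec$noise_sd), d, s)

    tum <- which(labels == "tumor")
    pl <- spec$planted
    if (spec$effect_model %in% c("shift", "correlated")) {
      logex[pl, tum] <- logex[pl, tum] + spec$effect_size
      if (spec$effect_model == "correlated") {
        z <- stats::rnorm(s)                  # shared latent factor, loading 1
        logex[pl, ] <- logex[pl, ] + matrix(z, length(pl), s, byrow = TRUE)
      }
    } else {                                  # xor on the first planted pair
      # class lives in the sign-product of the pair's centred values; the
      # pair's marginals are bimodal but match the null features' mean AND
      # variance exactly (centres at +/- noise_sd*kap, within-cluster sd
      # noise_sd*sqrt(1-kap^2)), so no single-feature statistic sees it.
      # effect_size/2 is the centre-to-spread ratio of the two clusters.
      r <- spec$effect_size / 2
      kap <- r / sqrt(1 + r^2)
      sgn <- sample(c(-1, 1), s, replace = TRUE)
      u1 <- spec$noise_sd * (sgn * kap + stats::rnorm(s, 0, sqrt(1 - kap^2)))
      partner <- ifelse(labels == "tumor", sgn, -sgn)
      u2 <- spec$noise_sd * (partner * kap + stats::rnorm(s, 0, sqrt(1 - kap^2)))
      # replace (not add) the sample noise on the pair so the construction
      # controls both marginals exactly
      logex[pl[1], ] <- mu[pl[1]] + u1
      logex[pl[2], ] <- mu[pl[2]] + u2
    }

    # overdispersed Poisson counts around RPM-scale intensities at a drawn
    # library depth. Feature totals are NOT renormalized to close the
    # composition: that keeps non-planted features exactly class-independent
    # (renormalizing would depress every other feature in tumors whenever
    # planted features gain reads, leaking class signal genome-wide)
    lib <- stats::runif(s, spec$library_size_range[1], spec$library_size_range[2])
    shape <- 1 / spec$dispersion
    gmix <- matrix(stats::rgamma(d * s, shape = shape, rate = shape), d, s)
    lambda <- sweep(2^logex * gmix, 2, lib / 1e6, `*`)
    counts <- matrix(stats::rpois(d * s, lambda), d, s,
                     dimnames = list(feature_names, sample_ids))

    list(counts = counts,
         library_sizes = stats::setNames(lib, sample_ids),
         labels = stats::setNames(labels, sample_ids),
         truth = list(planted = pl, planted_names = feature_names[pl],
                      spec = spec))
  })
}

#' Convert a generated dataset to a normalized expression_matrix
#'
#' Convenience wrapper: applies [normalize_rpm_log2()] to the simulated
#' counts (using the realized library sizes) and packs the result into an
#' [expression_matrix()].
#'
#' @param sim output of [generate_synthetic()].
#' @return An [expression_matrix()].
#' @export
as_expression_matrix <- function(sim) {
  vals <- normalize_rpm_log2(sim$counts, sim$library_sizes)
  expression_matrix(t(vals), colnames(sim$counts), rownames(sim$counts),
                    as.character(sim$labels))
}

#' Write a simulated dataset in the TSV dialect read_expression() reads
#'
#' Writes the normalized log2-RPM matrix, the labels table, and a JSON truth
#' record (planted indices/names and the spec echo).
#'
#' @param sim output of [generate_synthetic()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "labels.tsv", "truth.json"))
  write_expression(as_expression_matrix(sim), paths[1], paths[2])
  truth <- sim$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Precision and recall of a panel against the planted truth
#'
#' @param panel character vector of selected miRNA names (or integer indices).
#' @param truth the `truth` element of [generate_synthetic()]'s output.
#' @return list with `precision`, `recall` (both in `[0, 1]`) and
#'   `empty_panel` flag; an empty panel reports precision 0 with the flag set.
#' @export
planted_recovery <- function(panel, truth) {
  want <- truth$planted_names
  if (is.numeric(panel)) panel <- sprintf("mir-%04d", as.integer(panel))
  if (length(panel) == 0)
    return(list(precision = 0, recall = 0, empty_panel = TRUE))
  panel <- unique(as.character(panel))
  hits <- sum(panel %in% want)
  list(precision = hits / length(panel), recall = hits / length(want),
       empty_panel = FALSE)
}
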