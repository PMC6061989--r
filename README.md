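# panelDE

Differential-evolution selection of miRNA biomarker panels from two-class
expression data.

## What it does

Small panels of miRNAs can discriminate tumor from control samples, but
panels whose value lies in *joint* expression patterns are invisible to
per-feature statistics. panelDE implements a wrapper selector for this
setting: an integer-coded differential evolution (DE) searches over
candidate index vectors `v` of `n` distinct miRNAs, scoring each candidate
by the 10-fold cross-validated accuracy of an RBF-kernel SVM
(`gamma = 0.5`, `C = 2.0`) applied to a component-enhanced view of the
selected columns. The enhancement multiplies the selected submatrix
`E(v)` entrywise with an `s x n` component-score matrix (PCA or kernel
PCA, chosen empirically per dataset), so candidates are judged in a
representation that retains the dataset-wide covariance structure.

Because single DE runs are stochastic, the procedure runs `theta`
independent searches, pools their best vectors by majority voting into a
frequency-ranked list `R = {r_1, ..., r_k}` (with `#(r_i) >= #(r_j)` for
`i < j`), and sizes the final panel by scanning prefixes of `R` for the
shortest one maximizing cross-validated accuracy on the raw expression
columns. A closed-form null model puts the observed `k` in context: under
random selection the expected number of distinct miRNAs reported at least
once is

```
E[k] = d * (1 - (1 - n/d)^theta)
```

with `d * (1 - n/d)^theta * (n/d)` new miRNAs expected from one more run.
An observed `k` far below `E[k]` shows the ensemble converges rather than
wanders. Finished panels are evaluated by accuracy, F-measure, Matthews
correlation, AUC, and an aggregated score bounded in `[0, 4]`, plus
cosine-similarity cluster homogeneity/separation diagnostics.

A synthetic two-class miRNA-seq generator (lognormal–Poisson counts with
planted mean-shift, correlated, or variance-matched xor panels) makes the
whole pipeline testable without external data.

## Worked example

```r
library(panelDE)

sim <- generate_synthetic(synthetic_spec(s_tumor = 40, s_control = 40,
                                         d = 25, p = 4, effect_size = 5,
                                         noise_sd = 1, seed = 13))
E <- as_expression_matrix(sim)
E
#> expression_matrix: 80 samples x 25 miRNAs (40 tumor, 40 control)

run <- select_panel(E,
                    de_config(n = 4, pop_size = 8, generations = 6,
                              runs = 3, seed = 21),
                    classifier_config(folds = 5, seed = 2),
                    encoder = "kpca")
run
#> panel_run: 3 DE runs, encoder kpca
#> panel_report: 3 of 11 reported miRNAs selected (accuracy 1.0000)
#>   mir-0005, mir-0002, mir-0003
#> accuracy 1.0000 | F 1.0000 | MCC 1.0000 | AUC 1.0000 | aggregated score 4.0000
#>   distinct miRNAs over runs k = 11 (random expectation 10.18)

run$quality
#> cluster quality (3-miRNA panel):
#>   tumor homogeneity   0.9941
#>   control homogeneity 0.9849
#>   separation          0.9780
```

The three runs reported `k = 11` distinct miRNAs out of 25; the prefix
scan keeps the shortest prefix whose joint cross-validated accuracy is
maximal (here 3 miRNAs at accuracy 1.0, reached because the planted shift
is large — two of the three are planted). The aggregated score of 4.0 is
the maximum of its `[0, 4]` range. Homogeneity only slightly above
separation indicates the within-class profiles are not a tight linear
cluster — the regime where a wrapper selector is preferable to clustering.

The analytic null model is a one-liner:

```r
expected_reported(1046, 10, 50)
#> random-selection null (d = 1046, n = 10, theta = 50):
#>   expected distinct miRNAs reported: 398.95
#>   expected new miRNAs in one more run: 6.19
```

File-based runs (`run_pipeline()`) read a TSV expression matrix (miRNA
rows x sample columns) and a two-column label file, and write the panel
table, metrics, quality report, and a full manifest; a thin command-line
front end is installed at `inst/scripts/panelde.R` with subcommands
`expect`, `simulate`, and `run`.

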