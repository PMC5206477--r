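# exprdose

Predicting a continuous clinical dose or concentration from microarray
gene-expression profiles, and studying when tree ensembles pay off at
small sample sizes.

Expression studies that expose samples to graded doses (a drug
concentration, glucose, copper sulfate, ...) produce data with a few
dozen samples and thousands of genes. `exprdose` provides the full
analysis path for such data:

* **Feature selection** — iterative sure independence screening:
  rank genes by |Pearson correlation| with the dose, keep the top
  `d = ⌊n / ln n⌋`, select with a cross-validated lasso, then re-screen
  the remaining genes against the OLS residual of the current selection
  to catch marginally weak but jointly relevant genes (`isis()`);
  followed by a multicollinearity (VIF > 10) and coefficient
  significance (p ≥ 0.10) post-filter (`post_filter()`).
* **Learners**, written from scratch and oracle-tested —
  * CART-style regression trees: exact greedy search over all features
    and split points minimising
    `min_{j,s} [ min_{c1} Σ_{x ∈ R1(j,s)} (y_i − c1)² + min_{c2} Σ_{x ∈ R2(j,s)} (y_i − c2)² ]`,
    leaf prediction = region mean (`rtree()`);
  * ε-insensitive support vector regression minimising
    `‖w‖²/2 + (C/N) Σ_i L_ε(y_i, f(x_i))` with an SMO dual solver,
    linear and polynomial kernels (`esvr()`);
  * bootstrap aggregation of any base learner, mean-combined
    (`bagging()`), and squared-loss gradient boosting of shallow trees
    (`rt_boost()`).
* **Evaluation** — RMSE, MAD and R² = 1 − SSE/SST on held-out data,
  repeated 70/30 splits with per-split 10-fold CV tuning
  (`repeated_holdout()`, `tune_esvr()`, `tune_rtree()`).
* **Simulation** — multivariate-normal dose–gene generator driven by a
  correlation specification, with the standardise/back-transform pair
  `z = (y − ȳ)/σ_y`, `y = z·σ_y + ȳ` (`synthetic_dataset()`,
  `dose_scaler()`), and a Monte-Carlo sweep over training-set sizes
  comparing single, bagged and boosted trees and locating the size at
  which bagging's advantage is sustained (`run_sweep()`,
  `detect_cutoff()`).

Data enter as an `expr_dataset` (samples × genes matrix plus dose
vector), read from a GEO Series Matrix export
(`read_series_matrix()`) or the package's plain TSV dialect
(`read_expr_tsv()`), and preprocessed with log2 transform, missing-gene
exclusion and median imputation (`preprocess_dataset()`).

## Worked example

```r
library(exprdose)

# synthetic stand-in for an 8-gene anticancer-drug dose dataset (n = 69,
# dose-gene correlation 0.52, gene-gene 0.25, dose scale 13.60 ± 9.59)
ds <- synthetic_dataset(gse2409_like_config(), seed = 1)

res <- repeated_holdout(ds, methods = c("svr-linear", "rt", "rt-bagging"),
                        n_splits = 20, seed = 1)
res
#> Repeated holdout: 20 splits (seed 1, tuning: per-split)
#>      method mean_rmse sd_rmse mean_mad sd_mad mean_r2  sd_r2 n_ok
#>  svr-linear     4.675  0.6500    3.726 0.5792  0.6562 0.1733   20
#>          rt     8.687  1.4628    6.940 1.1893 -0.1980 0.7248   20
#>  rt-bagging     6.748  0.9239    5.282 0.6616  0.3320 0.1946   20
```

Read: over 20 random 70/30 splits of this 69-sample dataset, the linear
SVR explains about 66% of the held-out dose variance (RMSE ≈ 4.7 dose
units). A single tree is erratic on 21-sample test sets — its mean R²
is negative because bad splits predict worse than the test mean — and
bagging 50 trees stabilises it to a clearly positive R² of 0.33: the
ordering expected for a near-linear dose–gene signal.

```r
sw <- run_sweep(sweep_config(train_sizes = c(15L, 35L, 55L), reps = 200L,
                             master_seed = 1L))
sw$table[sw$table$train_size == 55, c("method", "mean_rmse", "mean_mad")]
#>      method mean_rmse mean_mad
#>          rt     8.156    6.509
#>  rt-bagging     6.262    4.970
#>    rt-boost     6.056    4.820
```

At a training size of 55 the boosted trees lead, bagging follows, and
the single tree trails; the bagging advantage (single − bagged mean
RMSE) widens from 1.80 dose units at n = 15 to 1.89 at n = 55.
`detect_cutoff(sw)` reports the smallest grid size from which bagging
stays ahead of the single tree, with bootstrap confidence intervals on
the per-size differences.

A command-line front end covering the same pipeline
(`simulate-data`, `select`, `evaluate`, `simulate`, `report`) is
installed at `exec/exprdose`; every run writes a `run_manifest.json`
and identical manifests produce byte-identical outputs.

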