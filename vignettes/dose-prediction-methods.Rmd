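---
title: "Predicting clinical dose from expression profiles: models, tuning and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting clinical dose from expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprdose)
```

## The problem

Microarray experiments routinely pair a continuous per-sample quantity
-- a drug dose, a glucose or copper concentration, an LDL-cholesterol
level -- with the expression of thousands of genes measured on a handful
of samples (n between roughly 15 and 100, p in the thousands). exprdose
treats the continuous quantity as the response `y` and the expression
profiles as predictors `x`, and asks two questions:

1. Which few genes carry the dose signal, and how well can flexible
   regression methods predict the dose from them?
2. At what training-set size does bootstrap aggregation of regression
   trees start to pay off relative to a single tree?

Everything in the package is organised around these two questions: a
screening-based feature selector for the p >> n step, four from-scratch
learners (CART-style trees, epsilon-insensitive SVR, bagging, gradient
boosting), a repeated-holdout benchmark harness, and a Monte-Carlo
training-size sweep on synthetic dose-gene data.

## Preprocessing

`preprocess_dataset()` applies `log2(max(v, 0) + 1)` to raw
intensities. Plain `log2` is undefined at the zero and slightly
negative values that background correction produces, so the transform
adds a pseudo-count of one and floors negatives; it is total, monotone,
and an identity question only for data already on the log scale
(`already_log2 = TRUE`). Genes whose missing fraction exceeds
`max_missing_fraction` (default 0.2 -- "excessively many" made
concrete, configurable) are dropped; fully missing genes always drop.
Remaining missing cells take the gene's observed median: robust,
deterministic, and inert for the rank-based tree learners.

Train/test splits (`split_train_test()`) draw `round(0.7 n)` samples
(half away from zero -- note n = 5 or 15 do produce halves) uniformly
without replacement from a single integer seed, so every experiment in
the package is reproducible from its seed alone.

## Feature selection: iterative sure independence screening

With p in the thousands and n below 100, ordinary least squares cannot
even be fit, and one-shot marginal screening misses genes whose
association with the dose is masked by other genes. `isis()` follows
the iterative screening recipe:

* **Screen**: rank all genes by absolute Pearson correlation with the
  target and keep the top `d = floor(n / log(n))` (the classical
  screening size; zero-variance genes rank last with statistic 0).
* **Select**: run a 10-fold cross-validated lasso (glmnet's coordinate
  descent) on the screened set and keep the genes with nonzero
  coefficients at the CV-minimising penalty. The fold assignment comes
  from the user's seed, so selection is deterministic.
* **Iterate**: regress the dose on the current selection by OLS, screen
  the *remaining* genes against the residual (this is what catches
  marginally weak but jointly relevant genes), lasso-select on the
  union, and repeat until the selection stabilises or `max_iter = 5`.

The selection is truncated at `n - 2` genes so a downstream OLS is
always well-posed; a truncation leaves a warning in the iteration
trace. The lasso penalty is chosen by cross-validated squared error
(`lambda.min`): we examined sparser rules (the one-standard-error rule,
BIC and extended-BIC on refitted active sets) and per-iteration
significance pruning, and none improved support recovery on sparse
Gaussian test beds -- screened candidates are selected for their sample
correlation with the target, which defeats in-sample complexity
penalties; the documented rule is the simplest of the equally good
options.

A known limitation, visible in the package's own simulations: when a
true gene's *realised* sample correlation with the dose is unusually
weak (which happens regularly at effect sizes around half the noise
standard deviation), the screened noise genes absorb its signal and no
residual the iteration can construct reveals it. At n = 100, p = 1000,
eight true genes with coefficients 0.5 and unit noise, the pipeline
recovers at least seven of the eight true genes in roughly 75--80% of
replicates -- good, but not complete, and no variant we tested
(documented above) does better.

`post_filter()` then mimics what a regression modeller does before
interpreting coefficients: iteratively drop the gene with the largest
variance-inflation factor while any VIF exceeds 10 (the conventional
multicollinearity bound; an exactly collinear pair loses its
later-indexed member), then drop genes whose OLS coefficient p-value is
0.10 or larger in a single pass. The 0.10 level keeps genes of the
borderline kind (p around 0.07) that practitioners retain in small-n
expression studies. The VIF stage runs first so that the significance
stage sees a stable, interpretable fit; the reverse order would test
coefficients in a collinear design where p-values are unreliable.

## Learners

**Regression trees** (`rtree()`). Exact greedy CART: at each node,
`find_best_split()` scans every feature and every midpoint between
consecutive distinct sorted values and minimises the summed within-child
squared error; leaves predict the node mean. Ties break toward the
smaller feature index, then the smaller split point, and boundary
values route left (`x <= s`) -- pinned so that an exhaustive-search
oracle can reproduce the tree bit for bit. A split must reduce the
tree's training SSE by at least `cp` times the root sum of squares
(CART's complexity gate; `cp = 1` therefore forbids all but a perfect
first split), respect `min_node_size >= 2` per child, and lie within
`max_depth` levels.

**Epsilon-insensitive SVR** (`esvr()`). The fitted function minimises
`||w||^2/2 + (C/N) * sum_i max(|y_i - f(x_i)| - epsilon, 0)`. The
`C/N` scaling means the per-sample dual box bound is `C/N`; C values
are therefore comparable across training sizes but not numerically
interchangeable with implementations whose per-sample bound is C (when
cross-checking against libsvm, pass `cost = C/N`). The convex dual is
solved by sequential minimal optimisation with maximal-violating-pair
selection, run to a KKT tolerance of 1e-8; tests verify box
feasibility, per-sample complementarity, a duality gap below 1e-6
relative, and objective agreement with an independent solver to 1e-5.
The bias is the mean KKT-implied value over unbounded support vectors,
or the midpoint of the feasible interval when every multiplier sits at
a bound (e.g. when the tube covers the data and the solution is the
constant function). Linear and polynomial kernels are provided --
the kernels that matter for expression data, where sample sizes rarely
support heavier nonlinearity; `gamma` defaults to `1/p` and `coef0`
to 1 so the polynomial kernel includes lower-order terms.

**Bagging** (`bagging()`). Member b trains on n indices drawn with
replacement under seed `seed + b`; predictions average the members.
A bootstrap draw with constant response yields a constant-predictor
member rather than an error. The aggregation is the unweighted mean --
the regression-bagging convention (weighted-median combination belongs
to the AdaBoost.R family, which this package deliberately does not
implement).

**Gradient boosting** (`rt_boost()`). Squared-loss stagewise additive
modelling: start from the response mean, fit a shallow tree (depth 3 by
default) to the current residuals, add it scaled by `nu = 0.1`. For
squared loss with `nu <= 1` the training loss is non-increasing by
construction, and the implementation asserts it. The stage count M is
either fixed (100 in the simulation, for tractability at hundreds of
replicates) or chosen by 10-fold cross-validation over 50..500 in the
holdout harness, where the staged-prediction trick prices all
candidate M from one fit per fold.

## Evaluation protocol

`compute_metrics()` reports RMSE, MAD and R2 = 1 - SSE/SST with SST
about the *test-set* mean. On a holdout set R2 can be negative (the
model is worse than predicting the test mean) and is NA when the test
responses are constant; both conventions are deliberate and tested.

`repeated_holdout()` repeats, 100 times by default: split 70/30, tune
tree and SVR hyperparameters on the training part by 10-fold CV
(grids: C in 10^-2..10^2, epsilon in {0.05, 0.1, 0.2}, gamma in
10^-3..10^2 for the polynomial kernel; tree minimum node size
{2, 5, 10}, complexity {0.001, 0.01, 0.05}, depth {2, 3, 5, 10}), fit
every requested method, and score the test part. Within a split the
tuned configuration is shared by a method's single and ensemble
variants, so ensemble gains are attributable to aggregation rather
than retuning. Tuning ties resolve toward the smaller C, then smaller
epsilon (then smaller gamma) -- the flatter, smoother model. Whether
tuning should be per split (default) or once globally is genuinely
ambiguous in small-n practice; both are exposed (`tune = "per-split"`
/ `"global"`). Split k uses seed `seed + k`, making the per-split
table prefix-stable as `n_splits` grows.

## Synthetic dose-gene data

`synthetic_dataset()` draws multivariate-normal rows whose first
column is a standardised dose `z` and whose remaining q columns are
gene expressions, from a correlation matrix assembled by
`build_correlation_matrix()`; a non-positive-definite specification is
repaired by clipping eigenvalues at 1e-6 and rescaling to unit
diagonal. Raw doses are recovered as `y = z * sd + mean`
(`to_raw_dose()`), the exact inverse of standardisation, so simulated
errors are reported in raw dose units.

`gse2409_like_config()` is the stand-in for the 8-gene anticancer-drug
dataset that anchors the sample-size experiment: q = 8 genes, dose-gene
correlation 0.52 each, gene-gene equicorrelation 0.25, dose scaler
(13.60, 9.59). The real estimated 9x9 correlation matrix is not
public; the equicorrelated surrogate is calibrated so that the
population dose R2, `q rho^2 / (1 + (q-1) r) = 0.787`, echoes the
~0.81 linear predictability reported for that dataset. Conclusions
drawn from it are therefore *qualitative* -- orderings and trends, not
error levels. Real expression data also have heavier tails, block
correlation structure and batch effects that a Gaussian equicorrelated
draw does not emulate; passing simulation tests show the machinery and
the relative behaviour of the learners, not performance on any
particular real dataset.

`sparse_highdim_data()` is the p >> n test bed for the feature
selector: standard normal design, k active genes with known
coefficients, Gaussian noise, truth recorded in the dataset metadata.

## The training-size sweep

`run_sweep()` runs the Monte-Carlo experiment: for each training size
n in {15, 20, ..., 60} (a grid bracketing both the real-data sample
sizes and the region where ensemble behaviour changes) and each of 500
replicates (defaults; the packaged acceptance checks use 200
replicates and sizes {15, 35, 55} to keep a laptop run in minutes),
draw a fresh training set of size n and a fresh test set of 1000
samples, fit a single tree, a 50-member bagged ensemble and a
100-stage boosted ensemble on the standardised dose, back-transform,
and record test RMSE and MAD in raw dose units. The large fixed test
set keeps evaluation noise small relative to the training variability
under study, which is the quantity of interest. Replicate r at size n
uses seed `master + 100000*n + r`, so adding sizes to the grid never
changes existing cells, and boosting is deterministic given the data.

`detect_cutoff()` declares the cutoff at the smallest grid size from
which the ensemble's mean RMSE stays below the baseline's (minus an
optional margin) at *every* larger grid size -- a sustained-crossing
rule that a single noisy dip cannot trigger -- and attaches
percentile-bootstrap confidence intervals computed from the paired
per-replicate differences. With the equicorrelated stand-in the bagged
ensemble already beats the single tree at n = 15 and its advantage
widens with n, so the detected cutoff sits at the bottom of the grid;
locating a literal crossing point requires the original correlation
structure, which the surrogate does not claim to reproduce.

## Numerical choices collected

* Split ties: smallest feature index, then smallest split point;
  boundary `x = s` routes left.
* SMO stop: maximal KKT violation <= 1e-8; kernel matrices get a chol
  check with 1e-8 jitter before solving; per-sample complementarity is
  restored exactly after convergence.
* Lasso: glmnet path, 10-fold CV at `lambda.min`, folds seeded;
  single-column designs are handled by column duplication (the lasso
  zero-condition is unaffected).
* VIF of exactly collinear columns is infinite; the later-indexed
  column drops first.
* Correlation repair: eigenvalue floor 1e-6, then unit-diagonal
  rescale, then a hard PD verification.
* All RNG flows through a single integer seed per entry point;
  internal seeding restores the caller's RNG state.

## Worked example

```{r example, eval = FALSE}
library(exprdose)

# synthetic stand-in for an 8-gene dose dataset, n = 69
ds <- synthetic_dataset(gse2409_like_config(), seed = 1)

# benchmark four methods over 20 random 70/30 splits
res <- repeated_holdout(ds, methods = c("svr-linear", "rt", "rt-bagging"),
                        n_splits = 20, seed = 1)
res

# training-size sweep and cutoff report (reduced size for illustration)
sw <- run_sweep(sweep_config(train_sizes = c(15L, 35L, 55L), reps = 50L,
                             master_seed = 1L))
detect_cutoff(sw)
```
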