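---
title: "Class-imbalance corrections in high dimensions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-imbalance corrections in high dimensions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smotehd)
```

## The problem

Two-class prediction rules trained on class-imbalanced data tend to assign
new samples to the majority class, and the effect worsens when the number of
variables `p` greatly exceeds the number of samples `n` — the typical shape
of gene-expression classification problems. This package provides a complete,
reproducible desk-scale framework for studying how three standard corrections
behave in that regime:

* **SMOTE** — synthetic minority oversampling: new minority samples are
  created as `s = x + u (x^R - x)`, where `x` is a minority sample, `x^R` is
  drawn uniformly from its k = 5 Euclidean nearest minority neighbors (or
  `n_min - 1` neighbors when `n_min <= 5`), and a single `u ~ U(0, 1)` is
  shared by all variables of a synthetic sample, so the sample lies on the
  segment joining its two parents. The minority class is augmented until the
  classes balance.
* **Simple undersampling** — discarding a random subset of the majority class
  until the classes balance.
* **Cut-off adjustment** — keeping the data untouched but classifying into
  Class 1 only when the posterior score exceeds the training Class-1 fraction
  `k1` (random assignment at exact equality) instead of 0.5.

## Why SMOTE behaves differently in high dimensions

For independent `x` and `x^R` with common mean and variance, the synthetic
variable `S = (1 - U) X + U X^R`, `U ~ U(0,1)`, satisfies

* `E(S) = E(X)` — class means are preserved, so mean-based classifiers
  (DLDA) are barely affected;
* `var(S) = E[(1-U)^2 + U^2] var(X) = (2/3) var(X)` — the minority-class
  variance is underestimated, which biases class-specific-variance
  classifiers (DQDA) and inflates two-sample t statistics;
* `cov(S, X) = var(X)/2`, hence `cor(S, X) = (1/2)/sqrt(2/3) ~ 0.612` —
  synthetic samples are strongly correlated with their parents, violating
  the independence assumption of most classifiers and selection methods,
  while no correlation between *variables* is introduced;
* `E||T - S||^2 = (5/3) p` against `E||T - X||^2 = 2 p` for a new sample
  `T` with the same unit-variance null distribution: synthetic samples sit
  systematically closer to new samples. As `p` grows the two distance
  distributions separate, until the nearest neighbor of essentially every
  test sample is synthetic — which is why SMOTE-augmented k-NN without
  variable selection classifies nearly everything into the minority class.

The independence of `x` and `x^R` is an approximation: it is accurate in
high dimensions and fails in low dimensions, where nearest neighbors are
genuinely close. The `properties` functions of this package
(`moment_check()`, `correlation_check()`, `nn_composition()`) verify each
claim numerically rather than symbolically.

### Estimator design for the Monte-Carlo checks

Two choices matter and are deliberate:

* **Variance ratio.** The claim `var(S) = (2/3) var(X)` concerns the
  generator's unconditional distribution. Estimating it from a *single*
  minority sample of size 30 is biased downward (about 0.63 instead of
  0.667): the conditional variance misses the between-dataset variability of
  the sample mean (a factor `(n-1)/n`) and central points are preferentially
  selected as nearest neighbors. `moment_check()` therefore pools synthetic
  samples over `n_datasets` independently drawn minority sets (default 20
  sets of 500 synthetics each), which is the direct Monte-Carlo estimator of
  the unconditional moments; it concentrates at 2/3.
* **Parent correlation.** Averaging per-pair Pearson correlations across
  variables estimates `E_u[(1-u)/sqrt((1-u)^2+u^2)] ~ 0.623`, not the
  population correlation, because the shared interpolation weight enters
  each pair's correlation nonlinearly. `correlation_check()` reports the
  pooled covariance-based estimator as `parent_corr` (it converges to the
  closed form 0.612) and the per-pair average separately as
  `parent_corr_pairwise`.
* **Distance oracles.** The closed forms `2p` and `(5/3)p` inherit the
  independence approximation: nearest-neighbor selection induces a small
  positive covariance between parents, so the empirical mean squared
  test-synthetic distance exceeds `(5/3)p` by roughly 1-2% at `p = 300`,
  `n_min = 36`. At 20 replicates the Monte-Carlo error is commensurate with
  that approximation error; at much higher replication the discrepancy
  becomes statistically detectable. `nn_composition()` reports Monte-Carlo
  standard errors so users can see both regimes.

## The data-generating designs

`sim_config()`/`simulate_dataset()` emulate gene-expression-like data:
`p = 1000` variables in blocks of 10 with within-block exchangeable
correlation `rho` in {0, 0.2, 0.5, 0.8} (independent across blocks),
`n = 100` samples split into 80 training samples with Class-1 fraction `k1`
(0.05-0.95) and a balanced test set of 20. Under the null all variables are
N(0, 1) in both classes; under the alternative the first `p_DE = 20`
variables are shifted to `N(mu2, 1)` in Class 2 with `mu2` in
{0.5, 0.7, 1, 2}, the all-DE variant shifts every variable by 0.2, and an
exponential variant replaces the marginals by Exp(1) with Class-2 shifts
drawn from U(1, 1.5), one draw per DE variable per dataset. Low-dimensional
designs (`simulate_lowdim()`) use `p = 5` or 10 variables, `n_train` in
{40, 80, 200}, `k1 = 0.10` and a balanced test set of 40.

Design choices where the blueprint leaves room:

* The DE variables are the *first* `p_DE` (the first two blocks when
  `block_size = 10`), so shifted variables share the correlation structure.
* Block correlation is realized as
  `sqrt(rho) * Z_block + sqrt(1 - rho) * Z_own`, an exact equicorrelation
  construction; any method with the same population covariance would do.
* Class counts round half up, and a configuration that would round a class
  to zero samples is an error rather than a silent adjustment.
* The exponential variant keeps the block structure through a Gaussian
  copula (`qexp(pnorm(z))`), which preserves the Exp(1) marginals exactly;
  the Pearson correlation is mildly attenuated relative to the Gaussian
  `rho` (rank correlations are preserved).
* In the low-dimensional designs all `p` variables form one exchangeable
  block (10-variable blocks are meaningless at `p = 5`) and the alternative
  case shifts all of them by `mu2 = 1`.
* A single master seed spawns per-replicate child streams
  (`derive_seeds()`), so studies are bitwise reproducible and trivially
  parallelizable.

The generator emulates the statistical skeleton of expression data —
blockwise correlation, sparse mean shifts, controlled imbalance — but not
chip-level artifacts: no heavy tails beyond the exponential variant, no
batch effects, no missing values, no probe-level noise. Passing tests
demonstrate the behavior of the corrections under that skeleton, not under
every real-data pathology; `read_dataset()` lets users run the identical
pipelines on their own labeled expression matrices.

## Pipelines

A `pipeline_config()` fixes normalization (`"samples"` row centering — the
headline setting, `"variables"` column centering, or `"raw"`, used in the
all-DE design), variable selection (top `G = 40` by absolute pooled-variance
two-sample t statistic, ties to the smaller index, zero-variance variables
get t = 0), the correction, and the classifier. Selection can run before or
after SMOTE (after is the headline order; the two give very similar
selections because SMOTE barely reorders t statistics); undersampling always
precedes selection. Normalization is computed separately on training and
test data; within leave-one-out cross-validation the held-out sample is
centered with the fold's training column means, since column means of a
single sample are undefined — row centering is self-contained and
unaffected.

Eleven classifiers sit behind one score contract (`predict_score()` returns
`p(c = 1 | x)`): 1/3/5-NN, DLDA, DQDA and nearest shrunken centroids (PAM)
are implemented from definition; CART (rpart: pruning, maximum depth 5,
complexity 0.01), random forest (randomForest defaults, vote-fraction
score), SVM (e1071 radial kernel defaults, cross-validated sigmoid
probability), and L1/L2 penalized logistic regression (glmnet, penalty by
cross-validated deviance) are delegated. DLDA/DQDA use equal priors so the
0.5 threshold is the familiar minimum-distance rule; PAM keeps its
class-proportion priors — its embedded imbalance correction — with
`s0 = median(s_j)`, 10 shrinkage values from 0 to `max |d_cj|` and
`min(10, n_min)` internal CV folds, accuracy ties resolved toward more
shrinkage. Variances in the diagonal discriminants are floored at `1e-8`
times the mean pooled variance to survive degenerate inputs.

Evaluation uses five measures — PA, PA1, PA2, the rank-based (Mann-Whitney,
half tie credit) AUC, and the G-mean `sqrt(PA1 * PA2)` — on independent
test sets (`evaluate_on_test()`) or via LOOCV repeated over independently
re-drawn resampled training sets (`loocv_evaluate()`, default 50 repeats).
The AUC is threshold-invariant by construction, which the study machinery
exploits as a pairing fingerprint. Because scores of discrete classifiers
(k-NN) can tie the threshold exactly, ties are resolved by a fair coin from
a seeded stream.

## Studies and their desk-scale defaults

`run_study()` crosses designs, `k1` levels, corrections and classifiers with
every cell of one replicate sharing the same simulated dataset (paired
comparisons); `run_titration()` holds the minority class at `n_min` in {5, 10}
training samples while the majority fraction grows from 0.50 to 0.90, with a
balanced held-out test set. The reference design used 1000 replicates per
cell (500 for the titration); the package defaults to 50 (100 for the
titration) so that a full directional battery runs in minutes on one core,
and the corresponding checks are sign tests on paired replicates rather than
tight numeric comparisons. Replication counts are ordinary configuration
knobs for users who want reference-scale runs. Cells whose delegated
optimizer fails on a degenerate replicate are recorded and skipped, not
fatal.

## Known limitations

* Real microarray preprocessing (normalization of chips, probe models) is
  out of scope; the package consumes ready expression matrices.
* SMOTE variants (Borderline-SMOTE, Safe-Level-SMOTE) and
  bagged/ensemble undersampling are not implemented.
* The exponential variant's Pearson correlation is attenuated by the copula
  construction (documented above).
* Probability scores of the delegated classifiers are as calibrated as
  their implementations make them (vote fractions, leaf frequencies, Platt
  scaling); the AUC is rank-based and unaffected, but threshold-based
  corrections inherit any miscalibration.
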