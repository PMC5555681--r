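# pgselect

Feature selection for binary classification of high-dimensional gene
expression under class imbalance.

Most feature-selection methods rank genes by how well they separate the two
classes *on average*. When one class is several times larger than the other —
vaccine responders vs non-responders, or any cohort where one outcome
dominates — the average is dominated by the majority class, and the handful
of samples that every "good" marker gets wrong are silently written off.
`pgselect` implements the opposite idea: after screening for differential
expression and single-gene predictive power, it deliberately hunts for the
samples that the *majority* of strong markers misclassify, and then selects
the genes that classify exactly those samples correctly. These class-specific
"peculiar" genes are the signature. The package also ships the companion
evaluation harness (SVM grid search with class weights under stratified
cross-validation) and a synthetic-data generator with planted ground truth,
so the whole pipeline is testable at desk scale.

It is aimed at transcriptomics practitioners (bulk microarray/RNA-seq, and
single-cell pseudobulk) working on two-class prediction problems with
imbalanced cohorts.

## The method

Let the expression matrix hold J genes by N samples with binary labels
ȳ ∈ {0,1}ᴺ, n samples in class 0 and m in class 1.

1. **Differential expression.** Genes are screened by a two-sided t test
   (optionally empirical-Bayes moderated: per-gene variances are shrunk
   toward a method-of-moments prior on the log variances, giving
   s̃²ⱼ = (d₀s₀² + d·s²ⱼ)/(d₀ + d) with d + d₀ degrees of freedom), followed
   by Benjamini–Hochberg adjustment. Genes with adjusted p ≤ α survive.

2. **Predictive power.** For each surviving gene j, a one-predictor logistic
   regression logit(pᵢ) = β₀ + βⱼxⱼᵢ is fit by IRLS; probabilities are
   thresholded at τ (ŷᵢ = 1 iff pᵢ ≥ τ) and the gene's *predictive power*
   is ppⱼ = #{i : ŷᵢ = ȳᵢ}/N. Genes in the upper tail of the pp
   distribution (pp ≥ the chosen quantile, ties included) are the P *good
   predictors*.

3. **Peculiar genes.** The P prediction vectors are stacked into a binary
   vote matrix ℳ (P × N, class-0 columns first). For a class-0 sample the
   column sum counts the predictors that misclassify it; for a class-1
   sample it counts those that classify it correctly. Samples with column
   sum > K₀ (class 0) or < K₁ (class 1) are the *hard* samples. G0 collects
   the genes voting 0 on every hard class-0 sample (up to a tolerance), G1
   those voting 1 on every hard class-1 sample, and the signature is
   S = G0 ∪ G1. If either set is empty, thresholds/tolerance are relaxed
   along a schedule.

The signature is then evaluated with an SVM (linear, polynomial, gaussian,
sigmoid kernels; cost; per-class weights w₀, w₁) under stratified 10-fold
cross-validation, maximising accuracy or the recall of either class.

## Worked example

```r
library(pgselect)

sim <- simulate_peculiar_data(seed = 42)   # 2000 genes, 15 vs 45 samples
fit <- pgs(sim$expression, sim$labels,
           quantile_level = 0.5,           # median pp cutoff
           K0 = 0.8, K1 = 5/45)            # hard-sample quantiles
fit
#> <pgs_fit> 51 DEG(s) -> 29 good predictor(s) (pp >= 0.85) -> |G0| = 10, |G1| = 10, |S| = 10
#> hard samples: 3 class-0 (votes > 7), 5 class-1 (votes < 26.78)
```

The DEG screen keeps 51 of 2000 genes; the median predictive-power cutoff
(pp ≥ 0.85) keeps 29 good predictors; the vote-matrix analysis flags 3 hard
class-0 and 5 hard class-1 samples and extracts a 10-gene signature. Against
the generator's ground truth the signature is exact:

```r
score_recovery(fit$signature, sim$truth)
#> # A tibble: 1 × 3
#>   recall0 recall1 false_marker_rate
#>     <dbl>   <dbl>             <dbl>
#> 1       1       1                 0
```

Both planted peculiar-marker sets are fully recovered and no noise gene
enters the signature. Evaluating the signature with the SVM harness:

```r
sig_expr <- dplyr::filter(sim$expression, gene_id %in% fit$signature$S)
cv <- grid_search(sig_expr, sim$labels,
                  svm_grid(kernels = c("linear", "polynomial"),
                           cost = c(0.1, 1), degree = 3, coef0 = 1,
                           class_weights = list(c(1, 1), c(100, 1))),
                  metric = "accuracy", k = 10, seed = 1)
cv
#> <pgs_cv> 8 grid point(s), 10-fold CV, optimising accuracy
#> best: linear kernel, cost 0.1, weights (1, 1) -> mean accuracy = 1.0000
```

On this synthetic scenario the peculiar genes separate the classes
perfectly, so the best grid point reaches mean CV accuracy 1. `tidy()`,
`glance()` and `autoplot()` methods are available for the fit, the
predictive-power table, the vote matrix and the CV results.

A thin command-line front end over the same functions is installed with the
package (`system.file("exec", "pgs.R", package = "pgselect")`) with
`simulate`, `select` and `evaluate` subcommands.

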