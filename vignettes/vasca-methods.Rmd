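---
title: "Variable-selection ASCA: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-selection ASCA: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasca)
```

## The model

A designed multivariate experiment yields a data matrix $X$ ($N$
observations $\times$ $M$ variables) and a table of categorical factors.
The package partitions the variation of $X$ by the terms of the design,

$$X = 1\,m^\top + Z_A + Z_B + Z_{AB} + \dots + E,$$

by regressing $X$ on a deviation-coded (sum-coded) regressor matrix
$C = [1, C_A, C_B, C_{AB}, \dots]$ and assembling each term's effect matrix
as $Z = C_Z \Theta_Z$ from the least-squares coefficients. Deviation coding
gives a factor with $L$ levels $L-1$ columns: level $l < L$ puts a one in
column $l$, the last level puts $-1$ in every column, so effects sum to
zero over the levels; interaction columns are element-wise products of the
parent columns. The least-squares formulation (the ASCA+ variant of the
classical ASCA factorization) remains well defined under mild
unbalancedness, where the textbook cell-means partition breaks down. The
coefficients are computed through a QR factorization rather than the
normal-equations inverse; the estimator is the same, the conditioning is
better.

Each term is tested by permutation: rows of $X$ are shuffled $K$ times,
the model is refitted, and the observed statistic $S$ is ranked among its
permuted replicas,

$$p = \frac{\#\{S^*_k \ge S\} + 1}{K + 1},$$

so $p$ can never be smaller than $1/(K+1)$. Available statistics are the
effect sum of squares $\|Z\|_F^2$, the F-ratio of mean sums of squares
(effect over residual, by default), and — for whole-matrix tests only —
the energy of the two leading principal components of $Z$.

## Variable selection inside the permutation test

The whole-matrix ("holistic") test dilutes effects carried by a few
variables among hundreds of noisy ones. VASCA breaks the statistic into
per-variable pieces $S^v$, ranks the variables by decreasing $S^v$, and
tests every nested sub-matrix of the top-$m$ variables, $m = 1,\dots,M$.
The crucial detail is what happens under the null: **within every
permutation the variables are re-ranked by their own permuted statistics**
before the permuted cumulative statistic is formed. The null at size $m$
is therefore "the best $m$ variables of that shuffle", i.e. the selection
step itself is subjected to the permutation — this is what keeps the
procedure honest where a naive fixed-order null would be wildly
anticonservative. The term is called significant for the largest $m$ with
$p_m \le \alpha$; since $m = M$ reproduces the ordinary ASCA test exactly
(bit-for-bit under a shared permutation plan), VASCA is at least as
powerful as ASCA.

Two comparison baselines are included. The *FDR baseline* computes
per-variable permutation p-values and applies the Benjamini–Hochberg
step-up adjustment (`stats::p.adjust`); p-values are taken from the
permutation null pooled across variables ($K \times M$ draws). Pooling is
what gives the baseline enough resolution to reject at $\alpha = 0.01$
after BH correction when $K$ is moderate — with per-variable nulls the
smallest attainable adjusted p-value is $M/(K+1)$, which for
$M = 400, K = 1000$ is $0.4$: the baseline could never fire. Pooling is
statistically sound here because both statistics offered for selection are
comparable across variables (the F-ratio by construction, the SSQ after
autoscaling). The *leverage/SPE baseline* (in the style of ASCA-genes)
fits a PCA to the term's effect matrix and flags variables by leverage
(squared loading mass on the retained components) and squared prediction
error against empirical control limits, taken as the pooled
$(1-\alpha)$-quantile of both indices across permutations and variables —
the original publication's exact limit construction is not specified here,
so the package documents this quantile rule as its baseline approximation.
A variable beyond either limit counts as a detection (the
"relevant", "poorly-modelled" and "odd" quadrants of the leverage/SPE
plane); only the low-leverage/low-SPE quadrant is a non-detection. The
approach needs terms with at least two degrees of freedom, one of the
practical limitations VASCA removes.

## Preprocessing

All pipeline entry points autoscale the data (per-variable mean 0,
variance 1) by default. For the raw-SSQ statistic this is mandatory — the
per-variable statistics must share a null scale for the ranking to mean
anything, and the test functions enforce it. The per-variable F-ratio is
scale-free, but the cumulative and whole-matrix statistics formed from
summed SSQs are not: with heterogeneous variances a handful of
high-variance variables dominates the sums regardless of their relation to
the design (in the strong-bias scenario below, the three biased variables
carry variance $\approx 26$ against a unit-variance background, and on
unscaled data the "holistic" test becomes an inadvertent variance test).
Autoscaling is the standard ASCA practice for exactly this reason. Scaling
is fitted once on the observed data and is invariant under the row
shuffles, so it does not interact with the permutation null.

## Post hoc analysis of a selection

A significant sub-matrix can still contain variables that merely ride
along with the truly associated ones (multivariate models filter, they do
not certify every coordinate). For a selected term the package fits a PCA
to the effect matrix restricted to the selection — at most as many
components as the term's degrees of freedom are meaningful, and scores
plots show $Z + E$ projected on the effect loadings. Loading significance
is assessed by a stratified bootstrap: observations are resampled with
replacement within each design cell (cell sizes preserved, so the design —
and hence the coding matrix — is unchanged; a stratum can never be emptied
by construction), the GLM and PCA are refitted per resample, components
are aligned to the point estimate by maximal absolute congruence with a
sign flip toward positive congruence (without alignment, sign and order
indeterminacy of PCA would destroy the intervals), and percentile
intervals at level $1-\alpha$ are formed per loading. A variable whose
interval excludes zero on at least one retained component is kept;
everything else can be discarded a posteriori.

Percentile intervals were chosen over BCa as the simplest method
consistent with how the intervals are used (a zero-exclusion flag, not a
coverage-critical estimate); the resample count defaults to $B = 1000$ and
is configurable.

## The synthetic-data suite

The simulation suite regenerates the benchmark scenarios used to
characterize the method:

* **ex1** — null, single binary factor, $40 \times 400$ correlated
  background; the class is the sign of independent normal draws.
* **ex1b** — null, $4 \times 3$ full factorial with 4 replicates
  ($48 \times 400$).
* **ex2** — one-to-one associations: variables 1–3 are $N(0,1)$ plus
  `bias` times the $\pm 1$ class code (`bias = 5` strong, `0.5` weak).
* **ex3** — additive multivariate association: the class is the sign of
  the *sum* of three independent $N(0,1)$ variables, so no single variable
  separates the classes.
* **ex4** — two crossed factors: variables 1–3 carry $0.5\times$ a random
  level effect per factor plus a correlated per-cell noise block shared by
  the cell's replicates; 397 background variables.

The correlated background emulates the low-effective-rank covariance of
omics panels with a single dial, `corrLevel` $\in [0, 10]$: the
correlation matrix is $U \Lambda U^\top$ with a random orthonormal basis
$U$, the leading eigenvalue carrying a fraction
$f(\ell) = 1/M + (\ell/10)^2\,(0.98 - 1/M)$ of the total variance and the
remainder decaying exponentially; columns are standardized to exact unit
variance (which softens the concentration somewhat in the sampled data).
Level 0 is exactly independent; at level 10 the first principal component
of a generated sample explains over 90% of the variance; the benchmark
levels 7 and 8 put roughly half and 0.63 of the population variance on
the leading eigenvalue. This generator reproduces the *kind* of
dependence that matters for the methods' error rates — the null results
are insensitive to the exact background, and power comparisons inherit a
wider tolerance — but it is not a reimplementation of any particular
published simulator, and it does not emulate heavy tails, block structure
or count-like marginals of real omics data. Passing benchmarks therefore
demonstrate calibration and relative power under a Gaussian
correlated-background model, not performance guarantees on any given real
dataset.

`runBenchmark()` runs one dataset per replicate and hands **one shared
permutation stream to every method** (ASCA, VASCA, FDR, leverage/SPE),
which makes the methods' rates directly comparable replicate by
replicate. Counting conventions: ASCA's false positive rate is the
fraction of null replicates with $p \le \alpha$; for the
variable-selecting methods the per-variable rate is the fraction of
non-informative variables called significant, pooled over replicates —
for VASCA a variable counts as called whenever it sits inside the largest
significant sub-matrix. On null data VASCA's rejections select small
sub-matrices, so its per-variable rate is far below $\alpha$ while the
per-dataset rate $P(\text{any } p_m \le \alpha)$ (reported as
`fpr_dataset`) sits at or slightly above $\alpha$ and is the natural
comparison to ASCA's rate; on data with planted signal the per-variable
rate is the informative one, and it is visibly inflated when a few
variables carry very strong effects (bystander variables ride into the
significant sub-matrix — the bootstrap pruning step exists precisely to
remove them).
Power at $\ge t$ is the fraction of replicates recovering at least $t$ of
the planted variables. Significance is counted as $p \le \alpha$
throughout: on the $i/(K+1)$ grid this keeps the null rejection
probability exactly $\alpha$ for any $K$ with $(K+1)\alpha$ integral,
whereas a strict inequality would bias small-$K$ runs conservative (at
$K = 1000$ and the usual $\alpha$ both conventions coincide).

## Numerical choices

* Least squares via QR; aliased (rank-deficient) codings are refused with
  the offending terms named. Singular values below $10^{-10}$ of the
  largest count as zero in rank decisions.
* Ordering ties (exactly equal per-variable statistics) break by ascending
  column index — a stable radix sort — so permutation results are
  reproducible to the bit.
* The permutation engine refits via fixed linear maps applied to the
  shuffled data (the coding matrix never changes), stacked across
  permutations into single BLAS calls; per-variable effect SSQs come from
  whitened coefficient blocks ($G_Z\Theta_Z$ with
  $G_Z = \mathrm{chol}(C_Z^\top C_Z)$), and residual SSQs use the
  permutation invariance of column norms. Cumulative null curves for all
  $K$ permutations are built from one two-key radix sort. The leverage/SPE
  null uses closed-form eigenstructure of the $2\times 2$ and $3\times 3$
  coefficient Gram matrices (the common cases) and falls back to a
  per-permutation eigendecomposition otherwise. All fast paths are tested
  against brute-force refits and the SVD route.
* A perfect-fit variable (zero residual SSQ) maps to an infinite
  per-variable F-ratio with a warning; it ranks first and the cumulative
  statistics stay finite because they are built from summed SSQs.
* Zero-variance columns fail autoscaling with the columns named (or are
  dropped under an explicit flag).
* Exact reconstruction reproduction ($1m^\top + \sum Z + E = X$) is held
  to $10^{-8}$ max-abs in the test suite.

## Problem sizes in the shipped checks

The test suite runs the null and power benchmarks at a few hundred
replicates with $K = 199$ permutations (chosen so that
$(K+1)\,\alpha$ is integral at $\alpha = 0.01$) and compares rates within
three binomial standard errors at the replicate count actually run; the
`scripts/acceptance.R` reproduction uses $K = 1000$ permutations with
1000 replicates for the single- and two-factor null tables, 500 for the
power table, 200 (with $B = 1000$) for the
bootstrap pruning rate and 100 for the strong-bias p-curve. These sizes
were chosen so a complete reproduction runs on one CPU in well under half
an hour; all of them exceed the scale at which the 3-SE bands become
informative.

## Known limitations

* Only two-way interactions; no nested or random effects, no continuous
  covariates, no missing cells.
* Unrestricted row permutation is the only resampling scheme; for
  interaction terms in multi-factor designs restricted/exact schemes are
  known alternatives and are deliberately out of scope.
* The two-PC statistic is whole-matrix only (it is not column-additive,
  so it cannot drive the step-up curve).
* The leverage/SPE baseline is a documented approximation of the original
  method's control limits, adequate for the role it plays here (a
  comparison baseline); its degenerate case (2-df terms, where SPE is
  identically zero after retaining both components) detects through
  leverage alone.
* BH correction of pooled permutation p-values assumes cross-variable
  comparability of the statistic; with the raw-SSQ statistic this is only
  true after autoscaling, which the API enforces.
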