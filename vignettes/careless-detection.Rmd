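---
title: "Detecting careless responding: models, simulator, and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting careless responding: models, simulator, and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

carelessboost flags survey respondents who answer Likert items without
regard to their content. It implements three families of tools: the
traditional unsupervised indices (Mahalanobis distance, psychometric
antonyms, even–odd consistency, longstring, intraindividual response
variability), a polytomous-IRT person-fit statistic ($Z_h$) built on
per-construct graded response models, and a supervised stochastic
gradient-boosted-tree classifier trained on labeled data. A
Gaussian-copula ordinal simulator and a replication harness let all of
them be benchmarked under controlled contamination. This vignette explains
the models, the numerical choices, and what the synthetic benchmark can and
cannot show.

## The detection problem

The data are an $n \times J$ matrix of integer responses in $1..K$
(default: $J = 60$ items, $K = 5$ categories, six constructs of ten items
each with every second item reverse-keyed, ten items per survey page).
Careless respondents — people who click through without reading — leave
statistical fingerprints: response vectors far from the multivariate
centroid, inconsistent half-scale scores, implausibly long runs of
identical answers, too much or too little within-person variability, or
response patterns that no trait level makes likely. Each index formalizes
one fingerprint; each comes with a flagging rule turning scores into a
binary decision, and flagged/true labels are summarized as sensitivity,
specificity, precision, accuracy, and balanced accuracy (the mean of
sensitivity and specificity).

Conventions follow standard practice: longstring, IRV, and antonym scores
are computed on the raw responses; Mahalanobis distance and even–odd
consistency after reflecting reverse-keyed items ($x \mapsto K + 1 - x$).
The Mahalanobis rule flags $D^2_i = (x_i-\bar x)^\top S^{-1}(x_i-\bar x)$
above the $\chi^2_{0.95}$ quantile at $J$ degrees of freedom, with $\bar x$
and $S$ (unbiased, $n-1$ denominator) taken from the analysis sample
itself, contaminants included — the post-hoc screening situation. The
longstring rule flags runs of six or more identical consecutive responses.
The remaining cutoffs are not standardized in the literature; the
configurable defaults are: antonym score $> 0$, Spearman–Brown-adjusted
even–odd score $< .30$, IRV outside the sample's 5th/95th percentiles
(both tails evaluated, the better-accuracy tail reported — a deliberate
overestimate that mirrors common benchmarking practice), and $Z_h < -1.96$.
Undefined scores (zero-variance half vectors, constant rows) are reported
but never flagged, which is conservative with respect to false positives.
Under 10% prevalence the 5th/95th-percentile IRV rule can flag at most ten
percent of a sample, capping its sensitivity near .5; published
benchmarks that report higher IRV sensitivity evidently used laxer
(unprinted) cutoffs, which is one reason IRV is not an anchored quantity
here.

## The graded response model and $Z_h$

Between-item multidimensionality is assumed: one unidimensional graded
response model per construct with independent standard-normal traits.
For item $j$ with discrimination $a_j > 0$ and ordered thresholds
$b_{j1} < \dots < b_{j,K-1}$, the cumulative-logit model sets
$P^*_{jk}(\theta) = \mathrm{logit}^{-1}(a_j(\theta - b_{j,k-1}))$ and
category probabilities $P_{jk} = P^*_{jk} - P^*_{j,k+1}$. Estimation is
marginal maximum likelihood by EM on a fixed Gauss–Hermite grid (41 nodes
by default) with a standard-normal prior. Each cycle takes a few BFGS
steps per item on the expected complete-data log-likelihood (a generalized
EM), parameterized as $(\log a, b_1, \log \Delta b)$ so positivity and
threshold ordering are maintained by construction. Convergence is declared
when the largest parameter change drops below $10^{-4}$, with a 500-cycle
cap and a secondary stop when the observed-data log-likelihood improves by
less than $10^{-6}$ for three consecutive cycles — on contaminated samples
a weakly identified threshold can drift for hundreds of cycles with no
measurable likelihood gain. Categories unobserved for an item are merged
with their neighbor toward the mode during estimation and the threshold
grid is expanded back on output. Trait estimates are EAP (posterior means
on the grid), which stay finite for extreme patterns.

The person-fit statistic standardizes the pattern log-likelihood at the
estimated traits: with $\ell_i = \sum_j \log P_{j,x_{ij}}(\hat\theta)$,
$E[\ell_i] = \sum_j \sum_k P_{jk} \log P_{jk}$ and
$V[\ell_i] = \sum_j [\sum_k P_{jk} (\log P_{jk})^2 - (\sum_k P_{jk}
\log P_{jk})^2]$, all terms evaluated at the respondent's own construct
estimates, $Z_h = (\ell - E[\ell]) / \sqrt{V[\ell]}$. Evaluated at the
data-generating trait values the statistic is standard normal to good
approximation at $J = 60$ (measured mean .013, SD 1.000 across 2000
model-consistent simulees). With EAP plug-in estimates the null mean
shifts to roughly $+0.7$ and the SD contracts to about $0.88$ — the
well-documented conservative bias of plug-in person-fit statistics. The
$-1.96$ cutoff is therefore conservative for regular respondents while
uniform-random responders still land many standard deviations below zero,
which is why flagging is robust to any conventional cutoff choice. In the
benchmark loop the EM runs on a 21-node grid with a 150-cycle cap: flags
agree exactly with the full settings on contaminated test samples at a
quarter of the cost, because the score gap between random responders and
regulars dwarfs the remaining parameter drift.

## Stochastic gradient boosting with logistic loss

The supervised detector is a from-scratch gradient-boosted-tree ensemble.
With binary outcome $y_i$ (careless $= 1$) and margin $\hat y$, the loss
is $L(y, \hat y) = y \ln(1 + e^{-\hat y}) + (1 - y)\ln(1 + e^{\hat y})$,
whose negative gradient is the residual $y - p$ with
$p = \mathrm{logit}^{-1}(\hat y)$. Boosting starts from the log-odds of
the training base rate and, at each of $M$ iterations, fits a
depth-limited regression tree to the pseudo-residuals on a
without-replacement subsample (default fraction .5), then updates margins
by a shrinkage factor $\lambda$ times the tree prediction. Trees grow
level-wise by greedy least-squares splits; candidate thresholds are
midpoints of consecutive distinct feature values, ties broken toward the
lowest feature index and threshold; leaf values are a single Newton step
$\sum g / \sum p(1-p)$ over the leaf's in-bag rows, the standard
terminal-node update for logistic-loss boosting that yields calibrated
margins. For low-cardinality features (Likert categories) the split scan
uses exact per-value histograms; continuous features (response-time
parcels) fall back to a presorted scan, so both paths consider exactly the
same candidate set. Identical seed and data give a bit-identical ensemble.

Class imbalance is handled by up-sampling: minority rows are replicated
with replacement until the classes match, *inside each training fold
only* — validation folds and test samples are never touched, and per-fold
provenance indices make that leakage check assertable. Hyperparameters
are selected by stratified 10-fold cross-validation minimizing mean
validation logistic loss, ties broken toward fewer trees, then shallower
depth, then larger leaves. The full benchmark grid (depth 2–4, minimum
leaf 4–10, shrinkage .001–.03 in steps of .002, 250–800 trees in steps of
50) is available as `full_grid()`; the harness defaults to the desk-scale
`reduced_grid()` (depth {2, 3}, leaf {5, 10}, shrinkage {.005, .015, .03},
trees {250, 500}), with cells differing only in tree count sharing one fit
via the boosting trace. Test respondents are classified at $p \ge .5$.

## The synthetic-data generator

Regular responders are drawn from a Gaussian copula: a latent multivariate
normal is discretized at per-item thresholds, so marginal category
distributions and inter-item correlations can be controlled separately.

**Target correlations.** The surrogate correlation matrix comes from a
one-factor-per-construct model: absolute loadings uniform on [.45, .75],
construct intercorrelations uniform on [−.10, .20], rescaled so the mean
off-diagonal correlation *on the conventionally recoded scale* equals .05
with every entry inside [−.45, .63] — the summary statistics a
six-construct, half-reverse-keyed personality inventory typically reports.
Reverse-keyed rows and columns are then sign-flipped to the raw scale the
generator works on. The "mean inter-item $r$ of .05" is thus the strong
within-construct/weak between-construct pattern of a real inventory, not a
near-diagonal matrix; the distinction matters, because the covariance
structure is precisely what makes uniform-random responders stand out to
the Mahalanobis and person-fit detectors.

**Marginals.** Each item's category distribution is a discretized normal
with item-specific location drawn from [2.2, 4.1] and spread from
[0.85, 1.35] on the 1..$K$ scale (mirrored for reverse-keyed items, floored
at .01). Real inventory items differ strongly in endorsement — some are
strongly skewed, some nearly symmetric — and that heterogeneity is the
single feature of empirical response distributions that matters most for
separating content-driven from careless answering; near-identical
marginals across 60 items would make every single item uninformative and
depress all detectors at once.

**Calibration.** For every item pair the latent correlation is found by
monotone root-finding so that the implied ordinal Pearson correlation
(computed from bivariate-normal rectangle probabilities over the threshold
grids, using the Drezner–Wesolowsky single-integral form of the bivariate
normal CDF with 24 Gauss–Legendre nodes) matches the target within
$10^{-3}$. The covariance identity
$\mathrm{Cov}(X,Y) = \sum_{k,l < K} [F_{XY}(k,l) - F_X(k)F_Y(l)]$ for
integer-valued categories keeps that evaluation cheap. The calibrated
matrix is repaired to positive definiteness by eigenvalue clipping at
$10^{-6}$ with diagonal renormalization; the repair-induced drift is
reported and is zero for the default configuration. The test suite checks
the calibration against an independent two-dimensional Gauss–Legendre
integration oracle.

**Careless styles.** Three generators mirror the canonical simulation
styles: *random* responders draw uniformly over all $K$ categories;
*midpoint* responders draw from (.05, .20, .50, .20, .05); *pattern*
responders draw two distinct categories $a < b$ and tile the ascending run
$a, a{+}1, \dots, b$ across the questionnaire (draws 1 and 3 give
1-2-3-1-2-3…), so their responses vary within every cycle and defeat
run-length screens by construction. The two-draw ascending-run reading is
one of several consistent with "a repeating sequence of random numbers";
it is the implemented default, and the samplers are independent functions
so alternatives can be substituted. A condition assembles
$\mathrm{round}(\text{prevalence} \times n)$ careless rows of one style
with copula regulars, shuffles, and labels.

**Response times.** Item-level durations are log-normal per condition:
regular median 7 s (log-SD 0.45), careless median 3 s (log-SD 0.55). These
defaults are invented — chosen so the distributions overlap heavily and
separate mainly in the lower tail, the qualitative shape reported for
instructed careless responding — and are explicitly configurable; setting
both conditions equal gives the no-signal control used in the tests.
Response times are winsorized per item at the 95th percentile and summed
into page parcels of ten items before entering the classifier (sums and
means differ by a constant factor, which trees ignore).

## The benchmark harness

`run_simulation_study()` repeats, per replication: generate a training
sample ($n = 425$) and a test sample ($n = 180$) at the condition's
prevalence and style; score all indices on the test sample (the GRM is
calibrated on the contaminated test sample itself, matching post-hoc
screening; a clean calibration sample can be supplied instead); up-sample
the training sample, grid-search the classifier with 10-fold CV, classify
the test sample; compute the five metrics per method. Aggregates are means
and SDs across replications. `run_empirical_emulation()` mirrors an
instructed-careless web study on synthetic data: a fixed population of 361
regular and 244 careless respondents (styles mixed in equal shares) with
response times, split repeatedly under the 30% / 9:1 constraint — which
lands exactly on a 162:18 test and 199:226 training sample at $n = 605$ —
and evaluated with three classifier feature sets: responses only, RT
parcels only, and both.

Problem sizes are the package defaults throughout: 200 replications for
index-only anchors, 50 for EM- and classifier-inclusive ones, training
$n = 425$ as in the empirical design (the per-condition training sizes of
the original simulation are not printed; mirroring the empirical training
size is the assumption made here). Tuning is re-run per replication, as a
per-sample analysis implies; a tune-once fast path is available by passing
a one-cell grid.

## What the benchmark does and does not show

The simulator reproduces the printed summary statistics of the reference
questionnaire — category heterogeneity, mean recoded inter-item
correlation, correlation range — but not its full empirical correlation
matrix or response distribution, which live in a repository that is
deliberately not a build dependency (they can be supplied as inputs). The
surrogate questionnaire is treated as a fixed study input, like the single
inventory a real study administers: benchmark runs vary the simulated
respondents, splits, and fits, not the questionnaire. One visible
consequence of the substitution: Mahalanobis sensitivity for uniform-random
responders stabilizes slightly below the published near-perfect value
(about .97–.98 across surrogate realizations) — a real inventory's more
extreme item response distributions make uniform-random vectors stand out
even more than the discretized-normal surrogate allows.
Careless styles are rule-based and cleanly separable; real careless
responding is more erratic, partial, and heterogeneous, and published
results show every detector, supervised or not, degrading sharply on real
instructed-careless data. Passing the synthetic anchors therefore
demonstrates that the machinery is implemented correctly under the stated
generating model, not that comparable accuracy will transfer to field
data. Empirical-scale numbers (the response-time-augmented classifier's
advantage, absolute precision around .19) are explicitly out of scope; the
package ships the emulation pipeline and a no-signal RT control (balanced
accuracy ≈ .5) in their place.

## Numerical and design choices, collected

- Covariance denominator $n-1$; Mahalanobis via the stable built-in solve,
  optional ridge $\lambda\,\mathrm{tr}(S)/J$ for $n \le J$ (off by
  default; the benchmark has $n = 180 > J = 60$).
- Antonym pairs: all pairs with sample $r \le -.20$ on raw responses,
  across scales; at least three pairs required, else an error advises a
  laxer criterion.
- Even–odd halves are construct-level means over odd/even positions within
  each construct, Spearman–Brown adjusted.
- Tree ties: lowest feature index, then lowest threshold; a split must
  strictly reduce SSE. Leaf Newton denominators are floored at $10^{-12}$.
- Subsample fraction .5 (the stochastic variant's fraction is not printed;
  .5 is a labeled assumption), up-sampled base rate gives $F_0 \approx 0$.
- Quadrature: Gauss–Hermite re-expressed for a standard-normal weight; 41
  nodes for calibration-grade fits, 21 in the benchmark loop.
- All randomness flows from one seed through derived independent
  sub-seeds; every sampler is bit-reproducible given its seed.
- Correlation-recovery checks compare sample to target correlations as a
  mean absolute deviation (≤ .03 at $n = 5000$) plus a loose per-entry cap
  (.06): with 1,770 entries the expected maximum of the sampling noise
  alone exceeds a .03 per-entry band, so an all-entries assertion at that
  level would reject a correct generator.
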