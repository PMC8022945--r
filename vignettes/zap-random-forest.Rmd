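---
title: "Hurdle random forests for zero-inflated count traits: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hurdle random forests for zero-inflated count traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zapforest)
```

## The problem and the model

Genomic selection trains a prediction model on lines that are both
genotyped (here: biallelic SNP markers coded 0/1) and phenotyped, and then
predicts phenotypes of new lines from their genotypes alone. Many disease
and yield-component traits are counts — infected spikelets, seeds, lesions
— and often carry far more zeros than a Poisson law allows.

`zapforest` models such counts with a *zero-altered* (hurdle) Poisson
random variable: the response is 0 with probability $\theta$ and otherwise
follows a zero-truncated Poisson (ZTP) with rate $\mu$,

$$P(Y=0)=\theta,\qquad
  P(Y=y)=(1-\theta)\,\frac{e^{-\mu}\mu^{y}}{(1-e^{-\mu})\,y!},\quad y\ge1,$$

with mean $E[Y]=(1-\theta)\,\mu/(1-e^{-\mu})$. Unlike zero-*inflated*
(mixture) models, the hurdle form attributes every zero to the zero
component, which makes the two parts separable: different covariates may
drive "is the count zero?" and "how large is a positive count?".

Instead of linking $\theta$ and $\mu$ to markers through linear
predictors, both links are left nonparametric and estimated by random
forests in two steps (`fit_zap()`):

1. **Zero part.** A binary forest fit to the indicator $I(Y=0)$ with the
   Gini splitting criterion; its ensemble output is $\hat\theta(x)$,
   a probability (trees are averaged by leaf proportion, never majority
   vote, precisely so this stays continuous).
2. **Truncated part.** A forest fit on the positive observations only,
   where the splitting criterion is the ZTP log-likelihood
   $LL^+ = -N^+\log(1-e^{-\mu}) + \log(\mu)\sum_i Y_i^+ - N^+\mu -
   \sum_i\log(Y_i^+!)$ evaluated at the node's maximum-likelihood rate.
   The best split maximizes the summed child log-likelihoods; each child
   re-optimizes its own $\hat\mu$ by solving
   $\bar Y^+ = \mu/(1-e^{-\mu})$.

Two prediction rules share one fitted model: the expected value
$(1-\hat\theta)\,\hat\mu/(1-e^{-\hat\mu})$ (`type = "mean"`, the ZAP_RF
rule), and a classification-style rule returning 0 where
$\hat\theta > 0.5$ and $\hat\mu$ otherwise (`type = "class"`, ZAPC_RF;
the boundary $\hat\theta = 0.5$ goes to the count branch). The 0.5
default encodes no prior preference between the two outcomes and is
configurable.

## Tunable parameters

* `ntree` (default 500 for raw forests; the benchmark grids use 100/300/500):
  more trees only stabilize the ensemble; variance across seeds shrinks
  as `ntree` grows (tested).
* `mtry` — candidate features drawn per node, the main
  bias/decorrelation dial. Grids of (30, 50, 100) for panels of order
  10^3 markers and (150, 230, 320) for order 10^4 are the defaults of
  `default_grid()`.
* `nodesize` — minimum observations per *leaf*; a node with fewer than
  `2 * nodesize` observations is terminal. The source protocol only says
  "samples in the final nodes", so the per-leaf reading was chosen; grid
  (2, 5, 15).
* `threshold` — the ZAPC zero-probability cutoff, default 0.5.
* Ridge baselines: `lambda` selected on a 100-point log-spaced grid below
  $\lambda_{max} = \max_j |\sum_i x_{ij}(y_i-\bar y)|/n$ by k-fold CV
  (10-fold in the benchmark), minimizing MAE with ties resolved toward
  stronger shrinkage.

## The evaluation protocol

`run_benchmark()` implements nested cross-validation: outer 5-fold over
(line, environment) records; inside each outer training set, forests are
tuned by 5-fold grid search on mean MAE and the penalties of the ridge
(RR) and Poisson-ridge (GPR) baselines by 10-fold CV; the winner is refit
on the full outer training set and scored on the held-out fold. Spearman
correlation of tie-averaged ranks, MAAPE and MAE are reported per
environment and across environments as mean ± sd/√5 over folds.

Records, not whole lines, are partitioned by default — this mimics lines
observed in some environments and missing in others, so the same line may
inform training in one environment and be tested in another (`by_line =
TRUE` switches to whole-line folds). "Across environments" pools the test
records of a fold before computing a metric; averaging the
per-environment values instead is available (`pool = "average"`) because
the protocol's wording does not pin this down.

MAAPE, $\tfrac1n\sum\arctan|(y-\hat y)/y|$, needs explicit zero
conventions here because observed counts are full of zeros: a term is 0
when $y=\hat y=0$ and $\pi/2$ (the arctan limit) when $y=0,\hat y\neq0$.
The MAAPE formula itself is the standard arctangent form; the source
text names the metric without printing it.

Permutation importance (`permutation_vim()`) follows the test-set
convention: per tree, the held-out fold's prediction error is compared
before and after permuting one predictor; differences are averaged over
trees and normalized by their standard deviation across trees (a 0/0 —
e.g. a never-used predictor — reports 0). Hurdle models give two tables,
zero part (misclassification error) and truncated part (squared error of
$\hat\mu$ against positive counts), averaged over the outer folds.

## The synthetic world

`simulate_markers()` draws independent 0/1 markers with per-marker
presence frequencies uniform on (0.1, 0.5) — post-QC panels rarely keep
rarer markers. `simulate_zap_phenotypes()` builds, for every line ×
environment record, $\mathrm{logit}\,\theta$ and $\log\mu$ as sparse
additive marker effects plus environment offsets, then draws the count
from the hurdle law. Intercepts are calibrated so the mean $\theta$ and
mean $\mu$ over records hit stated targets; $\theta$ is clipped to
$[10^{-6}, 1-10^{-6}]$ so parameters stay valid for any effect draw.

The `dataset1_like()` preset states a world resembling a small wheat
disease-severity panel: 115 lines × 1635 markers × 3 environments, a 35%
zero share and positive-part rate near 2.5 (matching a reported 34.87%
zero share and mean count 1.78). Ten markers drive each part, with
disjoint informative sets (the hurdle model's selling point), effect
sizes ±0.9 on the logit scale and ±0.5 on the log scale, environment
offsets ±0.3 and ±0.2 — moderate, realistic signals chosen once. The
informative markers sit among the first 30 columns so that desk-scale
truncations (`p = 200`) keep the signal. `dataset2_like()` mirrors the
larger, mildly zero-inflated panel (438 × 11,617 × 6, ~6% zeros).

What the generator does **not** emulate: linkage disequilibrium between
markers, kinship/pedigree structure, genotype-by-environment effects on
the *marker* effects (environments only shift intercepts), or
overdispersion beyond what the hurdle construction induces. A green test
therefore establishes that the estimator recovers the stated world — not
that it matches any particular field trial.

## Numerical choices

* The rate MLE solves $\bar Y^+=\mu/(1-e^{-\mu})$ by Newton iteration
  with an analytic derivative, safeguarded by bisection on
  $[10^{-12}, 2\max(\bar Y^+,2)]$, tolerance $10^{-10}$; the map is
  strictly increasing so the bracket is guaranteed. All-ones nodes have
  no interior MLE and take the boundary value `MU_MIN = 1e-8` (ZTP mean
  1, the limit).
* ZTP sampling is exact inverse-CDF via the Poisson quantile function on
  $u\sim U(e^{-\mu},1)$, so small-$\mu$ nodes never stall in a rejection
  loop.
* Candidate thresholds are midpoints of consecutive distinct sorted
  values (0.5 for binary markers). The $\sum\log(y!)$ likelihood term
  cancels between a parent and its children and is dropped from split
  comparison, never from reported likelihoods.
* A split must improve the children's objective by more than
  $10^{-9}(|\mathrm{parent}|+1)$; candidates are scanned in ascending
  (feature, threshold) order and only a better-by-tolerance candidate
  replaces the incumbent. This makes tie-breaking deterministic and
  robust to float accumulation order — identical partitions reached
  through different features (frequent once bootstrap duplicates rows)
  otherwise resolve on last-bit noise. One consequence: forest fits are
  invariant to feature-column permutation only for tie-free designs.
* Forest randomness runs on internal `mt19937_64` streams seeded per
  tree from (forest seed, tree index): fits are bit-reproducible, do not
  touch R's RNG state, and would remain identical under parallel tree
  growth.
* $\hat\theta$ may hit 0 or 1 exactly (pure leaves); the distribution
  helpers accept the closed interval and degenerate cleanly.
* The two hurdle parts are tuned jointly (one grid, shared
  hyperparameters, model scored by its mean-rule MAE): the protocol
  reports a single grid per model, and separate tuning would double the
  search at no demonstrated benefit. Truncated-part trees predict their
  leaf rates and the forest averages the rates, applying the mean
  formula once at the forest level; averaging per-tree ZTP means instead
  is available via `aggregate = "mean"`.
* Ridge and Poisson-ridge penalize only slope coefficients, on the raw
  feature scale — exactly the printed losses, confirmed by the
  closed-form single-feature solution $\hat\beta = S_{xy}/(S_{xx} +
  \lambda)$. Internal standardization is an option, off by default
  (markers are already on a common 0/1 scale). The Poisson fit is
  penalized IRLS with step halving; an all-zero response returns the
  intercept limit rather than an error.

## Design choices that were genuinely open

* **Zero-part criterion.** The source description is ambiguous between
  the Gini index and Bernoulli deviance; Gini is implemented (it is the
  conventional binary-forest default and the first-named option). For
  0/1 responses the node Gini score $n\,p(1-p)$ equals the within-node
  SSE, so the choice affects nothing at the split level for this
  encoding.
* **Grid size.** The protocol mentions "9 combinations" of a 3×3×3 grid;
  the full 27-cell factorial is run by default, and an explicit
  combination list (e.g. 9 rows) can be supplied as a data frame.
* **GE encoding.** Genotype-by-environment interaction columns are
  line-within-environment indicators labeled `Z.G<line>.Env<env>`
  (matching the naming visible in reported importance plots), with
  marker × environment products as an alternative (`ge_mode =
  "product"`); the original encoding is not documented.
* **Across-environment pooling** and **record-level folds**: see the
  protocol section; both alternatives are implemented behind arguments.

## Known limitations

* Trees handle binary and ordered numeric features only: no surrogate
  splits, no missing values, no multi-level categorical splits, no
  pruning (none is used by the protocol).
* The ZAPC rule outputs $\hat\mu$, the truncated-part *rate*, on the
  count branch — not the ZTP mean. This follows the printed rule; for
  small rates the two differ visibly.
* Real-data descriptive checks (zero percentages, phenotype summaries of
  the deposited wheat datasets) require downloading the original
  serialized files; `convert_rdata()` ingests them once downloaded, but
  no test depends on network access.
* Importance values are comparable within one table, not across parts or
  models; the normalization is per-tree-sd, not an absolute scale.
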