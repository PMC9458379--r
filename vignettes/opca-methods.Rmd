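---
title: "Selecting tumor gene panels with PCA screening and neighborhood rough sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting tumor gene panels with PCA screening and neighborhood rough sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opcaselect)
```

## The problem

Two-class expression matrices (tumor vs normal microarrays, or any
samples-by-genes table with a binary phenotype) have thousands of genes
and a few dozen samples. Most genes are noise, and many of the
informative ones are redundant copies of each other. The goal of this
package is to select a *compact* panel of genes that classifies the
samples well — few enough genes to interpret, discriminative enough to
use downstream.

The method, which we call the OPCA pipeline, couples two classical
ideas:

1. **A PCA contribution-rate screen.** The covariance matrix of the
   samples-by-genes matrix is eigendecomposed; component $k$'s
   *contribution rate* is its share of total variance,
   $c_k = \beta_k / \sum_j \beta_j$. Components with $c_k$ above a
   threshold (default 1%) are retained, each gene $j$ is scored by its
   contribution-weighted squared loading on the retained components,
   $s_j = \sum_k c_k\, l_{kj}^2$ (renormalized to sum to one), and the
   same 1% rule is applied to the gene scores. This removes the bulk of
   the noise genes cheaply before the expensive combinatorial step.

2. **Neighborhood rough set (NRS) attribute reduction.** The surviving
   candidate genes are min–max normalized to $[0,1]$ and treated as the
   condition attributes of a *decision table* whose decision attribute
   is the class label. For a radius $\delta$ and attribute subset $B$,
   sample $i$'s neighborhood is
   $N_B(i) = \{j : \lVert x_i - x_j \rVert_2 \le \delta \text{ over } B\}$
   (a closed ball, so $i \in N_B(i)$; the empty subset has distance 0
   and its neighborhood is the whole universe). The *positive region*
   is the set of samples whose neighborhood is class-pure, the
   *dependency degree* is $\gamma_B = |POS_B| / |U|$, and the
   *significance* of gene $a$ is the dependency gain
   $SIG(a, B) = \gamma_{B \cup \{a\}} - \gamma_B$. A greedy forward
   search adds the most significant gene while that gain exceeds a
   floor (default 0.01), and a grid sweep over $\delta \in [0, 2]$
   (default step 0.01) picks the radius whose reduct cross-validates
   best.

The selected panel is then evaluated by stratified k-fold
cross-validation (default 10-fold, linear SVM; 1-nearest-neighbor as an
alternative), reporting pooled accuracy and positive-class precision.

## Why these definitions

The dependency and significance formulas are the standard neighborhood
rough set definitions; nothing exotic is needed for two classes.
A few conventions are fixed deliberately:

* **Covariance divisor.** The population form $1/M$ is the default
  (`divisor = "M"` in `expr_covariance()`), with the unbiased $1/(M-1)$
  switchable. Contribution rates are scale-invariant, so the choice
  does not affect the screen; it is exposed for reproducibility.
* **Component-to-gene mapping.** A contribution-rate rule on components
  alone cannot output genes, which the downstream reduction needs. The
  contribution-weighted squared-loading score is the natural bridge: it
  is non-negative, sums to one across genes, and reduces to the
  per-gene variance share when all components are retained. The 1% rule
  is applied at both levels. If no gene clears the threshold (possible
  when the spectrum is nearly flat), the top $\lceil\sqrt{m}\rceil$
  genes by score are kept so the pipeline never stalls.
* **Min–max normalization.** Applied per gene before any distance
  computation, so a single radius grid $[0, 2]$ is commensurate across
  genes of wildly different raw scales. Constant genes map to zero.
  Distances are *not* divided by $\sqrt{|B|}$: raw Euclidean distances
  keep dependency monotone in attribute-set inclusion, which the greedy
  search and its tests rely on.
* **Sign and tie conventions.** Eigenvector signs are fixed by making
  the largest-magnitude entry non-negative; greedy ties go to the
  lowest gene index; radius ties go to fewer selected genes, then the
  smaller radius. Together with seeded fold assignment this makes every
  run bit-reproducible.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `contribution_threshold` | 0.01 | fraction of variance a component / gene score must exceed to survive the screen |
| `delta_grid` | `seq(0, 2, 0.01)` | neighborhood radii swept; units of normalized expression |
| `significance_floor` | 0.01 | minimum dependency gain for a gene to enter the reduct |
| `classifier` | `"linear-svm"` | classifier refit in each CV fold (`"knn1"` alternative) |
| `cv_folds` | 10 | stratified folds; every class needs at least this many samples |
| `seed` | 1 | controls fold assignment and simulation |

A single radius can be forced with a singleton `delta_grid` (the CLI
flag `--delta 0.77` does this), which skips the sweep entirely.

## What the synthetic generator emulates

`simulate_expression()` produces the study condition used throughout
the tests: 60 samples (30 per class) by 200 genes, of which 6 are
informative (class means separated by 2 SD), 20 are redundant (noisy
copies of cyclically assigned informative parents, noise SD 0.3, giving
parent correlations well above 0.5), and 174 are pure standard normal
noise. Intensities are on a standardized scale rather than raw
microarray units: the pipeline min–max normalizes before computing
neighborhoods, so only relative structure matters. Gene order is
shuffled deterministically under the seed, and a truth table records
each gene's role.

What it does **not** emulate: probe- and batch-effects, heavy-tailed or
multiplicative microarray noise, correlated noise blocks, class
imbalance beyond what the caller requests, or multi-class phenotypes.
Passing tests on this generator therefore show that the machinery
recovers planted low-dimensional signal under Gaussian noise — not that
the method's published performance on any particular real dataset is
reproduced.

```{r sim-example}
sim <- simulate_expression(seed = 1)
fit <- run_opca(sim$data, opca_config(delta_grid = seq(0, 2, by = 0.05),
                                      seed = 1))
glance(fit)
tidy(fit)
```

## Evaluation protocols, honest and optimistic

`run_opca()` reports the cross-validated accuracy of the panel it
selected — but the panel was selected *using all samples*, and the
radius sweep explicitly maximizes that same cross-validated accuracy.
On data with real signal this optimism is small; on data with **no**
signal it is large and structural (on 60-sample, 200-null-gene
simulations the non-nested report sits around 0.6 rather than 0.5).
This mirrors the common practice of selecting features once and
cross-validating the classifier only, and it is the package's default
because it is what the comparison harness and most published feature
selection results use.

`nested_opca_cv()` is the honest estimator: the entire pipeline — PCA
screen, radius sweep, greedy reduction — is re-run from scratch inside
each training fold, and only the held-out samples are scored. Under a
null simulation its pooled accuracy is consistent with chance, which
the acceptance suite verifies across 20 seeded replicates. Use it
whenever the performance number itself is the scientific claim
(CLI: `opca select --nested`).

## Numerical and degenerate-input choices

* Neighborhood membership uses squared distances compared with
  $\delta^2$ — no epsilon slop. Ties at the boundary are measure-zero
  for continuous data and are resolved identically by the vectorized
  engine and the brute-force reference used in the tests.
* A constant gene normalizes to all zeros and can never change a
  neighborhood; a single-class table makes every sample's lower
  approximation trivially full (dependency 1 for any subset).
* `delta = 0` makes each sample's neighborhood the set of samples
  identical to it on `B`; for continuous data that is the singleton
  $\{i\}$, so dependency is 1 for any non-degenerate single gene.
  Radius selection is therefore driven by the cross-validated score,
  not dependency, whenever an evaluator is available.
* Loaders reject non-finite cells by default, reporting the on-disk
  row/column of the first offender; per-gene mean imputation is opt-in.
* An empty reduct (possible when the significance floor gates out every
  gene) is reported as such; evaluation falls back to the single
  best-scoring candidate gene and the report is flagged.

## Known limitations

* **Greedy stalls at coarse granulation.** The significance-gated
  forward search examines one gene at a time. At radii large relative
  to the spacing of normalized samples, every *single* attribute can
  have zero marginal gain while a *pair* of attributes separates the
  classes perfectly; the search then stops early and below the
  exhaustive optimum. At radii at or below the typical nearest-neighbor
  spacing ($\approx 1/(n-1)$ for $n$ samples on a normalized axis) we
  observe exact agreement with exhaustive enumeration on hundreds of
  random 12-sample tables, and the test suite asserts the property in
  that regime. Users forcing a large single radius should expect
  possibly empty or short reducts.
* The radius sweep evaluates one radius at a time; simultaneous
  multi-radius granulation is not implemented.
* Two-class decisions only; multi-class and regression decisions are
  out of scope, as are variable-precision and fuzzy rough sets.
* The dependency computation is $O(n^2 m)$ per greedy step via dense
  distance matrices — comfortable for microarray-scale cohorts
  (hundreds of samples), not for single-cell-scale sample counts.

## Problem sizes used by the tests and the acceptance script

The property suites run on random tables of up to 20 samples and 6
attributes (with brute-force double-loop oracles), and the pipeline
studies run 20 seeded replicates of the 60 × 200 planted-panel
condition — non-nested for the recovery and accuracy summaries, nested
for the null calibration — plus a 5-replicate selector comparison.
These sizes were chosen so the whole suite completes in minutes on one
CPU while keeping the Monte Carlo standard errors of the asserted means
small.
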