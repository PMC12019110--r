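---
title: "Extracting bidirectionally interacting cores from directed functional networks"
author: "BidirCore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting bidirectionally interacting cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BidirCore)
```

## Overview

Feedback — reciprocal, bidirectional interaction between parts of a system —
is a different property from mere connection strength. A subnetwork can be
heavily wired and still be a one-way street. BidirCore implements a two-stage
framework for locating the parts of a system that interact *bidirectionally*:

1. **Network estimation.** From multi-trial time series (one column per
   region/node), the directed influence of every node on every other is
   estimated with normalized directed transfer entropy (NDTE) under a
   bivariate vector-autoregressive (VAR) model, and filtered by a
   block-permutation surrogate test.
2. **Core extraction.** From the resulting weighted directed network (or any
   user-supplied one), the hierarchically nested *complexes* — subnetworks
   that cannot be bipartitioned anywhere without cutting strong edges in
   *both* directions — are extracted exactly, together with a per-node
   *coreness*.

This vignette explains the models, the algorithms, the tunable parameters,
the numerical conventions, and what the synthetic-data generators do and do
not emulate.

## Stage 1: directed network estimation

### Model and information quantities

For every ordered node pair (X, Y) a bivariate VAR(T) model

$$Z_t = \sum_{k=1}^{T} A_k Z_{t-k} + \epsilon_t, \qquad
  Z_t = (X_t, Y_t)^\top$$

is fitted by ordinary least squares, pooling trials as independent
realizations: each trial contributes its own lagged rows, so lags never
cross trial boundaries, and the first $T$ frames of each trial are excluded
from the response. Residual covariances are maximum-likelihood estimates
(sums of squared residuals over the pooled row count), which makes the
nested-model comparisons below monotone in sample.

The transfer entropy from X to Y is the conditional mutual information
$I(Y_{i+1}; X^i \mid Y^i)$ between the target's next value and the source's
past, given the target's own past. Under the linear-Gaussian model all the
entropies reduce to log-variances, so

$$T_{XY} = \tfrac{1}{2}\,
  \ln\!\big(\sigma^2_{\mathrm{reduced}} / \sigma^2_{\mathrm{full}}\big),$$

where $\sigma^2_{\mathrm{full}}$ is the target's residual variance in the
bivariate fit and $\sigma^2_{\mathrm{reduced}}$ in the univariate AR(T) fit
of the target alone (same estimator, same sample range). `transferEntropy()`
clips negative sampling estimates to zero — the population value is
nonnegative, and with nested OLS fits on identical rows the in-sample
estimate already is. NDTE normalizes by the total mutual information between
$Y_{i+1}$ and the joint past,

$$F_{XY} = \frac{T_{XY}}{I(Y_{i+1}; X^i, Y^i)}, \qquad
  I(Y_{i+1}; X^i, Y^i) = I(Y_{i+1}; X^i \mid Y^i) + I(Y_{i+1}; Y^i)
  = \tfrac{1}{2}\ln\!\big(\mathrm{Var}(Y)/\sigma^2_{\mathrm{full}}\big),$$

so $F_{XY} \in [0, 1]$ weighs the source's predictive contribution against
the target's total predictability. If the normalization factor is
numerically zero (an unpredictable, uninfluenced target), the edge value is
defined as 0 with a warning.

The estimator is plain pooled OLS. Recursive VAR solvers (e.g.
Levinson-type recursions used by some toolboxes) are asymptotically
equivalent for stable processes; OLS was chosen as the reference because it
is transparent and directly yields the nested-model residual variances the
information quantities need. Exact numerical parity with any particular
toolbox is not a goal; correctness is anchored to analytic oracles instead
(see below).

### Significance filtering and thresholding

Per ordered pair, `buildDirectedNetwork()` generates `nSurrogates` (default
100) surrogates by **block permutation** of the *source* series: each trial
is cut into contiguous blocks of `blockSize` points whose order is permuted
uniformly while the within-block order is preserved. This destroys
source-target coupling but keeps short-range autocorrelation, and for short
series it provides vastly more distinct surrogates than circular shifting
(200 points in blocks of 10 give about $20!$ arrangements). A trailing
remainder shorter than `blockSize` is kept as one (short) block and permuted
with the rest, so no samples are discarded. The recommended block size is
the VAR order; both default to 10.

The p-value is the upper-tail mass of a Gaussian kernel density estimate
(Silverman's rule-of-thumb bandwidth) fitted to the surrogate NDTE values,
evaluated analytically as a mixture tail sum — one-sided, because only
excess predictability is evidence of influence. If all surrogates are
identical the empirical rank p-value is used instead. Edges are kept iff
$p < \alpha/m$ with $m = n(n-1)$ under Bonferroni correction (default
$\alpha = 0.05$). `thresholdToDensity()` then keeps the
$\lfloor \text{density}\cdot n(n-1) \rfloor$ strongest edges (reference
densities 5--20% mirror the sparsity of anatomical connectivity); ties at
the cutoff break lexicographically by (source, target) so outputs are
reproducible. The retained edge weights are the NDTE values themselves
(they serve as cut weights downstream), not binarized significances.

Two reproducibility conventions matter: every per-pair surrogate stream is
seeded deterministically from the run seed and the pair identity, so
results do not depend on iteration order; and identical inputs with an
identical seed give bit-identical networks.

### Preprocessing

`preprocessTimeSeries()` z-scores each (trial, node) series and then applies
a zero-phase (forward-backward) second-order Butterworth band-pass, by
default 0.008--0.08 Hz at a 0.72 s sampling interval — the standard slow
band for BOLD-like signals. Constant series are rejected with the offending
(trial, node) named. The filter's squared magnitude response is exposed as
`bandpassGain()` and is verified in the tests against sinusoids pushed
through the actual filter.

## Stage 2: exact extraction of bidirectional cores

### Cut strength, min-cut, complexes, coreness

For a bipartition $(V_L, V_R)$ of a directed graph, the two directed
crossing weights are summed separately and the **strength of bidirectional
connections** is their minimum,
$w(V_L; V_R) = \min\{w(V_L \to V_R),\, w(V_R \to V_L)\}$: zero whenever the
two sides are linked only one way. The **min-cut weight** $w^{\mathrm{mc}}$
of a (sub)graph is the minimum of $w(V_L; V_R)$ over all bipartitions — its
inseparability. Single nodes have $w^{\mathrm{mc}} = 0$ by convention.

An induced subgraph $G[S]$ is a **complex** if $w^{\mathrm{mc}}_{G[S]} > 0$
and $w^{\mathrm{mc}}_{G[S]} > w^{\mathrm{mc}}_{G[T]}$ for every strict
superset $T$. Complexes are pairwise nested or disjoint and nesting strictly
decreases the min-cut weight, so they form a hierarchy. The **coreness** of
a node is the largest $w^{\mathrm{mc}}$ over complexes containing it
(equivalently over *all* subnetworks containing it — the package tests
verify this equivalence exhaustively on small graphs), and 0 for nodes in no
complex.

### Exact search

Minimizing $w(V_L; V_R)$ looks combinatorial, but the objective is symmetric
under swapping the sides, and swapping exchanges the two directed sums.
Hence its global minimum over bipartitions equals the global minimum
*directed* cut of the digraph, which `minCut()` obtains exactly with a
max-flow global minimum-cut routine (igraph); below `bruteForceLimit`
(default 12) nodes it simply enumerates all $2^{n-1}-1$ bipartitions. This
choice — minimum directed cut rather than a pendant-pair routine for
symmetric set functions — was made because it rests on an elementary
identity, needs no submodularity argument, and is exact at every size; the
equivalence of the two paths is part of the test contract (they are compared
against exhaustive enumeration on one hundred random graphs).

`listComplexes()` uses hierarchical divide and conquer: find a min-cut of
the whole node set; any subset straddling that cut has a min-cut weight no
larger than the cut's strength (its induced bipartition crosses a subset of
the edges in each direction), so no complex except the whole set straddles
it; recurse into both sides. A recursion-tree subset is a complex exactly
when its $w^{\mathrm{mc}}$ is positive and strictly exceeds every
ancestor's. If the whole graph's min-cut weight is zero (disconnected or
partly unidirectional networks) the whole graph is simply not a complex and
recursion proceeds through the zero cut.

Numerical conventions: min-cut weights are compared with a relative
tolerance of $10^{-9}$, and a superset whose $w^{\mathrm{mc}}$ ties within
tolerance *blocks* complex status (the definition requires strict
inequality). Multiplying all weights by $c > 0$ scales all min-cut weights
and coreness by $c$ and leaves memberships unchanged.

### Comparison metrics

To quantify what bidirectionality adds, the package also provides:

* `symmetrize()` — analysis "regardless of bidirectionality": replace the
  weight matrix by $(W + W^\top)/2$ and rerun the complex search. Summing
  crossing edges regardless of direction (halved for consistency) is
  exactly the bidirectional measure applied to this symmetrized network.
* `weightedDegree()` — sum of attached edge weights, both directions.
* `sCore()` — weighted s-core decomposition on the symmetrized network:
  iteratively remove the minimum-strength node (strengths recomputed from
  scratch after every removal, levels taken at the realized strength
  values, no grid), a node's s-coreness being the largest level at which it
  survives.
* `fricScore()` / `fricRichClub()` — the functional rich-club score
  $G_{\mathrm{FRIC}}(k) = \sum_{i,j \in k} W_{ij} + \sum_{i \in k}\sum_j
  W_{ij} - \sum_i \sum_{j \in k} W_{ij}$ and a small-graph demonstration
  that selects, by exhaustive enumeration, the largest subnetwork scoring
  in the top 5% of its size class. The "top 5%" rule is only
  computationally defined by enumeration, so the demo restricts itself to
  size classes with at least 20 subsets (a 95th-percentile cutoff below
  that is vacuous) and to graphs of at most 16 nodes.

Per-node maps from different conditions are compared after dividing each by
its own maximum and averaging (`normalizeAverageCoreness()`); unequal
weights let two resting sessions count as one condition. The same
convention applies to the comparison metrics.

### Statistics

The statistics used to relate coreness to external per-region variables are
implemented in `pearsonBca()` (Pearson correlation with a bias-corrected and
accelerated bootstrap interval, pairs resampled jointly, 10,000 resamples by
default; degenerate bias or acceleration falls back to the percentile
interval with a warning), `regressionBand()` (the closed-form pointwise
confidence band for the least-squares line, $t$ quantile on $n-2$ degrees of
freedom), and `oneWayAnova()` (classic between/within decomposition with
$\eta^2 = SS_b / SS_t$; fully separated groups with zero within-group
variance yield $\eta^2 = 1$ and an infinite $F$ by convention).

## Synthetic data: what it emulates, what it does not

`makeToyNetwork()` builds the worked-example graphs. The `fig1d_like`
pattern places a complete reciprocal quartet {E,F,I,J} (weight 3), attaches
B reciprocally to E and J (weight 2), and wires {A,C,D,G,H} into a purely
feedforward periphery (weight 5: A feeds C and D; C and D feed every core
node; every core node feeds G and H). The edge weights are free parameters
of the pattern; the defaults were fixed once, with the feedforward
weight deliberately high enough that the *symmetrized* analysis pulls
feedforward nodes into its top core while the bidirectional analysis never
does — the central qualitative contrast. With these defaults the complexes
are {E,F,I,J} ($w^{\mathrm{mc}} = 9$) nested in {B,E,F,I,J} ($4$); the whole
graph has $w^{\mathrm{mc}} = 0$ and is no complex. The `two_modules` pattern
(two reciprocal triangles bridged by one reciprocal edge) yields two equal
maximal-strength complexes — the globality contrast with degree-based
methods, which lump the whole graph together.

`simulateVarTimeSeries()` generates stationary VAR(1) series with a planted
coupling matrix (spectral radius checked, burn-in of 100 frames discarded).
Only lag-1 ground truth is planted even though estimation uses $T = 10$:
this keeps the analytic covariance oracles tractable while still exercising
the estimator's full lag depth. The simulations are *not* a hemodynamic
forward model — no HRF convolution, measurement noise spectra, or
physiological confounds — so passing the recovery tests demonstrates the
statistical machinery, not robustness to fMRI artifacts.

## Worked example

```{r toy}
net <- makeToyNetwork("fig1d_like")
dec <- listComplexes(net)
complexTable(dec)
metricValues(coreness(net))
complexMembers(listComplexes(symmetrize(net)), 1)
```

The end-to-end path is exercised by `runPipeline()`, which chains
preprocess, estimation, thresholding, extraction and metrics, writes every
stage as TSV plus a provenance JSON (configuration, seed, configuration
hash), and is bit-identical on rerun.

## Problem sizes used in the test suite

The automated checks run at deliberately modest sizes chosen once as
representative: oracle equivalence on one hundred random digraphs of 4--8
nodes; planted-core recovery over 50 simulation seeds at coupling 0.4 with
20 trials of 500 frames on 5 nodes (lag order 10, 100 surrogates);
surrogate-test calibration over 200 independent-series replicates (3 trials
of 200 frames); BCa coverage over 500 replicates of $n = 200$ with 2,000
resamples; and a recovery-rate grid over coupling 0.2--0.5 and lengths
250--1000 frames with 3 trials. The grid saturates quickly: at these trial
counts recovery is near-perfect across the grid, so the monotonicity check
is a guard against regressions rather than a sharp power curve.

## Known limitations

* The bivariate (pairwise) VAR cannot distinguish direct influence from
  influence routed through a third node; a chain A→B→C generally yields a
  significant A→C edge. Conditional, fully multivariate transfer entropy is
  out of scope.
* KDE tail p-values are smooth but approximate for very few surrogates;
  with the default 100 surrogates the calibration test keeps the empirical
  rejection rate within the binomial band of the nominal level.
* The exact complex search scales with the cost of repeated global min-cut
  computations (polynomial); the exhaustive rich-club demo and the
  brute-force oracles are exponential and restricted to toy sizes.
* Surrogate alternatives (circular shift, IAAFT), upstream imaging
  pipelines (parcellation, nuisance regression) and spatially
  autocorrelated null maps for region-level correlations are intentionally
  not provided.
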