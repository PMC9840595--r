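---
title: "Hierarchical graph metrics for effective connectivity matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical graph metrics for effective connectivity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmgraph)
```

## The data model

The package analyzes group-level *effective connectivity matrices* (ECMs):
square, signed, weighted, directed matrices estimated for a large-scale
resting-state brain network of 36 regions grouped into seven resting-state
networks (RSNs). Entry $(i, j)$ is the coupling rate, in Hz, with which region
$j$ (column, source) drives region $i$ (row, target); it is the endogenous
coupling matrix $A$ of the linear neuronal-state model

$$\dot{x}(t) = A\,x(t) + v(t),$$

with $v(t)$ stochastic fluctuations. The diagonal entries are not couplings
but dimensionless log-scaling parameters $z_i$ of a default self-inhibition:
the effective self-connection is $-0.5\,e^{z_i}$ Hz, so $z_i = 0$ means
$-0.5$ Hz and positive $z_i$ means stronger self-inhibition. Upstream
Bayesian model reduction prunes uninformative couplings to exactly zero, so
the reader treats missing values as errors: a pruned coupling must be encoded
as 0.

Such a matrix is a signed, directed network *with loops*, for which standard
graph metrics are not defined. Following the two-step construction used in
this literature, the package derives

* a **WDCM** (weighted directed connectivity matrix): absolute values of the
  off-diagonal couplings, zero diagonal — the magnitude of an inhibitory
  influence is treated as its energetic cost; and
* a **WUCM** (weighted undirected connectivity matrix): the symmetric matrix
  $u_{ij} = w_{ij} + w_{ji}$ summing the two orientations of each pair.

Self-inhibitions are summarized separately (`self_inhibition_summary()`);
group-difference matrices (dECMs) are a distinct type that is never passed
through the graph transforms, because a difference of connectivities is not a
connectivity.

## Brain-level metrics

* **Strength.** $S = \sum_{i,j} u_{ij}$ over the WUCM. Because the matrix is
  symmetric the ordered sum is exactly twice the sum over unordered pairs;
  `total_strength()` exposes both conventions (`ordered_sum`, `pair_sum`)
  since published tables do not always say which was used.
* **Balance.** Reciprocal differences $w_{ij} - w_{ji}$ (upper minus lower
  triangle in atlas order, 630 pairs for 36 regions) are tested against zero
  mean with a two-sided one-sample t-test; the balance statistic is
  $-\log_{10} p$. The p-value is floored at $10^{-16}$ so the statistic stays
  finite; observed statistics live far below that cap. Blocks with a single
  pair (within a 2-region RSN) have no t-test and are reported `NA`.
* **Weighted assortativity.** A Pearson correlation over directed edges,
  each edge weighted by its coupling strength, between the source node's
  out-strength and the target node's in-strength (out/out and in/in variants
  are available via `assort_mode`). On a symmetric matrix all variants reduce
  to plain node strength at both ends.
* **Small-world propensity (SWP).** A density-independent small-worldness
  score for weighted graphs:
  $$\mathrm{SWP} = 1 - \sqrt{\frac{dC^2 + dL^2}{2}},$$
  where $dC = (C_{latt} - C_{obs})/(C_{latt} - C_{rand})$ and
  $dL = (L_{obs} - L_{rand})/(L_{latt} - L_{rand})$, both clipped to
  $[0, 1]$ before the formula. The clipping is essential: on single
  realizations the observed clustering can exceed the lattice reference (and
  analogously for path length), and without clipping SWP could leave
  $[0, 1]$.

### Null models and numerical choices

The lattice and random references are *weight-reassignment* surrogates that
preserve the weight multiset (zeros included, hence also density) exactly:

* `lattice_null()` places the sorted weights onto upper-triangle slots sorted
  by ring distance $\min(|i-j|,\ n-|i-j|)$, largest weights at the shortest
  distances. Ties are broken stably (descending weight, row-major slot), so
  the null is deterministic and idempotent.
* `random_null()` permutes the weights uniformly over the slots, seeded.

`small_world_propensity()` draws `n_null` random surrogates (default 1000),
computes $dC$, $dL$ and SWP per realization, and reports means and the sd of
SWP. Realizations with a degenerate denominator ($C_{latt} = C_{rand}$ or
$L_{latt} = L_{rand}$) are dropped and counted in the result.

Two conventions matter and are stated prominently:

* **Clustering** is the Onnela geometric-mean triangle intensity on weights
  normalized by the maximum weight; nodes with fewer than two neighbors
  contribute 0 to the mean. A Barrat (arithmetic-mean) variant is available
  behind the `variant` argument.
* **Path length** converts weights to distances as $1/w$ — strong couplings
  are short — and averages shortest-path lengths over connected ordered
  pairs, excluding disconnected pairs with a warning. $dL$ depends directly
  on this choice.

## RSN-level aggregation and regional screening

Every global metric is recomputed per block of the 7×7 RSN partition
(`rsn_metric_matrix()`): diagonal cells aggregate within-network pairs,
off-diagonal cells the between-network pairs. Strength cells sum the directed
entries over the block's directed edges, so the 28 blocks partition the 630
pairs and the cell total reconstructs the global pair-sum strength exactly
(this conservation is asserted in the test suite). Block assortativity
computes endpoint strengths on the block-induced edge set (the within-subset
assortment); full-matrix strengths are available via `strength_scope =
"full"`. `block_summary()` reduces the matrix to within/inter mean, max and
min, excluding undefined cells.

Regional screening (`regional_diff()`) works on the group-difference matrix:
for each region the incident off-diagonal entries (row ∪ column, i.e. both
afferent and efferent differences, 70 values for 36 regions) are split into
strictly positive and strictly negative parts and averaged separately.
`flag_regions()` flags regions strictly beyond the $q$ and $1-q$
linear-interpolation sample quantiles of those averages. The default
$q = 0.05$ flags roughly two regions per side among 36; decreases are kept
signed internally and reported as magnitudes in human-readable output.

## The synthetic generator: what it emulates, what it does not

`synthetic_spec()` + `sample_group_ecm()` generate atlas-conforming group
matrices with the structural features the pipeline consumes:

* Gaussian coupling magnitudes with **block structure** — within-RSN slots
  N(0.01, 0.004) Hz, between-RSN slots N(0.003, 0.0015) Hz by default,
  chosen so the global pair-sum strength lands at a few Hz, the scale of
  group-level effective connectivity;
* a **negative fraction** (default 0.4) of inhibitory couplings;
* **pruning**: each off-diagonal slot is zeroed with probability
  $1 - \mathrm{density}$ (default density 0.94, i.e. ≈76 of the 1260 slots,
  the scale of model-reduction pruning in 36-region group models);
* diagonal log-scaling parameters N(0.2, 0.1).

`sample_cohort()` adds subject-level Gaussian noise *only on nonzero slots*,
so the pruning structure survives cohort averaging, mirroring how model
reduction fixes pruned parameters at their priors. `plant_difference()`
injects known deltas on chosen directed edges and returns the exact
difference matrix as ground truth. `ws_weighted_graph()` provides
Watts–Strogatz graphs with i.i.d. weights for validating the small-world
machinery, and `simulate_neuronal()` integrates the linear state equation
with Euler–Maruyama steps (default dt = 0.01 s; higher-order schemes are out
of scope, and the closed-form decay test in the suite bounds the integration
error at this step size).

The generator does **not** emulate posterior uncertainty or covariance
between couplings, hemodynamics, measurement noise, or the model-inversion
process that produces real ECMs. Passing tests therefore demonstrate that the
*graph characterization* is correct and recovers planted structure under
realistic magnitudes — not that any upstream estimation step is valid.

### Recovery study conditions

The parameter-recovery checks use two cohorts of 20 subjects with
between-subject sd 0.005 Hz and planted deltas of 3× the within-block weight
sd (0.012 Hz) on six directed edges incident to each truth region. These
conditions come from a design calculation: the noise on a cohort-mean
difference per edge is $0.005\sqrt{2/20} \approx 0.0016$ Hz, an order of
magnitude below the planted effect, so the flagged regions should recover the
truth in essentially every replicate.

### Statistical reading of the Watts–Strogatz trend checks

Across a rewiring-probability sweep ($p \in \{0, 0.1, \dots, 1\}$, 50
unit-weight graphs per $p$, 20 nulls per graph) mean $dC$ rises and mean
$dL$ falls with $p$, and mean SWP peaks at intermediate $p$. Beyond
$p \approx 0.5$ both curves saturate and the ensemble means carry a sampling
noise floor of about 0.003, so the monotonicity assertions are strict in the
unsaturated region and allow three standard errors of the paired difference
in the saturated tail; no finite ensemble of this size can distinguish a
flat-but-noisy segment from a strictly monotone one. Unit weights are used
because a $p = 0$ graph with heterogeneous weights is not weight-sorted and
so differs from its own lattice null.

## Degenerate inputs

* All-zero matrices: strength 0, balance $-\log_{10}p = 0$ (p = 1); SWP and
  assortativity are undefined and reported `NA`, with the reason recorded in
  the report provenance.
* Zero-variance reciprocal differences with nonzero mean: p capped at
  $10^{-16}$ with a degeneracy flag.
* Regular graphs (zero variance of endpoint strengths): assortativity is an
  error at the function level and an `NA` cell at the RSN level.
* Unstable coupling matrices are refused by the simulator unless forced.

## Problem sizes

All matrices are 36×36; the SWP ensemble default is 1000 nulls (a few
seconds at this size). The test suite validates metrics against brute-force
oracles on graphs up to $n = 12$, where exhaustive triple and path
enumeration is exact and fast, and runs the recovery study at 100 replicates.

## Limitations

* The pipeline characterizes *given* group-level matrices; it does not
  estimate connectivity, model posterior uncertainty, or perform group
  inference beyond the descriptive balance statistic.
* The $1/w$ distance convention and the Onnela clustering variant are
  choices; alternatives (Barrat clustering, out/out and in/in assortativity
  endpoints, sum-mode S_diag) are exposed as arguments, and results should be
  reported together with these conventions.
* Published block-level strength tables in this literature are not always
  numerically consistent with a single summation convention for the global
  strength; this package computes plain block sums, whose total provably
  reconstructs the global pair-sum strength, and leaves any hidden
  normalization to the reader of the original tables.
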