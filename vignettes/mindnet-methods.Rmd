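---
title: "Information-theoretic causal discovery with mindnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic causal discovery with mindnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindnet)
```

## The problem

Given a rectangular table of observations over mixed continuous and
categorical variables, mindnet learns a partially oriented graphical model in
which edges represent direct statistical dependences and certain arrowheads
can be read causally: a *genuine* cause (significant head and tail), a
*putative* cause (significant head only, compatible with an unmeasured
confounder), a *bidirected* edge (two significant heads, the signature of a
latent common cause), or an undirected edge. The approach is constraint-based:
edges are removed when a (conditional) independence can be established, and
orientations are derived from the characteristic three-variable pattern of
causality in observational data, the v-structure.

## Regularized mutual information

All decisions rest on one scalar quantity: the regularized (conditional)
mutual information

$$I'(X;Y \mid \{A_i\}) = I(X;Y \mid \{A_i\}) - \frac{k_{X;Y|\{A_i\}}(N)}{N},$$

in nats per sample, where $k(N)$ is a complexity penalty that grows with the
level counts of the variables, the number of conditioning strata, and the
sample size $N$. Dependence is declared when $I' > 0$; a negative value
signals (conditional) independence and is *rectified* to exactly zero. The
rectification is not cosmetic: since a single-bin partition of either
variable always achieves $I' = 0$ and the estimate is defined as a supremum
over partitions, a negative value merely means the supremum was attained at
the trivial partition, so zero is the estimate. Rectification propagates
through every downstream formula and in particular forces the three-point
information of a doubly-independent triple to vanish exactly, which is what
prevents the orientation of self-contradictory v-structures.

Two penalties are provided (`mode` in `mindnet_control()`):

* `"nml"` (default): a normalized-maximum-likelihood penalty. Per
  conditioning stratum of size $n_j$ it charges
  $\log C_{r_x r_y}(n_j) - \log C_{r_x}(n_j) - \log C_{r_y}(n_j)$, where
  $C_L(n)$ is the parametric complexity of an $L$-category multinomial,
  computed by the standard linear recurrence. This is the difference in
  stochastic complexity between the joint and independent multinomial
  codes, and it converges to the BIC penalty for large $n$.
* `"bic"`: $\tfrac12 (r_x-1)(r_y-1)\, r_{\mathrm{cond}} \ln n$, kept as a
  transparent fallback.

The exact finite-sample penalty is not uniquely pinned down by the
literature this design follows; both choices are deliberately isolated
behind `complexity_term()` so they can be swapped.

## Optimal discretization of continuous variables

Mutual information involving a continuous variable is defined as the supremum
of the penalized plug-in information over partitions of that variable, with
the number *and* positions of cut-points free. The search is a
dynamic program over a candidate grid of cut-points (boundaries between
distinct sorted values, capped at `2 * max_bins` candidates, equally spaced
quantile boundaries when more are available). The partition cost is an
additive MDL scheme: one extra bin of $X$ against an opposite factor with
$r$ levels costs $\tfrac12 (r - 1)\ln N$ (the BIC increment of the joint
table) plus $\ln K$ for coding the cut-point position among $K$ candidates.
Additivity keeps the dynamic program exact given the candidate grid; this is
why the continuous search does not use the NML penalty, which is not
additive in the bin count.

When both variables are continuous the two partitions are optimized
alternately (at most 20 rounds, convergence at $10^{-9}$ on the joint
objective). Because the alternation cannot refine past the resolution of the
partner's current partition for near-deterministic relations, unconditional
pairs are started twice — once from a coarse equal-frequency grid
($\min(\texttt{max\_bins}, \lfloor n^{1/3}\rfloor)$ bins) and once from the
finest allowed grid — and the run with the better final objective wins.
Partitions never exceed `max_bins` (default 50), which keeps the overall
cost of an estimate essentially independent of how strongly the pair is
associated and near-linear in $n$; with this package's cut-point penalty the
cap binds for an exactly duplicated variable from roughly $n = 10^5$ up.

A conditional estimate $I'(X;Y\mid U)$ for a tuple involving continuous
variables proceeds in two stages. Partitions are selected by the supremum
search applied to the joint term $I'(X;\{Y,U\})$ (conditioning variables
merged into one joint factor; each continuous conditioner discretized into
2–5 equal-frequency bins, fewer when several continuous conditioners would
fragment the sample; the lexicographically smaller variable is the outer
argument, for determinism). The estimate itself then treats the
discretized variables exactly like categorical ones: the stratified plug-in
conditional information of the selected partitions, minus the per-stratum
complexity penalty and the cut-point coding costs. Keeping the reported
value on the categorical scale — rather than differencing two jointly
penalized optima — is what preserves conditional information for
continuous tuples; the supremum machinery is retained purely for choosing
cut-points. All-categorical tuples are computed directly from stratified
contingency tables.

During a learning run one further convention applies: a pair whose marginal
supremum fixed a non-trivial partition keeps those codes for all of its
conditional tests, so the telescoping contributor decomposition of that
pair lives on a single discretization and contributions compare like with
like; partitions are re-optimized under conditioning only where the
marginal estimate vanished (the v-structure scoring terms, which ask
whether dependence appears once a collider is conditioned on). The
stand-alone estimator `conditional_mi_reg()` always re-optimizes.

Every estimate uses the complete cases over exactly the variables involved
(tuple-wise deletion); this is the minimal contract for tables with missing
entries, and no imputation or missingness-aware correction is attempted.

## Skeleton learning

Starting from the complete graph, pairs with $I'(X;Y) = 0$ are removed
outright with empty separating sets. Each surviving edge then iteratively
collects *information contributors*: conditioning variables that carry away
part of the pair's dependence. A candidate $A$ qualifies if its raw
three-point contribution exceeds the complexity increase of the extended
conditioning set (a significance requirement that blocks junk contributors,
whose raw contribution is near zero while the penalty grows), or — under
the default `contributor_rule = "closure"` — if adding it drives the
rectified residual $I'(X;Y\mid\{A_i\},A)$ to exactly zero, in which case it
completes a separating set and the edge is removed on the spot.
`contributor_rule = "significance"` disables the closure clause; it keeps
more weak true edges at the cost of retaining weak indirectly-dependent
pairs, trading skeleton precision (about 0.95 versus 0.65 on the synthetic
benchmarks) for recall. Candidates are drawn from the union of the
endpoints' current neighborhoods (`scope = "common"` restricts to common
neighbors). At each
global step the edge whose residual minus its best next contribution is
smallest — the most confidently reducible one — moves first, so removals
happen in decreasing order of confidence. An edge whose conditioning set
reaches `max_cond` (default 20) is retained. Ties between equal-scoring
contributors or edges are broken lexicographically, which together with the
deterministic estimators makes the whole run reproducible bit for bit.

## Orientation

For every unshielded triple $X - Z - Y$ (arms present, $X,Y$ non-adjacent)
the signed conditional three-point information
$N\,I'(X;Y;Z\mid\{A_i\})$ is computed, conditioning on the separating set
recorded for the removed pair (minus $Z$ if it appears there). A negative
value is the signature of a v-structure and yields the head probability

$$P = \frac{1 + e^{N I_3'}}{1 + 3\,e^{N I_3'}} \in [0.5, 1),$$

handled in score form, $\mathrm{score}_v = -N I_3' + \mathrm{log1p}(e^{N I_3'}) - \ln 2$
with $P = (1 + e^{-\mathrm{score}_v})^{-1}$, so that orientations remain
strictly ordered even when the probabilities are numerically
indistinguishable from 1 at very large $N$. Orientations are applied in
decreasing score order, and a mark placed by a higher score is never
overwritten; equal scores resolve toward the lexicographically earlier
triple.

A landed arrowhead $Z \leftarrow Y$ induces further orientations through the
positive (non-v) triples it participates in: the far arm receives a tail at
$Z$ with the rectified induced score

$$\mathrm{score}_i = \max\!\big(0,\; m - \mathrm{log1p}(e^{m-M} + e^{-M})\big),
\qquad m = \min(N|I_3'|, \mathrm{score}_v),\; M = \max(N|I_3'|, \mathrm{score}_v),$$

whose probability provably never exceeds that of the head it derives from.
With `propagate = TRUE` the induced tail also lands as a head at the
opposite undefined end (the propagation rule of benchmark graphical models);
propagation is off by default for real-data analysis because it encodes a
structural assumption rather than information in the data, and on in the
benchmark harness.

Contextual variables (externally fixed quantities such as sex or year of
birth) are pinned before scoring: every one of their endpoints has
$p_{\mathrm{tail}} = 1$ and arrowheads into them are refused.

Finally each present edge is classified at threshold $\beta$ (default 0.5):
genuine (head $> \beta$ on one end, tail $> \beta$ on the other), putative
(significant head only), bidirected (two significant heads — interpreted as
a latent common cause), else undirected.

## Indirect-path consistency

A removed pair's separating set should be interpretable as indirect paths in
the final graph. Two levels are enforced by `learn_consistent()`: *skeleton*
consistency (every separating-set node lies on a simple path between the
extremities — checked by a two-commodity vertex-disjoint-path argument via
max-flow, a direct implementation of the contract rather than a block-cut
tree decomposition) and *orientation* consistency (additionally, each node
is a neighbor of an extremity of which it is not a descendant, descent
following single-head edges only). Learning is repeated with candidate
contributors filtered against the previous iteration's graph until the graph
sequence revisits a state; the edge-union of the limit cycle is returned,
with conflicting endpoint marks resolved toward the highest-probability mark
and ties to undefined. A fixed point is a cycle of length one and is
detected on the second iteration. If no cycle appears within
`max_iterations` (default 100) the union of the last two graphs is returned
and flagged (`meta$converged = FALSE`).

## Indirect contributions

For every non-independent pair, the fraction of its regularized information
explained by each collected contributor is
$\mathrm{IndC}(A_k) = I'(X;Y;A_k\mid\{A_i\}_{k-1})\,/\,I'(X;Y)$, computed
from the rectified telescoping differences recorded during skeleton
learning, so that per pair $\sum_k \mathrm{IndC}(A_k) + \text{residual
fraction} = 1$ holds to machine precision, with zero residual for removed
edges. Percentages are rounded only in the output table.

## The synthetic benchmark generator

`generate_benchmark()` emulates a nationwide cancer-registry style dataset:

* **Skeleton**: 51 nodes with degrees drawn from a right-skewed negative
  binomial (mean degree about 11, hence about 280 edges), jittered by ±2
  connections per node, realized deterministically and randomized by
  degree-preserving edge swaps.
* **DAG**: edges oriented along a uniformly random node ordering.
* **Types**: a configurable fraction of nodes categorical with 2–6 levels.
* **Sampling**: topological-order structural equations. Continuous roots
  follow a two-component location mixture (bimodal, like age or income
  distributions); categorical roots a skewed multinomial with 40–70% of the
  mass on the largest level. Each parent contributes one standardized effect
  with magnitude drawn in $[0.3, 1.0]$; continuous children add unit
  Gaussian noise; categorical children are drawn from a multinomial logit
  whose level scores are ordered, so every parent acts through a monotone
  linear predictor. The ordered-score form is deliberate: unstructured
  per-level weights frequently produce XOR-like mechanisms that are
  marginally unfaithful and unrecoverable by any constraint-based method,
  which would make the benchmark measure the generator rather than the
  learner.

What the generator does *not* emulate: missing data, selection bias,
near-deterministic clinical redundancies, contextual variables, and latent
confounders (every variable of the DAG is observed). Benchmark results
therefore speak to structure recovery under faithful mixed-type sampling,
not to robustness against those real-data complications.

`score_graphs()` reports precision, recall and F at three levels: skeleton
(presence only), CPDAG (an edge found but with the wrong orientation state
counts as a false positive), and the oriented-edge subgraph — precision,
recall and F restricted to the edges oriented in the true CPDAG versus the
edges carrying significant heads (genuine, putative or bidirected) in the
inferred graph. The oriented-subgraph scores are the causal-discovery
headline numbers: they measure exactly the subset of orientations that is
identifiable from observational data.

## Problem sizes and runtime

The default benchmark setting (51 nodes, mean degree 11, $N$ = 500–1000)
takes roughly 15–60 seconds per network on one core (continuous-heavy
settings are the slower end), dominated by conditional-information
evaluations during contributor collection; all estimates are memoized per
run and the dynamic program and counting kernels are compiled. The test
suite and the acceptance script use 8 networks per benchmark setting at
these sample sizes. Sample sizes of $10^5$ remain tractable for single
pairwise estimates (the candidate-grid DP is near-linear in $n$) but whole-
network runs at that scale are outside the default suites.

## Known limitations

* Categorical level-merging is implemented only as the single-bin-vs-full
  comparison implicit in rectification; the full supremum over level
  groupings is out of scope, which makes conditional estimates for
  many-level categorical variables more conservative than the ideal.
* The greedy contributor search can remove a weak true edge when a
  high-cardinality neighbor zeroes its rectified residual in one step;
  orientation precision at small $N$ is bounded by such erroneous
  removals, which later surface as false v-structures on shielded triples.
* Conditional estimates bin continuous conditioning variables marginally
  (2–5 equal-frequency bins) instead of optimizing their partitions jointly,
  trading estimator sharpness for tractability.
* The consistency iteration is guaranteed to terminate only through its
  iteration cap; convergence to a limit cycle is empirical, not proven.
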