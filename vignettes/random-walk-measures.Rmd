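---
title: "Random-walk information measures for weighted connectomes: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk information measures for weighted connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectropy)
```

## The model

A weighted undirected brain network is a graph $G=(N,E)$ on $n$ nodes with
a symmetric, nonnegative, zero-diagonal connectivity matrix $C$. We model
activity as a random walk: a particle on node $x_i$ steps to $x_j$ with
probability proportional to the edge weight,

$$P_{ij} = \frac{C_{ij}}{C_i}, \qquad C_i = \sum_j C_{ij}.$$

This is a first-order Markov assumption: the next region depends only on
the current region and its connections, not on the walk's history. For an
undirected graph the chain is reversible and its stationary distribution is
available in closed form,

$$\mu_i = \frac{C_i}{C_T}, \qquad C_T = \sum_{i,j} C_{ij},$$

which satisfies detailed balance $\mu_i P_{ij} = \mu_j P_{ji}$ exactly.
Two useful consequences, both verified as property tests: $\mu_i$ is
*local* (it depends only on the node's own strength and the total weight,
so rewiring elsewhere at constant $C_T$ leaves it unchanged), and both $P$
and $\mu$ are invariant under rescaling $C \mapsto cC$, $c>0$.

`random_walk_model()` is the single fitting function; it returns a classed
object carrying $(C, P, \mu)$ on which all measures, and the usual
`print`/`summary`/`coef`/`predict`/`simulate`/`plot` methods, operate.

### Global measures

All logarithms are base 2, results are in bits, and $0\log 0 = 0$
(zero-probability terms are skipped).

* **Stationary entropy** $H(\mu) = -\sum_i \mu_i \log_2 \mu_i$: the
  uncertainty of the walker's position; maximal, $\log_2 n$, when all
  strengths are equal.
* **Mutual information** $I(X_t;X_{t+1}) =
  \sum_i \mu_i \sum_j P_{ij}\log_2 (P_{ij}/\mu_j)
  = H(\mu) - H(X_{t+1}\mid X_t)$: the information the present node carries
  about the next one. For a stationary Markov chain this equals the excess
  entropy of the process, so it can be read as the amount of structure in
  the network.
* **Erasure mutual information** $I^-(X) = H(X_t) -
  H(X_t \mid X_{t-1}, X_{t+1})$: the reduction in uncertainty about the
  present state when its full context (past *and* future) is known. High
  values indicate networks of predictable, unique paths. It always
  satisfies $0 \le \mathrm{MI} \le \mathrm{EMI} \le H$.

### Local measures

Each global measure admits a per-node decomposition
$\sum_i \mu_i\,v_i = \text{global}$, which the package treats as a
machine-checkable contract (tolerance $10^{-9}$ in the tests):

* entropic surprise $E_i = -\log_2 \mu_i$ (an exact log transform of
  strength: $E_i = \log_2 C_T - \log_2 C_i$);
* mutual surprise $I_{1,i} = \sum_j P_{ij}\log_2(P_{ij}/\mu_j)$, the
  Kullback–Leibler divergence of the node's next-step law from $\mu$,
  always nonnegative;
* mutual predictability $I_{2,i} = H(\mu) + \sum_j P_{ij}\log_2 P_{ij}$,
  which may be negative (a node whose outgoing distribution is more
  uncertain than the network average) and is additive over observations;
* erasure surprise $I^-_{1,i}$, the KL divergence between the
  (past, future) pair distribution conditioned on the present node and its
  stationary marginal $p(j,k) = \mu_j Q_{jk}$, $Q = P^2$; high for
  bridge-like nodes whose neighbours are not otherwise interconnected.

The printed closed form of the erasure surprise collapses several
fractions; we derive it instead through Bayes' rule and reversibility —
the backward step probability $p(X_{t-1}{=}j \mid X_t{=}i) =
\mu_j P_{ji}/\mu_i$ equals $P_{ij}$ — giving

$$I^-_{1,i} = \sum_{j,k} P_{ij}P_{ik}\,
  \log_2\!\frac{P_{ij}P_{ik}}{\mu_j Q_{jk}},$$

validated by the decomposition identity
$\sum_i \mu_i I^-_{1,i} = \mathrm{EMI}$ and by a brute-force enumeration
oracle in the test suite.

## Numerical choices

* **EMI without the $n^3$ joint.** Because $\mu$ is exactly stationary, the
  conditional entropy over (past, present, future) triples reduces to
  $H(X_t\mid X_{t-1},X_{t+1}) = 2\,H(X_{t+1}\mid X_t) -
  H(X_{t+1}\mid X_{t-1})$, where the last term uses the two-step kernel
  $Q=P^2$. The implementation therefore costs one matrix product plus
  $O(n^2)$ accumulation. The test suite keeps an independent $n^3$
  enumeration of the full triple joint and requires agreement to $10^{-9}$
  on randomized graphs with $n \le 8$.
* **Zero handling.** Isolated nodes (strength 0) stay in the model with
  $\mu_i = 0$ and an all-zero transition row; they contribute nothing to
  global measures and are reported as `NA` in per-node tables — an explicit
  not-applicable marker rather than a silent 0 or $\infty$. Pairs with
  $Q_{jk}=0$ contribute nothing (their conditional probability is also 0;
  on the support of $P_{ij}P_{ik}$ one always has $Q_{jk} \ge P_{ij}P_{ik}
  > 0$).
* **Cancellation guard.** Quantities that are nonnegative by theory but
  computed by subtraction are clamped to 0 only when the negative excursion
  is below $10^{-9}$; anything larger raises an internal-consistency error
  instead of being masked.
* **Tolerances.** Stochasticity and normalisation checks use $10^{-12}$
  absolute; symmetry of inputs likewise.
* **Directed or negative inputs.** Directed matrices are not solved as
  directed chains (the closed form for $\mu$ requires reversibility);
  callers must opt into symmetrization, which copies the upper triangle
  below the diagonal. Negative weights (thresholded functional
  correlations) are rejected unless explicitly clipped to zero.

## Reference measures and comparison fits

Strength, eccentricity and clustering are the conventional yardsticks.
Two genuinely open choices were fixed as follows:

* **Edge length for shortest paths** is $1/w$, the standard
  connectivity-to-distance inversion in the connectomics literature; a
  binary mode (`weighted = FALSE`) is available since hop-count
  eccentricity is also in common use. Nodes that cannot reach the whole
  graph have undefined eccentricity (`NA`).
* **Weighted clustering** uses the Onnela geometric-mean triangle
  intensity with weights normalised by the maximum weight, the weighted
  undirected variant used by the standard brain-connectivity toolchain;
  it is hand-implemented here because the igraph weighted transitivity is
  the Barrat variant, a different quantity.

`correlate_measures()` fits $f(x) = a + b\log_2 x$ by least squares and
reports $R^2 = 1 - SS_{res}/SS_{tot}$. Pairs with nonpositive $x$ are
dropped (the log is undefined; e.g. tree nodes with clustering 0), and
fewer than three remaining pairs is an error rather than a silent fit. Two
degenerate cases are defined explicitly: a constant response against a
varying predictor has $R^2=0$ (no information), while a constant response
against a constant predictor — e.g. entropic surprise vs strength on a
regular graph, an exact relation — has $R^2=1$.

## Synthetic network families

The generators produce the four benchmark topologies on $n$ nodes with an
exact number $m$ of undirected edges; weights are then drawn i.i.d.
uniform(0,1) (open interval, so edge presence and positive weight
coincide) after the topology, and every run is reproducible from its seed.
The published descriptions of the reference generators leave internals
open, so the procedures are fixed here once:

* *random*: $m$ distinct off-diagonal pairs drawn uniformly;
* *lattice*: pairs filled band by band away from the diagonal without
  wraparound, so boundary nodes have fewer connections;
* *ring lattice*: the same fill with wraparound — boundary-free and
  near-regular (degree $2k$ when $m = kn$);
* *small world*: contiguous fully connected modules of `cluster_size`
  nodes plus uniformly random inter-module edges up to $m$ (below the
  intra-module total, a uniform subsample of intra-module edges).

For the small-world family the module size for sweep-scale networks is not
prescribed anywhere, so the default is fixed once at
`cluster_size = ceiling(n/8)` — eight modules at any size, which keeps the
module structure visible across the whole node grid; it can always be set
explicitly.

`edge_sweep()` emulates the edge-count experiments (e.g. 128 nodes, edges
128 to 8192 in steps of 128; grid points beyond the complete graph are
clamped to it, mirroring a fixed-step grid overshooting $\binom{n}{2}$)
and `node_sweep()` the size experiment (32–512 nodes at density 0.4).
Replicates default to 10 per grid point, matching the ten-subject box
plots such experiments are usually summarised with. Per-run seeds are
derived from one master seed and recorded in the output table, so any
single row can be regenerated in isolation.

## What the synthetic data do and do not show

The generators emulate the *topological* regimes against which the
measures were characterised — density-driven entropy saturation at
$\log_2 n$, the rise-then-fall of MI as sparse graphs lose their isolated
nodes and then densify, the lower EMI of (ring-)lattices versus random and
small-world graphs, and $H \sim \log_2 n$ growth at fixed density. They do
**not** emulate real connectomes: empirical strength distributions are
heavy-tailed rather than uniform(0,1)-weighted, real networks have
geometric and hemispheric constraints, and functional matrices carry
thresholding artefacts. Passing the sweep tests therefore validates the
measures' behaviour as functions of controlled topology, not any clinical
claim. Experiments on human tractography or ICA datasets require those
(external) matrices as input files.

Problem sizes in the shipped tests were chosen so the full suite runs in
well under a minute on one core: enumeration oracles run at $n\le 8$ where
the $n^3$ joint is exact and cheap, decomposition identities at
$n \le 64$ over 200 random graphs, and the trend checks use 5 master seeds
over a thinned edge grid at $n=128$ plus a node grid to $n=512$. All
behaviours asserted are scale-stable, and the full-resolution grids are
available through the same functions.

## Known limitations

* Directed connectivity is handled only by symmetrization; there is no
  eigenvector solve for irreversible chains.
* The eccentricity of disconnected graphs is reported as `NA` for every
  node that cannot reach the full node set, rather than per-component.
* The log-curve comparison drops zero-clustering nodes; on triangle-free
  graphs the clustering fit errors by design.
* Measures are exact functionals of the input matrix: no estimation error
  model is attached when $C$ itself is an estimate (e.g. streamline
  counts), so uncertainty propagation is up to the caller.
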