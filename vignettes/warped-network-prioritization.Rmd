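---
title: "Prioritizing disease genes on a curvature- and prior-warped network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes on a curvature- and prior-warped network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warpnet)
```

## The problem

High-throughput case/control omics data reflect both the causes of a
disease state and its widespread downstream consequences. A per-gene
differential-expression score therefore flags far more genes than are
mechanistically interesting, and ranking by score alone performs barely
above chance against curated driver-gene lists. Network propagation —
spreading scores over a protein–protein interaction (PPI) graph — improves
this, but a classical random walk with restart (RWR) is indiscriminate: at
each node it treats all neighbors identically, regardless of whether an
edge leads into a protein complex, out of a promiscuous hub, or toward
genes already known to matter.

`warpnet` implements a three-stage warping pipeline that makes the walk
discriminate, using one *internal* feature (graph curvature, computable
from topology alone) and one *external* feature (a prior-knowledge gene
set), and then diffuses the omics scores over the warped network.

## Model and assumptions

### Stage 1 — curvature warping (internal)

For an undirected, unweighted, self-loop-free graph, the augmented
Forman–Ricci curvature of edge $e=(u,v)$ is

$$\kappa_e = 4 - |N_u| - |N_v| + 3\,|N_u \cap N_v|,$$

an integer on unweighted graphs. Inside a $k$-clique every edge has
$\kappa = k$; a spoke of a star with $d$ leaves has $\kappa = 2 - d$.
The biological reading: protein complexes are near-cliques, so their edges
carry high positive curvature, while hub spokes carry strongly negative
curvature. Because the raw range of $\kappa$ varies wildly between
networks, curvatures are standardized by their sample mean and standard
deviation (unbiased $n-1$ denominator over the unordered edge set — the
choice is documented and fixed so results are bit-stable) and mapped
through a sigmoid:

$$K_{ji} = \mathrm{Sigmoid}\!\big(\beta\,(\kappa_{(i,j)} - \overline{\kappa})/\mathrm{sd}(\kappa)\big)
\quad \text{on edges, } 0 \text{ elsewhere.}$$

$\beta$ controls the strength and *sign* of the curvature effect;
$\beta = 0$ gives every edge weight $1/2$, i.e. the original network up to
normalization. If all curvatures are equal (a single edge, one clique),
the standardization is undefined and the implementation falls back to the
uniform weight $1/2$ with a warning — this preserves the $\beta = 0$
semantics instead of erroring, a deliberate choice for a degenerate case
the formula leaves open. Curvature statistics are computed once per
network, not per connected component.

### Stage 2 — prior warping (external)

A prior gene set (e.g. known drivers) rarely covers everything relevant,
so it is *smoothed* before use. With $\phi$ uniform on the priors, the
column-stochastic restart kernel

$$P_{ji} = (1-\gamma)\,\frac{K_{ji}}{\sum_k K_{ki}} + \gamma\,\phi_j$$

has a stationary distribution $\pi$ ("smoothed prior knowledge"):
$\gamma = 1$ uses the priors raw, $\gamma = 0$ smooths completely. The
final warped adjacency scales incoming edges by the target's prior mass:

$$A^*_{ji} = K_{ji}\,\pi_j \ \text{ on edges.}$$

$A^*$ is asymmetric — the same undirected edge carries different weights
in its two directions ($A^*_{ji}/A^*_{ij} = \pi_j/\pi_i$ wherever
$\pi > 0$) — so the undirected input becomes implicitly directed, biased
toward prior-relevant regions. For $\gamma > 0$ on a connected network the
restart chain is irreducible and $\pi$ is strictly positive.

### Stage 3 — score diffusion

Initial scores $v^{(0)}$ are diffused by RWR over the warped network:

$$v^{(m+1)} = (1-q)\,A^* D^{*-1} v^{(m)} + q\,v^{(0)},$$

whose fixed point is $v^* = q\,(I - (1-q)A^*D^{*-1})^{-1} v^{(0)}$.
$D^*$ is the diagonal of **column sums** of $A^*$, so $A^*D^{*-1}$ is
column-stochastic; "degree matrix" is ambiguous for an asymmetric
adjacency, and column sums are the only axis consistent with the kernel
construction of stage 2 and with standard RWR conventions. $v^{(0)}$ is
used as given, with no normalization.

Variants as configuration: `pwn_no_curvature` substitutes the unweighted
adjacency for $K$, which is implemented as $\beta = 0$ because the two are
identical after column normalization (and this makes the equivalence
bit-exact); `rwr` diffuses over the raw adjacency; `rwr_curvature` over
$K$ without priors.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.5 | curvature sigmoid scale (dimensionless; sign flips the preference) |
| `gamma` | 0.5 | restart probability of the prior-smoothing kernel, in [0, 1] |
| `q` | 0.3 | restart probability of the score diffusion, in [0, 1] |
| `tol` | 1e-12 | L1 convergence tolerance of the iterative solvers |
| `max_iter` | 1e5 | iteration cap of the iterative solvers |

The hyperparameter defaults are the method's standard untuned settings.
Large $|\beta|$ squashes most edge weights to 0 and fragments the walk;
moderate $\gamma$ (roughly 0.3–0.7) balances using the priors against
discovering genes the priors miss.

## Numerical choices

* **Stationary distribution**: for $\gamma > 0$ the default is the
  closed-form sparse solve $\pi = \gamma(I - (1-\gamma)W)^{-1}\phi$
  (bounded, deterministic); power iteration (tol $10^{-12}$, cap $10^5$)
  is available as a cross-check and is the only route for $\gamma = 0$,
  which additionally requires a connected, non-bipartite network — the
  package refuses otherwise rather than return a non-unique or oscillating
  answer.
* **Diffusion**: closed-form sparse solve for $q \ge 0.05$, power
  iteration below. Both paths agree to $10\times$`tol` and are
  cross-checked against dense oracles in the test suite.
* **Zero-degree / zero-column nodes**: in the kernel, a zero-degree node's
  column becomes pure restart ($\phi$); with $\gamma = 0$ this is an
  error. In diffusion, a zero column stays zero after normalization and
  its outgoing mass leaks to the restart term only; both cases are logged.
* **Ties and determinism**: rankings sort by score descending with
  lexicographic gene-id tie-break; identical inputs reproduce identical
  outputs byte for byte.
* **Scoring clips**: p-values are clipped to $[10^{-300}, 1]$ before the
  Fisher log and to $[10^{-15}, 1-10^{-15}]$ before the normal quantile,
  keeping all statistics finite.

## Design decisions where the design was open

* **Z transform.** A common shorthand writes the transform as
  $\Phi(1-p)$, but a CDF applied to $1-p$ yields a probability, not a
  Z-score. The package implements the inverse CDF
  $Z = \Phi^{-1}(1-p) = -\Phi^{-1}(p)$, which is the only reading that
  produces a genuine Z-score and keeps the two shorthand forms equal.
* **t-test flavor.** Welch's unequal-variance two-sided test is the
  default (the robust modern choice); the pooled Student variant is a
  configuration option. Welch's slight conservativeness at small samples
  compounds under Fisher combination: with several null strata the
  combined Z acquires a small negative mean bias (about $-0.03$ at three
  5v5 strata), which is why the near-normality calibration is asserted per
  stratum.
* **Multiple-testing correction.** Benjamini–Hochberg is used for the
  family of paired method comparisons (the only standard reading of the
  procedure's description).
* **Train-gene exclusion.** Prior/train genes are removed from rankings
  before metrics are computed — leaving them in would let prior-based
  methods trivially "rediscover" their own inputs. A flag restores the
  strict-literal behavior.
* **Train-set size** uses base R's round-half-to-even.
* **Uniform-prior equivalence.** A uniform prior over all nodes yields a
  uniform $\pi$ only on regular graphs, because the kernel's non-restart
  part is degree-biased. The "$\beta=0$ + uniform $\pi$ equals plain RWR"
  identity is therefore asserted with uniform $\pi$ imposed directly (any
  graph) and through the full kernel chain on a regular graph.
* **Configuration.** The run configuration is a flat key-value object
  (`run_config()`); every CLI flag maps to one key. No YAML layer is
  shipped — flags and JSON manifests cover the contract without adding a
  parser dependency.

## The synthetic world

`planted_module_network()` generates the benchmark fixture: an
Erdős–Rényi background (default 300 nodes, edge probability 0.01), six
planted 8-cliques standing in for protein complexes, six star hubs of
degree 15, single-edge bridges to keep the graph connected (logged in an
attribute), a 40-gene ground truth with 80% of its mass inside the
cliques, and a 2:8 prior/test split convention. Cliques versus hubs give
the curvature signal its designed separation (clique edges always carry
higher mean curvature than hub spokes — a tested invariant).

Scores emulate the *weak-signal, pervasive-perturbation* regime of real
case/control omics: every gene carries a positive baseline
(`score_baseline = 3`, the typical magnitude of upper-tail Z-scores after
combining evidence across strata of a strongly perturbed transcriptome),
truth genes and their neighbors get a small additional shift
(`score_signal = 0.5`), and Gaussian noise (`sd = 1`) is added everywhere.
Two properties of this regime matter. First, the baseline keeps the score
field predominantly positive; a zero-mean score field would make the
expected inflow of any column-stochastic diffusion cancel, so *no*
prior-guided method could express its smoothed prior — positivity is a
property of real Z-vectors, not a concession to the method. Second, the
signal-to-noise ratio leaves the unweighted RWR baseline only modestly
above the chance level (about 1.6× the random-ranking expectation),
mirroring the regime reported for real PPI benchmarks rather than a
regime where scores alone nearly solve the task.

What the generator does **not** emulate: realistic PPI degree
distributions (power laws, assortativity), overlapping complexes,
correlated measurement noise between neighboring genes, or identifier
mapping issues. A green end-to-end test therefore establishes that the
pipeline's machinery behaves as designed and that prior-guided warping
adds information *in a world where the method's premises hold* — it does
not certify performance on any real PPI network.

## Known limitations

* Curvature alone (the `rwr_curvature` variant) is not expected to beat
  plain RWR — topology by itself is only weakly related to any specific
  biological task; its value emerges in combination with priors.
* The smoothed prior makes results more variable across prior samples than
  unwarped baselines; repeated-split benchmarking (`run_benchmark()`) is
  the intended usage, not single-split conclusions.
* $\gamma = 0$ (full smoothing) is only defined on connected,
  non-bipartite networks; the largest-connected-component step is exposed
  (`largest_connected_component()`, `lcc` flag) but optional, since the
  right remedy is data-dependent.
* Identifier namespaces are opaque strings: any gene/protein ID mapping
  must happen upstream.
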