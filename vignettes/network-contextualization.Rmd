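---
title: "Methods: contextualizing signed directed signaling networks"
author: "netcontext"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcontext)
```

# The problem

Prior-knowledge networks (PKNs) of intracellular signaling aggregate
interactions from many sources and contexts. Most of their edges are inactive
in any particular cell line or perturbation. *Contextualization* selects the
subnetwork plausibly active in one experiment, anchored by two measured node
sets:

- **sources** — perturbed nodes (e.g. direct drug targets), signed by the
  direction of perturbation;
- **targets** — downstream readouts (e.g. transcription-factor or kinase
  activities), signed by their observed change.

`netcontext` implements eight contextualization methods in four families on a
shared data model, four benchmarking strategies with permutation nulls, and a
synthetic fixture generator with a planted ground truth, so methods can be
compared under controlled conditions.

# Data model

A `pkn_graph` is a signed directed multigraph: edges are
`(source, target, sign, weight)` with `sign` in $\{-1, +1\}$ and positive
`weight`. Two parallel edges between the same node pair may carry opposite
signs (both a reported activation and a reported inhibition); exact duplicate
`(source, target, sign)` triples are collapsed to one edge, keeping the first
weight. Edges are stored in a canonical sort order so that structurally equal
graphs are byte-identical on disk. I/O covers SIF, an edge-list TSV dialect
and GraphML export (via igraph).

Measurements are `measurement_set`s: named numeric scores plus a role
(`source` or `target`). Methods that reason over signs use
`measurement_signs()`, the arithmetic sign of the scores; zero scores carry
no direction and are dropped with a warning.

# Method families

## Topology: `shortest_path`, `sign_consistent`, `all_paths`

All three return the edge union of source-to-target simple paths.

- `shortest_path` keeps every edge lying on at least one minimum-hop path for
  some (source, target) pair. An edge $(u, v)$ is on a shortest path from $s$
  to $t$ iff $d(s,u) + 1 + d(v,t) = d(s,t)$, so no path enumeration is needed.
- `all_paths` enumerates all simple paths with at most `max_len` edges
  (default 5 — beyond five steps, signaling-path interpretability drops fast
  while path counts explode). A path-count `cap` (default `1e5`) turns
  combinatorial explosions into a clear error rather than an unbounded run.
- `sign_consistent` keeps a path only when
  $\mathrm{sign}(s)\cdot\prod_{e \in \text{path}}\mathrm{sign}(e) =
  \mathrm{sign}(t)$: the chain of activations/inhibitions must reproduce the
  observed target direction. `mode` selects shortest paths (default), all
  paths, or a length bound. Parallel edges are resolved per combination, so a
  node path with both an activating and an inhibiting variant of one step can
  contribute either, but only the consistent combination's edges are kept.

Hops, not weights, define "shortest": PKN edge weights are confidence scores,
not distances, and hop-shortest paths are the standard mechanistic reading.

## Diffusion: `ppr`, `heat_diffusion`

Diffusion is sign-blind; weights enter as nonnegative propensities
$|w|$. Let $P$ be the row-normalized $|w|$ adjacency.

**Personalized PageRank** iterates
$x' = \alpha\,(P^\top x + m\,r) + (1-\alpha)\,r$ where $r$ is the normalized
seed (restart) distribution, $\alpha$ the damping (default 0.85, the
conventional value) and $m$ the probability mass sitting on dangling
(out-degree 0) nodes, which is redirected to the restart distribution so that
scores remain a probability vector. Convergence is declared at L1 change
below `tol` (default `1e-8`); the fixed point does not depend on the starting
vector.

**Heat diffusion** uses the truncated series
$x = \sum_{k=0}^{K} \frac{(-t)^k}{k!} (L^\top)^k s$ with $L = I - P$ the
random-walk Laplacian and $s$ the seed distribution. The *adjoint* is applied
to the seed vector — the mass-transport orientation — so heat flows along
edge direction (matching PPR's "forward" semantics) and total mass is
conserved on dangling-free graphs. Truncation can leave tiny negative
residues; values above $-10^{-9}$ are clamped to zero silently, larger
negatives are clamped with a warning that `K` (default 20) is too low for the
chosen `t` (default 1). The result is renormalized to sum 1.

Both methods extract a *two-sided* subnetwork: forward diffusion seeded by
the absolute source scores, reverse diffusion (on the edge-reversed graph)
seeded by the absolute target scores, combined by geometric mean — a node
scores highly only when it is both reachable from the perturbation *and*
upstream of the readouts. Nodes at or above the `percentile` of the combined
score (default 90, keeping roughly the top decile) and strictly positive are
kept; `percentile = 0` keeps every node touched from both sides.

## Recursive propagation: `recursive_propagation`

Starting from the signed target scores, each unscored node $u$ receives, one
layer at a time, the mean of $\mathrm{sign}(u \to v)\cdot x_v$ over its
already-scored successors $v$ with $x_v \neq 0$; `n_layers` (default 5)
bounds the upstream sweep. A node whose evidence cancels exactly to zero is
scored but propagates no further, and its incident edges are pruned: an edge
$(u, v)$ survives only when both endpoint scores are nonzero and
$\mathrm{sign}(x_u) = \mathrm{sign}(u \to v)\cdot\mathrm{sign}(x_v)$.

## Causal propagation: `causal_selection`, `two_phase_composite`

`causal_selection` searches for an edge subset $E'$ and signed node states
maximizing

$$\#\{\text{explained targets}\} - \lambda\,|E'|$$

subject to causal invariants: source states are fixed by the measurements;
every non-source node touched by $E'$ takes exactly the state forced by some
active incoming edge; every active edge emanates from a node reachable from a
source; all active edges are sign-consistent with the states they connect. A
target is *explained* when its forced state matches its measured sign.
Because states are uniquely forced by propagation from the sources over
$E'$, exhaustive subset enumeration is exact; it is used up to
`max_edges_exhaustive` (default 15, i.e. $2^{15}$ subsets) and a path-greedy
solver (repeatedly add the sign-consistent source-to-target path with the
best marginal objective) beyond that. Ties break deterministically: higher
objective, then fewer edges, then lexicographically smallest edge-index set,
so results are reproducible across platforms. `lambda` defaults to 0.1 —
small enough that explaining one more target always beats saving several
edges, large enough to prune free riders.

`two_phase_composite` first restricts the PKN to the union of sign-consistent
paths up to `max_len`, then runs causal selection inside that restriction,
and annotates nodes with their breadth-first hierarchy layer from the
sources. An empty phase 1 short-circuits with an explanatory note.

# Evaluation strategies

- `offtarget_recovery` / `binary_recovery`: how many labelled nodes (known
  drug off-targets; binarized responsive nodes) the network captures. The
  null draws node sets of the same size uniformly from the PKN — size-matched
  but not degree-matched, a stated simplification. The empirical p-value uses
  the add-one estimator $p = (1 + \#\{x_{\text{null}} \ge x\})/(1 + B)$, so
  it is never exactly zero.
- `ora_enrichment`: one-sided hypergeometric tail of the overlap between the
  network and an expected gene set within a finite background.
- `activity_rank_test`: difference in mean midrank of activity scores inside
  versus outside the network, against a label-permutation null (one-sided,
  "inside higher").

`evaluate_all()` runs a configured strategy set over a named network list and
writes a fixed-format TSV; identical inputs and seeds reproduce the table
byte for byte.

# Synthetic fixtures

`generate_pkn()` plants node-disjoint sign-consistent source-to-target paths
(the last edge sign is chosen so the path product matches the endpoint
signs), then adds Erdős–Rényi background edges. One deliberate design choice:
background edges never point *into* planted intermediate or target nodes.
This protects identifiability — the planted path stays the unique
source-to-target route, so recovery has an unambiguous ground truth and
recall can be interpreted cleanly even at appreciable background densities.
The cost is realism: real PKNs have confluent inputs; the fixtures trade that
for a crisp planted truth.

Measurements set source scores to their sign and target scores to sign plus
Gaussian noise (`noise_sd`). `generate_panacea_like()` emulates the shape of
a drug-panel perturbational atlas — by default 32 drugs crossed with 11 cell
lines, each condition with its own noisy target readouts and a per-drug
hidden off-target set — sized for benchmarking loops, not biological realism.

All generators are deterministic given `fixture_spec(seed = ...)`; the
internal RNG use saves and restores `.Random.seed`, so library calls never
disturb the caller's RNG state.

# Worked example

```{r example}
spec <- fixture_spec(n_nodes = 30, edge_prob = 0.05, seed = 42)
gen <- generate_pkn(spec)
ms <- generate_measurements(gen$truth, noise_sd = 0.1, seed = 43)
net <- run_method("sign_consistent", gen$pkn, ms$sources, ms$targets)
net
recs <- offtarget_recovery(net, gen$truth$offtarget_nodes, gen$pkn,
                           n_perm = 1000, seed = 44)
recs[[1]]
```

# Limitations

- The PKN is static and unweighted by context; edge confidence enters only
  diffusion, and only unsigned.
- Permutation nulls are size-matched, not degree-matched; hub-heavy networks
  will look better than a degree-preserving null would grant.
- Exhaustive causal selection is exponential and capped at 15 edges; the
  greedy fallback is a heuristic (it provably never exceeds the exhaustive
  objective, and matches it on planted fixtures, but carries no general
  approximation guarantee).
- Dataset descriptors (`list_datasets()`) are metadata and remote locators
  only; no download or parsing of the external resources is included.
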