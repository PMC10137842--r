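---
title: "Path-reachability spread centrality and influential-set selection: methods"
author: "spreadrank package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-reachability spread centrality and influential-set selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spreadrank)
```

## The problem

In an undirected contact network G = (V, E) with N = |V| nodes, we want a
*set* of nodes that maximises overall spreading influence: seeded as initial
infected nodes they should saturate the network quickly, and immunized
(placed in the recovered state) they should fragment the network so an
epidemic starting anywhere stays confined. Single-node centralities answer
a different question — a top-k list of individually strong nodes often
clusters in one region, and its members' influence ranges overlap.

The package combines (i) a *spread centrality* built from the reachability
of paths between hub nodes and (ii) a *dynamic set selection* that penalises
overlapping picks and stops against an explicit network-dismantling
criterion.

## Spread centrality

**Local vital nodes.** Only nodes with degree strictly above the network
mean 2E/N are scored. In scale-free networks this is a small hub population;
whether a message crosses from one region to another depends on the path
reachability between the regions' hubs. Non-vital nodes get SC = 0 and are
never candidates in the first selection phase.

**Valid spread paths.** For a vital pair (i, j) the valid paths are all
*simple* paths of edge-length at most `l_max` = 6, the usual six-degrees
horizon; longer routes contribute negligibly to spreading and make
enumeration explode. Path length counts *edges*.

**Three indices per pair.**

* PN_ij — the number of valid paths;
* PL_ijm — the length of the m-th path;
* PD_ij — the *path diversity*: the mean over all C(k, 2) unordered path
  pairs of `1 − 2 w / (d1 + d2)`, with d1, d2 the interior-node counts of
  the two paths and w their shared interior count. We read the formula's
  path "lengths" as interior-node counts: then two identical paths score
  exactly 0, interior-disjoint paths score exactly 1, and the index is a
  Jaccard-style non-overlap bounded in [0, 1] (a raw-edge-length reading
  would leave identical paths with a positive score, and values outside
  the unit interval). Results are clamped to [0, 1] defensively.

**Per-node aggregation.** For vital node i with l vital nodes in total,
PD_i and PN_i average the pairwise values over the l − 1 *other* vital
targets (a self term PD_ii is never defined, so the sum is read as j ≠ i),
and PL_i is the *pooled* mean length — total length of all valid paths
leaving i divided by their total count. The pooled reading is the only one
that stays well defined when the per-pair path count k varies by target.

**Fusion.** SC_i = (norm(PD_i) + norm(PN_i) + norm(1/PL_i)) / 3, where
`norm` is min–max normalisation across the vital population. High SC means:
many routes, short routes, mutually disjoint routes.

### Degenerate-case conventions

These cases are not fixed by the definitions above; the package's choices
are:

* k = 1 (a single path): PD_ij = 0 — one route offers no redundancy.
* k = 0 (no valid path): PD_ij = 0, PN_ij = 0, and the pair contributes no
  length terms to the pooled PL.
* A vital node reaching no target at all: PL_i = `l_max` + 1, one worse
  than any observable mean, so norm(1/PL_i) is finite and worst.
* All-equal normalisation input (max = min): every node gets 0.5. This
  preserves symmetry — on a vertex-transitive vital set all SC values are
  equal (0.5) rather than arbitrary — and avoids division by zero.
* Fewer than two vital nodes (regular graphs): SC is undefined; a classed
  error is raised, and `spreadrank_select()` falls back to a degree
  ranking (see below).
* Ties everywhere are broken by degree descending then label ascending, so
  all outputs are deterministic and platform-independent.

### Implementation notes

Path work is done in compiled code. A depth-first search with an on-path
visited set, depth cutoff, and label-sorted neighbour order enumerates
paths in lexicographic order, deterministically. For the pairwise indices
the package never materialises the C(k, 2) pair loop: paths are grouped by
interior length d, per-node interior membership counts c_d(v) are
accumulated during the search, and the pairwise overlap sums are recovered
exactly from products of those counts, in O(total path length) instead of
O(k²). The test suite checks this aggregation against a naive pairwise
recomputation (and against a second, independently implemented path
enumerator) to 1e-12.

## Influential-set selection

**Attenuation.** After a node is picked, its working SC becomes 0; nodes at
graph distance exactly 1 retain 1/2 of their working value, and distance-2
nodes retain 3/4. Picks close to a previous pick are thereby demoted, which
disperses the set. The factors *compound* multiplicatively across picks: a
node adjacent to two picks retains 1/4. The compounding choice (rather than
re-anchoring to the original SC on every hit) was made because it
suppresses clustered picks monotonically; a node repeatedly adjacent to
picks can only fall.

**Addition stage.** Pick the maximal-working-SC candidate, attenuate,
remove the accumulated set S from the graph, and compute the dismantling
statistic q = |GCC(G[V∖S])| / N — the denominator is the *original* N
throughout. Stop the first time q < μ. The default μ = 0.01 is the
conventional threshold for "destroyed" networks in the dismantling
literature. If the vital candidates run out while q ≥ μ (possible on
topologies without a hub population, which the method does not target),
the candidate pool is extended by the remaining nodes in degree order and
the loop continues, so termination is guaranteed (q = 0 once all nodes are
removed).

**Deletion stage.** Greedy pruning of redundancy: among the current S find
the node whose restoration to the network yields the smallest q (ties by
lowest SC, then label); if that q is still below μ, the node is deleted
from S. The loop stops when restoring even the best candidate breaks the
threshold, so the final set satisfies q < μ *and* every single further
restoration would violate it.

**Guarantees and a caveat.** The final set is always a subset of the
preselection, and the addition stage's pick sequence does not depend on μ —
so for μ1 < μ2 the μ1-preselection extends the μ2-preselection (nested,
monotone in size; property-tested). The *final* sizes are however not
guaranteed monotone in μ: the greedy deletion can prune a longer
preselection harder than a shorter one, and the test suite records this as
the expected behaviour of the two-stage design rather than a defect.

**Degree fallback.** On networks with fewer than two vital nodes (regular
and near-regular graphs) the selection uses node degree as the working
score with the same attenuation and stopping rules. This keeps the tool
total on all inputs while preserving the dismantling post-condition; it is
a fallback, not the method's intended operating regime.

## SIR engine

Discrete-time, synchronous: in each step every susceptible node with m
currently infected neighbours becomes infected with probability
1 − (1 − β)^m (independent per-contact Bernoulli trials with per-contact
probability β), and *simultaneously* every node infected at the start of
the step recovers with probability γ. A node infected in a step cannot
recover in the same step. This is the common discrete convention and makes
the deterministic limits exactly analysable: β = 0 gives a final recovered
fraction Pr = |seeds|/N, and β = γ = 1 floods exactly the seeded
components in breadth-first layers. Both are asserted exactly in the
tests, as is S + I + R = N at every step.

Runs stop at extinction (I = 0) or at a safety cap of 10·N steps (flagged,
never silently truncated). Ensembles derive per-run child seeds from one
master seed, so every table in the package is bit-reproducible; trajectories
are padded to the longest run by carrying the final state, keeping per-step
means averages over all runs.

*Experiment roles.* Spreading: the candidate set is the initial infected
set. Immunization: the candidate set starts recovered, and each realization
infects a fresh uniform sample of ceiling(f·(N − |immune|)) non-immune
nodes; f defaults to 0.05 (the initial infected share is a free protocol
parameter; 5% is a conventional choice that leaves room for both
suppression and spread). The immunization tables report the fraction
recovered *through infection*, (R_final − |immune|)/N; counting the immune
nodes themselves would add a constant |immune|/N and reverse the
interpretation of nested-immunity comparisons.

## Baselines

Degree, Brandes betweenness and k-shell peeling are delegated to igraph;
eigenvector centrality is a power iteration on the giant component
(tolerance 1e-10, L2-normalised, nodes outside the GCC score 0, iteration
on A + I so bipartite ±λ degeneracy cannot oscillate); VoteRank follows its
original formulation with per-round ability decrement δ = 1/⟨k⟩ floored at
0. All rankings are full permutations of V with deterministic tie-breaks,
and every method is compared at the same budget: its top-|S| nodes, with S
the selection's final set on the same graph.

## Synthetic networks and what the tests do (and do not) show

The generator is Barabási–Albert preferential attachment with an m-clique
seed (edge count exactly C(m,2) + m(n − m)), because the method's operating
assumption — a small above-average-degree hub population — is a scale-free
property. An Erdős–Rényi generator is included purely as a non-scale-free
contrast. The toy bridge graph (two 6-cliques with pendant leaves joined by
a 2-node bridge) gives hand-checkable vital nodes and cut structure.

Test scales are desk-sized: path-oracle equivalence on 200 random graphs
with n ≤ 12, equation fidelity on 50 BA graphs with n ≤ 30 (tolerance
1e-12), selection post-conditions on 50 BA(200, 2) instances at
μ ∈ {0.01, 0.05, 0.1}, SIR monotonicity at 200-run ensembles on BA(300, 2),
and the directional seeding/immunization comparison on BA(500, 3) at
β = 0.05, γ = 0.01 with 100-run ensembles. Synthetic BA graphs lack the
clustering, degree correlations and community structure of real contact
networks, so passing tests demonstrate algorithmic correctness and
qualitative behaviour, not performance claims on any particular real
network.

One desk-scale effect deserves emphasis: at μ = 0.01 on a 500-node graph
the selected set is a third of all nodes, and at β = 0.05, γ = 0.01 the
per-contact lifetime transmissibility β/(1 − (1−β)(1−γ)) ≈ 0.84 is far
above the percolation threshold — *any* seed set of that size saturates the
giant component, so final-size spreading comparisons against random seed
sets are uninformative at this scale (the corresponding acceptance check
records this honestly). The immunization comparison, by contrast, is
dramatic and robust: dismantling confines the epidemic to sub-μN fragments
(about a tenth of the random-immunization infection scale on the same
graphs, and better than a same-budget degree ranking).

## Complexity and problem sizes

With the l_max cutoff the centrality costs O(total bounded paths) ≈ O(N²)
on sparse scale-free graphs; both selection stages are O(N) rounds of O(N +
E) component computations. On one CPU the full pipeline runs in seconds at
N = 500 (the scale used throughout the examples and checks), which is the
intended desk scale of this implementation.

## Known limitations

* Undirected, unweighted, simple graphs only; self-loops and multi-edges
  are collapsed on input.
* The centrality is undefined on networks without at least two
  above-average-degree nodes; the degree fallback changes the method's
  character on such inputs.
* Bounded path enumeration is exact, not sampled; extremely dense
  neighbourhoods (far from the scale-free regime) can make l_max = 6
  expensive.
* The six-degrees bound, μ = 0.01, and the 1/2–3/4 attenuation pair are
  protocol constants taken as given, not fitted quantities.
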