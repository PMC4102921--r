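---
title: "Topology-based community detection: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based community detection: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topocomm)
```

# The model

`topocomm` detects communities in undirected, unweighted networks using
nothing but the topology: no resolution parameter, no random restarts, no
pre-set community count. It rests on three definitional ingredients.

**Community structure.** For a node set $S$ write $int(S)$ for the number
of edges with both endpoints in $S$ and $ext(S)$ for edges with exactly one
endpoint in $S$. $S$ is a *strong-sense* community when $int(S) > ext(S)$.
It is a *weak-sense* community when $int(S) \le ext(S)$ overall, yet
$int(S)$ exceeds the number of edges between $S$ and every *single* other
community. The two predicates are mutually exclusive by construction;
`is_strong_sense()` and `is_weak_sense()` expose them directly.

**Community membership.** Every node should sit in the community that
contains the maximum number of its neighbours, unless it is an overlapping
node. This is the fixed-point condition the iterative stage enforces.

**Hub members and overlapping nodes.** The *hubs* of a community are its
members with the most neighbours inside it (ties keep all maximizers). Two
overlap types are distinguished. A *type-1* node ties for its maximum
neighbour count across two or more communities *and* lies at the same
shortest-path distance from the hub members of each tied community. A
*type-2* node is a bridge: tightly attached to two communities that would
share few direct edges without it. In the karate-club network, nodes 3 and
10 tie in neighbour counts between the two factions but sit at different
distances from the two hubs (nodes 1 and 34), so neither is overlapping —
the distance condition is what keeps the classification conservative.

The text definition of type 2 does not quantify "tightly" or "few". The
package operationalizes it parameter-free: a node qualifies when it has at
least 2 edges into each of two communities and the residual edge count
between the two communities (node removed) is strictly below the node's
smaller attachment count. This is satisfied by the canonical case of two
cliques sharing one node (residual count 0) and fails as soon as the two
communities are directly well connected.

# The detection algorithm

Detection runs independently on every connected component, in four stages.

**1. Candidates.** Each non-isolated node anchors one candidate seed: its
closed neighbourhood (the node plus its adjacency list), with cached
internal/external edge counts (`seed_candidates()`).

**2. Strong-seed extraction by peeling** (`extract_strong_seeds()`). Rounds
operate on the *residual* graph (nodes not yet claimed). In each round:

* Candidates are recomputed on the residual graph.
* *Minimality filter*: a strong candidate that strictly contains another
  strong candidate is set aside. Without this, the closed neighbourhood of
  a node bridging two dense groups — which is the whole union and trivially
  strong — would always be claimed first, and detection could never
  separate structures such as two cliques sharing one node.
* *Ranking.* In the first round of a component the strong candidates are
  ranked by internal−external excess (descending, then internal edges, then
  anchor id): the highest-excess neighbourhoods belong to the component's
  global hubs, which are the most reliable seeds. In later rounds the
  residual frame no longer charges a candidate for edges toward already
  claimed communities, which inflates the excess of large left-over mixtures;
  there the ranking switches to neighbourhood density
  $int(S)/\binom{|S|}{2}$, which favours sets drawn from a single community
  over bridge-anchored mixtures of two.
* *Expansion.* Sparse communities (mean internal degree well below the
  community size) have no strong closed neighbourhood at all. A candidate
  that is not strong is grown greedily — repeatedly absorbing the unclaimed
  node with the most neighbours inside it — until it becomes strong. This
  is the merged-adjacency-list search: the seed is still found from
  adjacency lists, just more than one of them.
* *Trim.* The accepted set is then trimmed by the membership property:
  members (never the anchor) with strictly more neighbours outside the set
  than inside are removed, synchronously per round so the result is
  order-free. Trimming keeps a hub's seed from freezing in nodes that
  clearly belong elsewhere. If the trimmed core is not itself strong, the
  candidate is expanded one node further and re-trimmed until it
  stabilizes; candidates whose core collapses below two nodes are rejected
  (this is what dismisses small left-over fragments between claimed
  communities).
* The accepted seed is removed from the residual graph and the round
  repeats. If a component never yields a seed, its single best candidate is
  taken as a declared fallback seed.

**3. Weak-community growth** (`grow_weak_communities()`). Unclaimed nodes
join the seed community holding the maximum number of their neighbours.
Nodes with no edge into any claimed community are deferred and re-swept
after their neighbours have been placed, so growth always spans the
component. Grown communities are labeled strong or weak by the predicates
above.

**4. Iterative reassignment** (`reassign_to_convergence()`). Asynchronous
sweeps in canonical node order move each node to its maximum-membership
community until a full pass makes no move (or a cap of 100 passes, flagged
in the returned trace; in practice convergence takes a handful of passes).
Emptied communities are deleted. Asynchronous updating was chosen over
synchronous because it guarantees progress and cannot oscillate between
symmetric configurations.

**Tie rules.** All ties share one deterministic rule: a node tied between
communities goes to the community whose hub members are nearest by
shortest-path distance (minimum over the hub set — the only order-free
choice when hubs tie); remaining ties go to the smallest community id. With
multiple hubs the minimum distance is used. These are the same quantities
the type-1 overlap definition uses, so the tie-break and the overlap
classifier agree about what "closest community" means.

**Overlap classification** runs once, on the converged cover (overlaps are
properties of stable communities, not of intermediate sweeps). Type 1 is
tested before type 2 and a node carries at most one record; overlap nodes
are then added to the member lists of every community they bridge, while
their primary assignment (the tie-broken one) is retained so that
partition-based metrics stay computable.

**Determinism.** Node identifiers are canonicalized to character and
radix-sorted, every stage processes nodes in that order, and every tie has
an explicit rule, so the output is invariant under permutation of the input
edge list — a property the test suite asserts by shuffling.

# Evaluation metrics

**NMI.** Entropies are taken in bits over community-size distributions and
$\mathrm{NMI}(X,Y) = 2I(X,Y)/(H(X)+H(Y))$. Among the several normalizations
in circulation this is the standard community-comparison form, and it is
the single most consequential metric choice (third-decimal comparisons
depend on it); `igraph::compare(method = "nmi")` uses the same form and
serves as an independent cross-check in the tests. When both labelings have
zero entropy the value is 1 if they are identical as partitions, else 0.
Isolated nodes enter NMI as singleton communities.

**Modularity.** $Q = \sum_i (e_{ii} - a_i^2)$ over the community mixing
matrix $e$, whose diagonal holds within-community edge fractions and whose
off-diagonal entries split each between-community edge symmetrically, so
$\sum e = 1$ and $a_i$ is the fraction of edge ends in community $i$.
Isolated nodes carry no edges and are excluded from $Q$. Overlapping nodes
enter both metrics under their primary community, since partition-valued
baselines admit nothing else. The tests check $Q$ against a per-edge
brute-force sum and against `igraph::modularity()`.

# Synthetic benchmarks

**Planted partitions** (`generate_planted_partition()`): $l$ groups of
equal size with independent Bernoulli edges at `p_in` within and `p_out`
between groups. This family drives the recovery property (4 groups of 32,
`p_in = 0.5`, `p_out = 0.02`, perfect NMI in at least 95% of seeds) and
provides null models for the metric tests.

**LFR-style graphs** (`generate_lfr()`): truncated power-law degrees
(exponent `tau1 = 2`) with the minimum degree solved so the mean matches
`avg_k`; power-law community sizes (`tau2 = 1`) in `[min_c, max_c]`; a
mixing parameter `mu` giving the fraction of each node's stubs routed
outside its community; and `on` overlapping nodes holding `om` memberships
with internal stubs split evenly. The default parameterization — 128
nodes, average degree 9.328, maximum degree 30, `mu = 0.1`, sizes 10–30,
10 overlapping nodes with 2 memberships — is the benchmark configuration
whose recovery the acceptance suite measures; the exponents are the
canonical defaults of the benchmark family.

Generator mechanics worth knowing:

* Degrees are rounded per node and the total corrected to
  `round(n * avg_k)` by single-unit adjustments swept across the
  highest-degree nodes (never dragging one node to the cap), so the
  expected edge count is met exactly up to wiring losses.
* The community count is derived from the parameterization (total
  memberships over the expected community size under the truncated power
  law) — 8 for the default parameters — and sizes are then sampled from the
  power law and nudged by random unit steps to sum exactly to
  `n + on*(om-1)`. Deriving the count rather than letting renewal sampling
  decide keeps the planted composition at the stated one instead of
  wandering between 7 and 9; sizes, memberships and wiring stay fully
  random.
* Nodes are seated hardest-first under capacity and feasibility
  constraints (a node's per-community internal degree must fit the
  community), with bounded restarts and a repair step that grows one
  community enough to host the largest internal degree.
* Community interiors are wired by Havel–Hakimi realization of the
  internal degree sequence followed by double-edge-swap randomization;
  unrealizable internal stubs are rerouted through the external pool
  (except at `mu = 0`, where every edge must stay internal), and external
  stubs are matched randomly with rewiring that forbids self-loops,
  parallel edges and intra-community pairs. Realized mixing therefore runs
  slightly above nominal `mu` (about 0.126 at `mu = 0.1`, n = 512), from
  degree rounding and rerouting; the tests bound this at ±0.03.
* All randomness flows from the single `seed` argument; the caller's RNG
  state is saved and restored, and identical seed and parameters give
  bit-identical instances.

What the generators do *not* emulate: degree–community correlations,
weighted or directed mixing, hierarchical structure, and the heavy-tailed
degree exponents of some real networks. Passing the synthetic recovery
tests therefore says the algorithm recovers planted structure under the
stated conditions, not that it resolves every real network's communities.

# Problem sizes and tolerances

The test battery uses 25 LFR instances for the recovery checks, 50 for the
generator calibration, 50 planted-partition instances for the perfect-
recovery rate, 20 instances at n = 512 for the mixing bound, and 200 small
planted partitions for the binomial edge-count expectation — sizes chosen
so the whole suite runs in about a minute while keeping Monte-Carlo
standard errors well inside the asserted bands. Exact identities
(modularity against the per-edge oracle, mixing-matrix normalization) are
asserted at `1e-12`.

# Known limitations

* Directly connected community pairs anchored at adjacent hubs can merge
  into one community; the algorithm has no post-hoc splitting step
  (hierarchical decomposition is out of scope).
* Pure cycles carry no community signal; seeds decompose them into arcs (a
  4-node arc of a 6-cycle is genuinely strong-sense), which is as arbitrary
  as any other stable answer.
* The implementation is pure R and comfortably handles the hundreds-to-
  thousands-of-nodes range of the bundled studies; very large graphs would
  want the inner loops compiled.
* Weighted, bipartite and multigraph semantics are out of scope; directed
  input is symmetrized on construction.
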