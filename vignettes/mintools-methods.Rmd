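---
title: "Methods: vertex-centric analysis of molecular interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertex-centric analysis of molecular interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mintools)
```

## The graph model and its cleaning rules

A molecular interaction network is an undirected simple graph whose edges
may carry one confidence label in [0, 1]. Interaction databases do not hand
you a simple graph: MITAB exports repeat an interactor pair once per
evidence line, occasionally record self-interactions, and mix identifier
namespaces. `build_graph()` therefore applies three deterministic rules:

* **Parallel edges collapse to the maximum weight.** Each evidence line is
  one measurement of the same underlying interaction; keeping the strongest
  score makes every threshold query monotone in the input (adding evidence
  can only add neighbors, never remove them).
* **Self-loops are dropped** (with a warning giving the count). The density
  and closeness definitions assume a simple graph; a loop would push density
  out of [0, 1].
* **A graph is homogeneously labelled or unlabelled.** Mixing would make
  "the product of labels along a path" undefined for some paths, so it is
  rejected outright; in MITAB input, score-less rows inside a scored file
  are dropped and counted instead, since those rows are almost always
  evidence lines whose score the exporter could not compute.

Identifiers are kept as full `"db:accession"` strings; no accession
normalization or cross-database mapping is attempted — mapping policy is a
scientific decision that belongs to the user, not to a parser.

Every ordering the package produces (canonical endpoint order, exported
rows, degree tie-breaks, component ids) uses C-locale byte order, so results
are byte-identical across machines and `LC_COLLATE` settings.

## The superstep engine

All traversals are expressed against a bulk-synchronous vertex-centric
contract: a program is a triple of pure functions — `vprog` (fold the merged
message into the vertex state), `send_msg` (emit messages along edge
triplets), `merge_msg` (a commutative, associative combiner) — plus an
iteration cap and a message direction. Messages produced in superstep *t*
are visible only in superstep *t + 1*.

Design choices where the contract left room:

* **Superstep 0 evaluates `send_msg` on every triplet**, after running
  `vprog` everywhere with the initial message. The bundled programs use a
  neutral initial message that leaves states unchanged, so conditioning the
  first send round on state change would halt immediately; seeding the first
  round from all triplets is the standard resolution and is what the GraphX
  Pregel loop does.
* **Afterwards, activity is message-driven**: `vprog` runs only at vertices
  that received a message, and `send_msg` only on triplets incident to a
  vertex whose state changed. For monotone programs (everything bundled
  here) this is an invisible optimization: a vertex whose state did not
  change would re-emit messages that every receiver merges idempotently.
* **Change detection is exact** (`identical()`), not tolerance-based. All
  bundled programs update states by min/max over products or sums of input
  values, which are bit-reproducible, so exact comparison is both safe and
  the only choice that cannot mask a real update.
* **The parallel executor** groups triplets by edge partition, evaluates
  partitions on forked workers, and combines the per-partition message maps
  in fixed partition order. Correctness rests on the `merge_msg` algebra,
  not on scheduling, which is why serial and parallel runs are asserted
  byte-identical in the tests rather than merely "close". The algebra itself
  is spot-checked at program registration on sampled messages when samples
  are provided.

The three bundled programs are monotone bounded propagations: minimum label
(components), hop distance with cutoff (BFS/closeness), and maximum label
product above a threshold (weighted neighborhoods). Since each message
strictly improves a bounded state drawn from a finite set of values, all
three halt without an iteration cap.

## Neighborhood semantics

The weighted neighborhood keeps `v` when the best path product from the
query strictly exceeds `x`. Strict `>` is deliberate: the membership
condition composes through path concatenation (a product `> y ≥ x` remains
`> x`), whereas `≥` would not interact cleanly with thresholds supplied at
query time. The unweighted variant is read as "within `x` hops": an
equals-`x`-length reading would make neighborhoods grow with path length and
contradict how neighborhood extraction is used in practice. Query vertices
are excluded from their own neighborhood, and all subgraphs are
vertex-induced (every edge of the parent graph among the included vertices),
which is richer than a traversal tree and independent of traversal order.

A numerical note: the max-product propagation emits a message only when the
product exceeds both the threshold and the target's current best, so the
final state at a member is the true maximum, not merely some witness above
the threshold. Products of labels ≤ 1 never increase along a walk, so cycles
cannot inflate values and the simple-path and walk maxima coincide — this is
what makes a 50,000-vertex query terminate in a handful of supersteps.

## Components, closest components, dispersion

Component ids are the lexicographically smallest member id — the standard
label-propagation convention, and the tie-break for `closest_component` when
two components overlap a query set equally. The closest-component query is
defined for an arbitrary partition of the vertex set; the public API fixes
the partition to connected components, while the general form
(`closest_block`) remains an internal, tested helper.

Kleinberg dispersion `K(u, v)` counts unordered common-neighbor pairs
separated in the subgraph induced by `u`'s neighbors minus `{u, v}`. Two
conventions were genuinely open:

* **Unordered pairs** are the default. The separating indicator is
  symmetric, so an ordered sum is exactly twice the unordered one and
  carries no extra information; `counting = "ordered"` exposes the doubled
  convention for comparison with sources that use it.
* **The induced graph uses `u`'s neighborhood** (not `v`'s), which is why
  dispersion is not symmetric; the test suite includes an explicit
  asymmetric witness rather than leaving the asymmetry implied.

## The synthetic generator and what a green test establishes

`generate_min()` grows a connected preferential-attachment graph (initial
clique of `attach + 1` vertices; each newcomer links to `attach` distinct
degree-proportional targets) with i.i.d. edge labels — uniform by default,
Beta or constant on request. Defaults (`attach = 2`, uniform labels) give
the hub-dominated degree structure of real protein interaction networks: a
median degree of 2 with hubs tens of times larger, which the tests assert as
max/median ≥ 5 at 2,000 vertices. Uniform labels are a deliberately
assumption-free stand-in for database confidence scores, whose empirical
distribution varies by database and scoring pipeline.

What the generator does *not* emulate: degree correlations, clustering
coefficients of specific interactomes, evidence-dependent label structure,
or any particular database snapshot. A green test therefore establishes
algorithmic correctness (implementations agree with independent brute-force
oracles — exhaustive simple-path enumeration, queue BFS, union-find, pair
loops — on hundreds of seeded graphs) and engine invariances (determinism,
executor and partition transparency), not biological claims about any real
network.

## Degenerate inputs and numeric conventions

* Density requires at least two vertices; below that it is an explicit
  undefined-statistic error rather than `NaN`.
* Closeness on a disconnected graph uses the harmonic convention
  (unreachable vertices contribute 0), keeping the statistic finite without
  restricting to the query's component.
* Zero-edge and single-vertex graphs flow through every operation
  (components of an edgeless graph are singletons; dispersion with fewer
  than two common neighbors is 0).
* All printed numbers use 6 significant digits; exported edge lists
  round-trip to equality at that precision.
* Seeds: the generator uses an explicit RNG kind
  (Mersenne-Twister/Inversion/Rejection) and restores the caller's RNG
  state, so `generate_min()` is a pure function of its arguments.

## Known limitations

* The engine is single-host; partitioned parallelism uses forked processes
  (`parallel::mclapply`), so multicore speedups require a POSIX system and
  more than one available CPU — on a single CPU the fork barrier makes the
  parallel executor slower than the serial one, which is why the scaling
  smoke test reports wall times without asserting a speedup.
* Messages and per-triplet functions are ordinary R closures; the engine's
  constant factors suit networks up to a few hundred thousand edges, not
  database-scale graphs — the point of the contract is that programs
  written against it would port unchanged to a distributed Pregel runtime.
* Directed graphs, multigraphs and per-edge metadata beyond one confidence
  label are out of scope, as are Neo4j connectivity and functional
  enrichment of neighborhood results.
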