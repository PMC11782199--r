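---
title: "Degree-based irregularity indices of polyhedral networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based irregularity indices of polyhedral networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irregnet)
```

## The model

A topological index is a numeric invariant of a molecular graph, used as a
descriptor in quantitative structure–property work. An *irregularity index*
is a topological index that vanishes exactly on regular graphs (all vertices
of equal degree) and is positive otherwise, so it quantifies how far a
structure deviates from regularity. For large crystallographic and
metal–organic framework networks such descriptors stand in for properties
that are impractical to measure directly.

Every index in this package has the same shape:

$$ I(G) \;=\; c \sum_{uv \in E(G)} h(d_u, d_v), $$

where $d_u$ is the degree of vertex $u$, $h$ is a symmetric kernel with
$h(d, d) = 0$, and $c$ is a constant prefactor. The twelve kernels are:

| id | $c$ | $h(d_u, d_v)$ |
|------|-----|----------------------------------------------|
| IRDIF | 1 | $\lvert d_u/d_v - d_v/d_u\rvert$ |
| AL    | 1 | $\lvert d_u - d_v\rvert$ (Albertson) |
| IRL   | 1 | $\lvert \ln d_u - \ln d_v\rvert$ |
| IRLU  | 1 | $\lvert d_u - d_v\rvert / \min(d_u, d_v)$ |
| IRLF  | 1 | $\lvert d_u - d_v\rvert / \sqrt{d_u d_v}$ |
| IRF   | 1 | $(d_u - d_v)^2$ |
| IRLA  | 2 | $\lvert d_u - d_v\rvert / (d_u + d_v)$ |
| IRD1  | 1 | $\ln(1 + \lvert d_u - d_v\rvert)$ |
| IRA   | 1 | $(d_u^{-1/2} - d_v^{-1/2})^2$ |
| IRGA  | 2 | $\ln\!\big((d_u + d_v) / (2\sqrt{d_u d_v})\big)$ |
| IRB   | 1 | $(\sqrt{d_u} - \sqrt{d_v})^2$ |
| IRRt  | 1/2 | $\lvert d_u - d_v\rvert$ |

All logarithms are natural: the published numeric tables for these families
are only consistent with $\ln$ (e.g. the octahedral IRL coefficient
$36\ln 2 = 24.953299$). Two conventions deserve note. IRRt is defined here
as a *per-edge* half-sum; the wider literature's "total irregularity" sums
over all vertex pairs, but the published values for these networks force
the per-edge reading (and then $\mathrm{AL} = 2\,\mathrm{IRRt}$
identically, which the test suite asserts on every input). IRGA carries the
prefactor 2 of its printed definition; see *Known inconsistencies* below.

## The edge-partition technique

Because every index is a sum of a function of the endpoint degrees, it only
depends on the graph through its *edge partition*: the multiset of
unordered degree pairs $(d_1 \le d_2)$ with edge counts. `edge_partition()`
extracts this from a concrete graph; `irr_index_partition()` evaluates any
index from it; and `irr_index()` (direct edge iteration) agrees with the
partition route to machine precision, a property-tested invariant.

For a *parametric family* whose class counts are quadratics
$a_2 n^2 + a_1 n + a_0$ in a size parameter $n$, linearity gives each index
as a quadratic closed form with coefficients
$c \sum_{\text{classes}} h(d_1, d_2)\,(a_2, a_1, a_0)$ — `closed_form()`.
This is exact, not a fit; the suite checks it against direct partition
evaluation at $n = 1..5$ for all twelve indices and both families.

## The network families

Four related structures are covered:

* **Platonic solids** (`platonic_graph()`): the octahedron (6 vertices, 12
  edges, 4-regular, $K_{2,2,2}$) and icosahedron (12 vertices, 30 edges,
  5-regular). Regular, hence all indices are zero — the null case.
* **Corner-sharing chains** (`chain_graph()`): $n$ copies arranged
  linearly, consecutive copies sharing one corner. CHO$_n$ has $5n+1$
  vertices and $12n$ edges; CHI$_n$ has $11n+1$ and $30n$. Each shared
  corner belongs to two copies and reaches twice the base degree (8, resp.
  10).
* **Sheet networks** OT$_n$ and IS$_n$: two-dimensional arrangements of
  rings of corner-sharing octahedra (resp. icosahedra) of circumscribing
  order $n$, with $27n^2+3n$ / $63n^2+3n$ vertices and $72n^2$ / $180n^2$
  edges, represented by their published edge-partition families
  (`partition_family()`):

```{r}
partition_family("OT")
partition_family("IS")
```

### Design choice: partitions, not sheet graphs

The sheet networks are *not* constructed as explicit graphs. Their
published description (rings of corner-sharing polyhedra, linked in a
plane) fixes the vertex/edge counts and the degree-pair partition but
underdetermines the full adjacency; any explicit construction would add
assumptions the results do not need, since every index is a function of
the partition alone. All OT/IS results therefore flow through
`family_partition()` / `closed_form()`. The per-degree vertex censuses
(`degree_census_family()`) are solved from the partitions via incidence
consistency ($d \cdot \#\{v : d_v = d\}$ equals the number of edge
endpoints of degree $d$) and are checked against the handshake lemma and
the vertex-count quadratics at $n = 1..5$.

### Design choice: chain gluing

Within each solid copy the chain designates an *entry* and an *exit*
corner forming an antipodal (non-adjacent) pair — the $(1,2)$ pair of
$K_{2,2,2}$, the two apices of the icosahedron built as a gyroelongated
pentagonal bipyramid. Non-adjacency guarantees no edge joins two shared
(doubled-degree) corners, which is what the derived partitions require;
any non-adjacent corner pair yields the same degree census, so the choice
is canonical but not restrictive.

## Numerical choices

* **Double precision throughout.** Degrees are at most 10 and class counts
  at most a few times $10^5$ at the tabulated orders, so every
  integer-valued kernel sum (AL, IRF, IRRt, IRDIF, IRLU, IRLA on these
  degree sets) is exactly representable in doubles — exact rational
  arithmetic would change no reported digit. Irrational-valued indices are
  correct to close to machine precision and are rendered at 6 decimals in
  CSV output.
* **Tolerances.** Graph-vs-partition agreement is asserted at $10^{-12}$
  relative; closed-form-vs-direct at $10^{-9}$; comparisons against
  published 6-decimal values at $10^{-4}$ relative (the published tables
  themselves carry printing artifacts of order $10^{-7}$ relative).
* **Ties.** `compare_families()` reports a zero difference as a tie, never
  as dominance; the overall verdict is "mixed" unless one family leads (or
  ties) at every $n$.
* **Degenerate inputs.** Isolated vertices are accepted in graphs (they
  are invisible to every index); kernels reject degree-0 *endpoints* with
  a domain error naming the index. Empty graphs yield empty censuses and
  partitions, and an empty $n$ range yields an empty table.

## Known inconsistencies in the published tables

`discrepancy_report()` compares the definition-faithful computation against
the published reference values (shipped as CSV in `extdata/`) and
classifies every mismatch:

```{r}
discrepancy_report()[, c("family", "index", "n", "printed", "computed",
                         "classification")]
```

* The published IS IRGA table row is exactly *half* the prefactor-2
  definition used everywhere else (a convention slip), and the published
  IS IRGA quadratic coefficients match neither reading (a typo); the
  package reports the definition-faithful values and flags both.
* IS IRLA is exactly $36n^2 - 4n$ (integer at every $n$); the published
  cells carry decimal dust from evaluating $5/15$ at 6 decimals.
* The published IS IRB cell at $n = 4$ (720.736120) is an isolated typo;
  the value implied by its own row's quadratic is 720.606076.
* The octahedral table is reproduced in full with no discrepancy.

These are surfaced, never silently patched: reproduced tables always
contain the computed values.

## The comparison

On IRDIF the icosahedral family exceeds the octahedral one by
$27n^2 - 9n > 0$ at every order — the icosahedral network is the more
irregular, consistent with its wider degree spread at comparable size:

```{r}
comparison_series(report_config(n = 1:5))
```

## What the fixtures do and do not show

The test fixtures (`fixture_graphs()`) are paths, cycles, stars, complete
graphs, the two platonic solids, chains up to length 4, and seeded sparse
random graphs on 10 vertices. They exercise the regularity null, the
handshake/incidence invariants, the graph/partition equivalence and the
index identities on graphs with degree ranges similar to the target
networks (1–10). They are small by construction — problem sizes were chosen
so the whole suite evaluates in seconds — and they do not probe numerical
behaviour at extreme degrees, dense graphs, or families whose class counts
grow faster than quadratically; nothing here validates the *chemical*
interpretation of any index.

## Limitations

* Directed graphs, multigraphs and weighted edges are out of scope.
* No 3-D coordinates or rendering; the solids are pure skeletons.
* The sheet networks exist only as partition families; per-vertex or
  distance-based quantities on OT$_n$/IS$_n$ are not computable here.
* Closed forms are quadratics because the families' class counts are;
  the machinery does not target higher-degree families.
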