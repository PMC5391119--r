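---
title: "Converting degenerate half-space descriptions into skeleton graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting degenerate half-space descriptions into skeleton graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyskel)
```

## The problem

A constraint-based model -- a no-signaling correlation scenario in quantum
information, a stoichiometric network in systems biology -- typically arrives
as a system of linear inequalities $Ax \le b$: $m$ half-spaces
$H_i = \{x : a_i \cdot x \le b_i\}$ whose intersection is the feasible
polytope $P$ in dimension $n$.  What carries the scientific meaning is not
the inequality list but the *skeleton graph* $G(P) = (V, E)$: the extreme
points of $P$ (the elementary modes, the extremal correlations) and the
1-faces joining them.  `polyskel` computes $G(P)$ from $(A, b)$.

The hard case is **degeneracy**.  A vertex $p$ is determined by its active
set $Z(p) = \{i : a_i \cdot p = b_i\}$, which must span all of $\mathbb R^n$;
when $|Z(p)| = n + \sigma$ with $\sigma \ge 1$, more constraints meet at $p$
than the dimension requires.  A simplex-style neighbour search then faces

$$\mu = n\,(m - n - \sigma)\binom{n + \sigma}{n}$$

pivot alternatives at that single vertex (`multiplicity()`), which explodes
combinatorially -- for the bundled no-signaling example ($n = 14$, $m = 24$,
$\sigma = 6$ at the origin) $\mu$ is 2,170,560, far more than the 108
vertices of the whole graph.

## The method

The converter combines two classical ingredients.

**Incremental double-description slicing** resolves degeneracy locally.  The
cone at $p$, translated to the origin, is
$D_{Z(p)} = \{x : a_i \cdot x \le 0,\ i \in Z(p)\}$.  A basis
$B \subset Z(p)$ of $n$ independent rows spans a regular cone whose extreme
rays are obtained in closed form: they are the (negated) biorthogonal
companion of the basis rows, $a_i \cdot \rho_j = -\delta_{ij}$
(`biorthogonal_rays()`; we store rays as primitive integer vectors, so the
identity holds up to a positive scale).  The remaining $\sigma$ half-spaces
are inserted one at a time (`insert_halfspace()`): rays strictly inside the
cut survive, rays on the hyperplane survive, rays outside die -- but each
*colaminar* pair (a dying ray and a surviving ray spanning a 2-face of the
current cone) contributes a newborn ray
$\varphi_k(\rho', \rho) = (a_k \cdot \rho')\rho - (a_k \cdot \rho)\rho'$ on
the cutting hyperplane.  Colaminarity can be decided two ways, and both are
implemented: *algebraically* (the pair's joint active rows have rank
$n - 2$) or *combinatorially* (no third ray's active set contains the pair's
joint active set).  The two tests are logically equivalent; the test suite
asserts their agreement on every queried pair.

Two accelerations cut the number of tests run: a **rejection pre-test** (a
colaminar pair must share at least $n - 2$ active constraints, so smaller
joint sets are discarded immediately) and a **2-face record** seeded with
all ray pairs of the base cone -- in a regular cone every pair is colaminar
-- and maintained across insertions: a recorded pair skips the test, and
when its dying member is replaced by the newborn ray the record entry is
rewritten accordingly.  Record entries that reference dropped rays are
purged lazily (a dropped ray's key cannot recur inside the same cone, since
later rays all satisfy the constraint that killed it).  The recorded and the
plain slicer produce identical ray sets at every step; the suite replays
both on the worked example to check it.

**Min-ratio pivoting** turns rays into neighbours.  For a compact $P$ every
extreme ray $\rho$ of the vertex cone eventually hits a non-active
constraint; the first one,
$\lambda = \min_t (b_t - a_t \cdot p)/(a_t \cdot \rho)$ over
$\{t \notin Z(p): a_t \cdot \rho > 0\}$, yields the neighbouring vertex
$q = p + \lambda\rho$ (`neighbors()`).  Ties among the minimizing $t$ simply
mean $q$ is itself degenerate; only the value of $\lambda$ matters.  Rays
map to neighbours injectively (each is a 1-face); the kernel asserts this.

A **breadth-first traversal** (`skeleton_graph()`) assembles the graph: pop
a vertex from a FIFO queue, slice its cone, pivot along each ray, enqueue
unseen neighbours, record edges as unordered pairs.  Membership checks are
against scanned-or-queued vertices, so nothing is enqueued twice; edges
found from both endpoints collapse to one.

## Exact arithmetic

All geometry runs on GMP rationals.  This is a deliberate, load-bearing
choice: the method's branch points are *sign decisions* (slack zero or not,
dot product zero or not, rank full or not), and degeneracy means sitting
exactly on the boundary where floating point is least trustworthy.  A
tolerance-based mode would have to re-derive every guarantee the tests
assert (order invariance, record soundness, oracle equivalence) modulo an
epsilon, and misclassifying a single near-zero slack silently changes the
graph.  The package therefore has no floating mode; numeric input is
accepted but converted through its exact binary value, and decimal strings
are parsed as exact decimal fractions.  Rationals cross the R boundary as
`"p/q"` strings; rays are normalized to primitive integer vectors
(denominators cleared, gcd 1, orientation kept) and vertices are
deduplicated by their canonical coordinate string.

## Choices the design left open

* **Basis choice** (`choose_basis()`): the first $n$ active indices, in
  ascending order, that greedily increase the rank.  Deterministic, and on
  the bundled example it reproduces the basis $\{0,\dots,13\}$ with
  insertion order $(14,\dots,19)$ used throughout the published worked
  example.  The output graph provably does not depend on this choice; the
  suite re-runs conversions with randomized bases and orders (seeded) and
  checks that $(V, E)$ is unchanged.  Only the *work done* depends on it --
  the counters in `compute_metrics()` expose that.
* **Test selection** `"auto"`: the first vertex is sliced with both
  colaminarity tests, timed, and the faster one is kept for the remaining
  vertices.  Which test wins is input-dependent (the algebraic one tends to
  win on sparsely connected outputs, the combinatorial one on densely
  connected ones), so a small competition is the pragmatic default.
* **Record semantics**: a record hit produces the new ray and rewrites the
  entry without adding a fresh pair for it; only freshly *tested* positives
  append new entries.  This mirrors the recorded-slicer pseudocode exactly;
  a soundness audit in the tests re-verifies every live record entry
  algebraically after each insertion.
* **New rays' active sets** are recomputed by direct dot products over
  $J \cup \{k\}$ rather than set algebra on the parents' active sets, to
  capture coincidental incidences in highly degenerate inputs; later
  colaminarity tests depend on them being complete.
* **Duplicate newborn rays** (same primitive vector from two pairs) cannot
  occur with exact tests; a counter (`duplicates_merged`) tracks the
  assertion and the suite checks it stays zero.
* **Start acquisition**: `start = "auto"` tries the origin; any feasible
  point is accepted and tightened to a vertex (`tighten_to_vertex()`) by
  moving along exact null-space directions of the active rows, which adds
  an independent active row per step and so terminates in at most $n$
  moves.
* **Unboundedness** (an unblocked ray) is a hard error naming the ray,
  because the method's correctness assumes a compact feasible region;
  `allow_unbounded = TRUE` downgrades it to a skip with the output marked
  partial.

## What the generators emulate

The fixture families span the complexity spectrum the method is meant for:

* `gen_ns_example()` is the two-party no-signaling correlation system with
  binary inputs and 3/2 outcomes ($m = 24$, $n = 14$) -- moderately
  degenerate, with known ground truth: 108 vertices, 1548 edges, degrees
  16 (72 vertices) and 54 (36 vertices), 6144 bases at the origin.
* `gen_birkhoff(l)` builds the doubly-stochastic polytope in reduced
  coordinates ($n = (l-1)^2$, $m = l^2$): highly degenerate, densely
  connected, $l!$ permutation-matrix vertices, diameter 2 from $l = 4$ on.
  (At $l = 3$ the skeleton is the complete graph $K_6$, diameter 1, so the
  diameter fact is asserted only for $l \ge 4$.)
* `gen_random_regular(n, m, seed)` draws $m$ unit directions on the whole
  sphere, rationalized to denominator $10^6$, as tangent half-spaces
  $u_i \cdot x \le 1$.  Sampling the whole sphere (rather than one orthant)
  is what makes a bounded intersection achievable at all; draws whose
  directions fail to span positively are rejected and redrawn, with the
  boundedness check itself run exactly (`is_bounded()` slices the recession
  cone down to see whether anything survives).  Rationalization makes
  "regular with probability 1" into "regular minus measure-zero accidents";
  the shipped seeds are asserted regular in the tests.
* `gen_classic()` supplies the textbook oracles -- hypercube, simplex,
  cross-polytope -- whose skeletons are known in closed form; the
  cross-polytope contributes degeneracy ($\sigma = 2^{n-1} - n$)
  independent of the no-signaling fixture.

What the synthetic families do *not* emulate: irrational or
poorly-conditioned coefficient matrices (everything here is small-integer or
$10^{-6}$-grid rational), inputs with redundant (never-active) constraints
at scale, equality blocks (rejected at parse time), and unbounded feasible
regions as a use case rather than an error path.  Green tests on these
families show the algorithmic machinery is correct on exactly representable
inputs; they say nothing about floating-point robustness, which the package
deliberately does not offer.

## Verification strategy

Beyond unit examples, the suite leans on cross-checks that are independent
of the code paths they test: a brute-force oracle enumerates all
$\binom{m}{n}$ row subsets, solves each exactly, keeps the feasible
solutions and declares adjacency via $\mathrm{rank}(Z(p) \cap Z(q)) =
n - 1$; every fixture with $m \le 12$ must match it vertex-for-vertex and
edge-for-edge.  Invariance properties (final ray set under all 720
insertion orders of the worked example's origin cone and under sampled
alternative bases; the graph under start vertex, randomized bases and
orders) are asserted as set equalities after canonicalization.  The worked
example's published step details -- the first insertion's 3/9/2 partition
and its six newborn rays, the sparse 14-pair colaminarity pattern at the
fifth insertion, the 54 final rays, the intermediate ray-count trajectory
14, 18, 22, 31, 40, 47, 54 -- are frozen as explicit expected values.

## Problem sizes and costs

The package's own test problems are sized for interactive use: the worked
example converts in well under a second; the full 720-order sweep takes a
few seconds with the combinatorial test; exhaustively ranking all 38,760
candidate bases at the origin takes a few seconds of exact rank
computations.  Enumeration guards (`max_vertices`, the `cap` in
`enumerate_bases()`) protect against accidentally exponential inputs;
raising them is the user's explicit opt-in.  Timings are reported in
`compute_metrics()` split into slicing versus pivoting/traversal -- the two
regimes that dominate for densely versus sparsely connected outputs -- but
are never asserted in tests, being hardware-dependent.

## Limitations

* Equality ("linearity") blocks are not supported; eliminate them into a
  reduced coordinate system first (as `gen_birkhoff()` does).
* The feasible region must be full-dimensional and (for a complete graph)
  bounded; `m > n` is enforced structurally.
* Exact arithmetic trades speed for certainty: entries with huge numerators
  will slow the kernel, and there is no approximate fallback.
* The traversal keeps the whole vertex set in memory; polytopes with
  millions of vertices need a different engineering regime (disk spilling,
  parallel traversal) that is out of scope here.
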