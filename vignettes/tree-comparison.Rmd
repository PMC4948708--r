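---
title: "Comparing phylogenetic trees node by node: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing phylogenetic trees node by node: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocompare)
```

## The model

Two rooted trees $T_1$, $T_2$ on the same $n$ taxa are compared through
their clades. For a node $n$ let $L(n)$ be the set of leaf labels below
it. The similarity between nodes of opposite trees is the Jaccard index

$$S(a, b) = \frac{|L(a) \cap L(b)|}{|L(a) \cup L(b)|} \in [0, 1],$$

which is 1 exactly when the clades coincide and 0 when they are
disjoint. The *best corresponding node* of $a$ is
$\mathrm{BCN}(a) = \arg\max_b S(a, b)$, with its score colouring the
drawing of $a$. Tools in this tradition sometimes advertise
speed-optimized variants of the Jaccard index without spelling them
out; this package commits to the plain leaf-set Jaccard index and gets
its speed from the data structures and search order described below.

Because every $S$ is a ratio of small integers, ties are real and are
broken deterministically: larger intersection first (so an exact clade
match beats a vacuously large union), then smaller candidate clade, then
smaller preorder index. Tie comparisons use integer cross-multiplication,
never floating-point equality.

**Aggregate score.** The rooting search needs a whole-tree objective,
and no standard one exists for BCN scores, so this package defines one:
the mean BCN score over the internal non-root nodes of the first tree. The root is
excluded because its clade is always the full taxon set (it matches the
opposing root at 1.0 regardless of topology); leaves are excluded because
they match their namesakes at 1.0 whenever the leaf sets agree. For
degenerate trees with no internal non-root node the mean is taken over
leaves instead, giving 1.0 on identical taxa.

## Speed: fingerprints and the climbing search

Each node stores its leaf set as a bitset packed into raw bytes over a
shared leaf index, built in one post-order pass; $|L(a)\cap L(b)|$ is a
byte-wise AND plus an 8-bit popcount table, $O(n/8)$ per pair.

The fast BCN search (`bcn_fast`) does not enumerate all pairs: for a
query node $a$ it walks, from each leaf of $L(a)$, the ancestor chain in
the opposing tree, accumulating intersection counts. Only ancestors of
shared leaves — the only nodes with non-zero intersection, hence the only
possible argmax beyond score 0 — are visited, and any node's score and
BCN can be computed independently of the rest. That independence is what
the lazy-evaluation contract exploits: rendering requests scores for
visible nodes only, so collapsed regions of a large tree cost nothing
until expanded. The exhaustive $O(n^2)$ oracle (`bcn_oracle`) builds
explicit 0/1 membership matrices and scores every pair through one
matrix product; the test suite requires bit-for-bit agreement of the two
routes on hundreds of seeded tree pairs.

## Best rooting

"Most consistent rooting" is interpreted as: the edge of the query tree
whose induced rooting maximizes the aggregate BCN score against the
reference, all edges evaluated, ties to the edge whose child endpoint has
the smallest preorder index (the current rooting wins ties, so an
already-optimal tree is returned unchanged).

Naively this costs one full comparison per edge. Instead we use the fact
that the rooted clades induced by rooting on any edge are drawn from a
fixed family: for each node $c$ of the (internally unrooted) query,
either its clade $L(c)$ or the complement $\overline{L(c)}$. Both are
scored against the reference once — $\max_b S(L(c), b)$ via the climbing
search, and $\max_b S(\overline{L(c)}, b)$ via the identity
$|\overline{A} \cap L(b)| = |L(b)| - |A \cap L(b)|$, which turns one
climb's counts into complement scores for *all* reference nodes by a
vectorized pass. The per-edge aggregate then follows from an ancestor
walk (ancestors of the candidate edge flip from clade to complement),
giving $O(n \cdot \mathrm{depth})$ overall after the precomputation. A
unit test checks these per-edge aggregates against literally rerooting
on every edge and comparing, for trees up to 16 leaves; at 737 leaves the
search runs in about a second.

Rerooting itself places the new root at the midpoint of the chosen edge
when a branch length is present (preserving all leaf-to-leaf path
lengths, verified against an independent implementation of cophenetic
distances), or with two absent half-lengths otherwise; placing the root
at the midpoint is the common convention and the only choice that keeps
the path-length invariant exact. A degree-2 old root is suppressed and its two
branch lengths summed; singleton chains present in the *input* are
preserved. Support values travel with their edges under rerooting,
labels with their nodes.

## Leaf order

The branch-swapping step minimizes the number of discordant leaf pairs
(Kendall tau distance) between the query's displayed leaf sequence and
the reference's. The algorithm is the barycenter heuristic from layered
graph drawing: one bottom-up pass orders each node's children by the
mean reference rank of their leaves (ties by preorder index). On a query
sharing the reference's rooted clade set the children of every node have
disjoint, contiguous reference rank ranges, so sorting by mean rank
reproduces the reference order exactly — objective 0, confirmed equal to
exhaustive enumeration over all child permutations for trees up to 10
leaves. As a guard, if the heuristic ever failed to improve the
objective the original tree is returned, making "never increases"
unconditional.

## Collapsing and the viewport

With root depth 0, collapsing all internal nodes at depth $d$ leaves
$r(d) = |\{\text{leaves at depth} \le d\}| + |\{\text{internal nodes at
depth} = d\}|$ display rows. `estimate_collapse_depth` returns the
largest $d \ge 1$ with $r(d) \cdot \text{label\_height} \le
\text{viewport height}$, clamped to 1 when nothing fits. The greedy
largest-fitting-depth rule is this package's own definition of "optimal
collapsing depth" from leaf count and viewing area. For
a perfectly balanced 1024-leaf tree, viewport height 640 and 16 px
labels it yields depth 5 ($2^5 \cdot 16 = 512 \le 640 < 2^6 \cdot 16$).
Visible and hidden nodes always partition the node set; rendering stops
at collapsed nodes; `expand_path_to` removes exactly the collapsed
ancestors of a target, which is how a highlighted node's counterpart is
revealed inside a collapsed region.

## Rendering

SVG output is a pure function of its inputs: fixed monospace metrics,
two-decimal coordinates, no timestamps or randomness, so repeated calls
are byte-identical and testable. Scores map to colour bins as
$\min(\lfloor s \cdot k \rfloor, k - 1)$ over a $k$-class yellow-to-blue
sequential ColorBrewer ramp (default $k = 9$), uniform on $[0,1]$.
Collapsed clades draw as triangles one row tall, width proportional to
the hidden leaf count and capped at 15% of the panel — a legibility
choice. The second tree of a
pair is mirrored with labels facing inward. CSS classes (`bin-0` …,
`highlight`, `selected`, `search-path`) carry the semantics; exact glyph
styling is not contractual.

## Serialization

Extended output attaches NHX-style tags after the branch length:
per-node `collapsed=1` / `highlighted=1`, per-node scores `S=`, and the
viewport (`vw`, `vh`, `lh`) on the root. The tag vocabulary is this
package's own dialect; the NHX convention was chosen because bracketed
tags survive any plain parser. Branch lengths print with 10 significant digits, lossless at
printed scale; writing, parsing, and re-writing an annotated tree is the
string identity, which is how round-trip tests are phrased. Internal
numeric labels are read as support values — consequently a deliberately
numeric internal *name* would be coerced to support, a documented
limitation.

## Synthetic data: what it does and does not establish

No external dataset is required or used; the stated world is synthetic.
`random_tree` grows binary topologies by seeded random sequential leaf
attachment (each new leaf subdivides a uniformly chosen edge) with
optional Exp(1) branch lengths; labels are `T0001…`. Perturbations are
NNI moves across uniformly chosen internal (in the unrooted sense)
edges, random rerooting, and child-order shuffles, all pure functions of
a single integer seed. The 737-leaf recovery case exercises the method
at the scale of real many-taxon gene-family trees, on a synthetic
topology.

A green identity-recovery test therefore establishes that rooting and
ordering differences are fully undone for same-topology pairs at
realistic sizes, and that NNI-perturbed pairs degrade monotonically in
the median. It does *not* establish anything about trees with partially
overlapping taxon sets (rejected up front, by design), about real
support-value distributions, or about which of two *different*
topologies is "right" — the comparison localizes disagreement, it does
not adjudicate it.

## Numerical and degenerate-input choices

- Exact rational comparison for all argmax ties; a `1e-9` float window
  only pre-screens candidates.
- `best_rooting` treats aggregates within `1e-12` as tied; sums of exact
  1.0 scores make the recovery criterion exact, not approximate.
- Absent branch lengths are `NA` end to end (never 0); phylogram layout
  treats them as 0 for drawing only.
- Polytomies are accepted everywhere (parser, splits, swaps, barycenter,
  NNI candidates); star trees have an empty split set.
- Trees with fewer than 2 internal non-root clades get aggregate 1.0 by
  the leaf fallback; rooting search returns such trees unchanged.

## Known limitations

- Both trees must carry exactly the same leaf label set.
- The leaf-order heuristic is optimal for same-topology pairs but only
  heuristic across genuinely different topologies (the general problem
  is NP-hard).
- Node ids are renumbered by rerooting; visualization state is keyed to
  node ids and is therefore dropped on reroot.
- Search is exact-match and case-sensitive.
- NEXUS/PhyloXML input, interactive viewing, and sharing services are
  out of scope.
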