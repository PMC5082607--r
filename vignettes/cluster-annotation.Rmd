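---
title: "Methods: automatic cluster annotation and summarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic cluster annotation and summarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netannotate)
```

`netannotate` summarizes a modular network in four stages — cluster, build a
word cloud per cluster, condense it to a label, annotate or collapse — and
this vignette records how each stage is defined, which parameters matter,
and where a genuinely open design choice was made.

## The network model

A network is a pair of tibbles: nodes (`id`, optional `x`/`y` coordinates,
text or numeric attribute columns) and edges (`from`, `to`, optional
`weight`). Node ids are opaque strings — `"1"` and `"01"` are different
nodes, and numeric-looking ids are never coerced, because identifier
coercion is a classic source of silent joins gone wrong when tables come
from mixed sources. Directed input is accepted and stored as given, but all
cluster, adjacency and collapse logic is direction-free, and parallel edges
are kept in storage while deduplicated for adjacency queries: multi-edge
networks (several interaction types between two proteins) should neither
lose data nor double-count neighbors.

## Clustering

Two paths produce a partition. `clusters_from_attribute()` groups nodes by a
shared attribute value — the route for precomputed cluster ids or categorical
annotations; nodes missing the attribute stay unclustered. `mcl_clusters()`
is a standard dense Markov-clustering iteration:

* self-loops of weight 1 are added (guaranteeing aperiodicity), columns are
  normalized to a transition matrix;
* expansion (matrix squaring) alternates with inflation (entrywise power,
  default 2, then column renormalization);
* entries below `1e-6` are pruned each iteration; iteration stops when
  successive matrices differ by less than `1e-8` in max norm or after 100
  rounds;
* clusters are read off attractor rows (nonzero diagonal); overlapping
  attractor systems are merged, and a node attracted to no attractor becomes
  its own singleton so the disjoint-cover invariant always holds.

These iteration controls are this package's own choices — standard MCL
practice, stated here because the algorithm's behavior near convergence
depends on them. Expansion cannot create entries across disconnected blocks,
so the result provably refines the connected components; the tests check
this against igraph's component labeling on random graphs. Weights of
parallel edges are summed into the single transition-matrix entry, reading
parallel edges as additive connection strength. Cluster ids are consecutive
integers ordered by descending size (ties: smallest member id), making runs
bit-reproducible.

The dense implementation targets the networks this tool is built for —
enrichment maps and similar summaries of hundreds, not millions, of nodes.

## Word clouds and the normalization factor

Tokenization lower-cases, splits on whitespace and punctuation while keeping
intra-word hyphens and underscores (`tgf-beta` stays one token), and removes
a compact English stopword list plus pure numbers. The stopword list is
user-extensible; pathway descriptions and publication titles are English
phrases, so an English default is appropriate.

Each word's score blends two frequencies, each min–max rescaled to
[0, 1] across the cloud before blending so the normalization factor `k`
interpolates comparable quantities:

$$\mathrm{score}(w) = (1-k)\,\widetilde{f_c}(w) + k\,\widetilde{\left(\frac{f_c(w)}{f_n(w)}\right)}$$

with `f_c` the word's share of the cluster's tokens and `f_n` its share of
the whole network's tokens (all nodes, clustered or not — the network-wide
background should include everything the reader sees). The two published
limit behaviors anchor the algebra: at `k = 0` the ranking equals the raw
cluster-count ranking, and as `k` grows, words spread uniformly over the
network (ratio ≈ 1, minimal after rescaling) fall behind words concentrated
in the cluster. The exact blending algebra between those limits is this
package's design choice; min–max rescaling keeps `k` dimensionless and makes
the interpolation exact at both ends. A degenerate cloud whose values are
all equal rescales to 1, so a one-word cloud sits at maximum font.

Scores map affinely onto the font range (default 1–64 pt; all-equal scores
map to the maximum). Word order is the index of first appearance scanning
member nodes sorted by id, attributes in their selected order — determinism
is the goal; any fixed scan order would do.

**Adjacency groups.** Two words are linked when they occupy adjacent token
positions in the text of at least two member nodes; connected components of
that link graph are the groups. The two-node threshold asks for *repeated*
adjacency — a phrase, not a coincidence — while clusters with fewer than
three members drop the threshold to one so tiny clusters are not starved of
grouping information. The threshold is a package constant, stated here
because no published value exists for it.

## Label selection

Both selectors emit at most `max_words` words (1–10; default 3) in their
original text order, so labels read like the source descriptions.

* *Biggest words*: take the `max_words` largest-font words (size ties break
  toward the earlier word), re-sort by appearance order. The test suite
  checks this greedy rule against a brute-force subset-enumeration oracle.
* *Adjacent words* (default): find the top `max_words` words, give every
  word sharing an adjacency group with any of them a `size_bonus` (default
  8), capped at the largest original size within the word's **own** group —
  the cap read as group-local, since a global cap would almost never bind —
  then re-sort by boosted size and take the top `max_words`. With bonus 0 or
  all-singleton groups this provably reduces to biggest-words, which the
  tests exercise. The bonus also applies to the top words themselves;
  the cap makes that a no-op.

Emission order after the boosted re-sort is by appearance order, matching
the sibling selector; boosted size decides membership, not display order.

## Annotation geometry and display

A cluster's shape is the axis-aligned bounding box of its member positions,
expanded by `padding` (default 10 layout units) on every side; the ellipse
variant circumscribes the padded box (semi-axes √2 times the half-sides), so
member positions always fall inside either shape kind. The label anchors
horizontally centered just above the box top. With font scaling on, a
cluster of *n* nodes gets label font `base_font · (1 + log10 n)` —
sublinear, so a 100-node cluster reads larger but not 100× larger. Both the
padding and the scaling curve are package choices with no published values.
Labels are layout-free: a cluster without coordinates can be labeled but
not drawn.

## Collapse semantics

Collapsing removes the member nodes and every incident edge, adds one group
node (id `group:<cluster>`, named by the label, at the member centroid), and
adds exactly one meta-edge per external neighbor, carrying the count of
underlying boundary edges. Meta-edges aggregate no weights — only
connectivity and multiplicity are summarized; any weight-aggregation policy
(sum? max? mean?) would silently assert semantics the data may not have.
Collapses apply sequentially, so earlier group nodes are external to later
collapses and two adjacent collapsed clusters end up joined by one
meta-edge. Expansion is LIFO: `expand_all()` restores in reverse collapse
order, after which node set, edge multiset, attributes and positions equal
the pre-collapse state exactly (property-tested over random fixtures).
Expanding out of order fails loudly when a stored edge endpoint is still
collapsed rather than restoring a half-consistent network. Switching the
active annotation set requires expanding first, because grouped nodes may
belong to different clusters in the other set.

## The synthetic fixture generator

`make_themed_network()` emulates the inputs this tool is designed for — an
enrichment map with themed pathway descriptions — as a planted-partition
graph with planted word themes. Defaults are the regime the package is
validated in: 4 clusters × 10 nodes, `p_in = 0.9`, `p_out = 0.02`, 10 words
per node of which 80% come from the cluster's 20-word theme vocabulary and
the rest from a shared background sampled with Zipf-like weights, so a few
fillers recur network-wide the way "pathway" and "regulation" recur in real
descriptions. Theme words are written as a contiguous block, giving
adjacency grouping phrase structure to find. Positions come from per-cluster
Gaussians (σ = 30 around centers on a radius-200 circle). All randomness
derives from the `seed` argument; no OS entropy is used.

What the generator does **not** emulate: overlapping gene sets (enrichment
map edges weighted by gene overlap), heavy-tailed degree distributions,
natural-language morphology (plurals, stemming variants), or enrichment
statistics. Passing tests therefore demonstrate the machinery's correctness
and its behavior under clean modular structure, not performance on noisy
real data — on real enrichment maps, label quality depends on attribute
choice and on tuning `k`, exactly the experimentation multiple annotation
sets exist for.

## Validation scale

The test suite and `scripts/acceptance.R` validate at sizes chosen to
exercise every code path while keeping a full run in seconds: 200 random
clouds of ≤ 8 words against the brute-force selection oracle, 100 random
score vectors for the `k = 0` limit, 50 constructed exclusive-vs-ubiquitous
word pairs over the `k` grid {0, 0.25, 0.5, 0.75, 1}, 100 random
network/partition fixtures for collapse round-trips and meta-edge scans, and
20 seeds each for MCL planted-partition recovery (adjusted Rand index
against the planted labels, via mclust) and 3-word label theme recovery.

## Known limitations

* Dense-matrix MCL is O(n³) per iteration; networks beyond a few thousand
  nodes need a sparse implementation.
* No stemming or lemmatization: "pathway" and "pathways" are distinct words
  and can both enter a label.
* Shape annotations of overlapping clusters are drawn as-is; no overlap
  resolution is attempted.
* Session JSON stores the full network; it is a model file, not an
  incremental format.
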