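# netannotate

Automatic cluster annotation and summarization for networks.

Modular networks — enrichment maps whose nodes are pathways, co-authorship
networks, protein–protein interaction networks annotated with GO terms —
contain regions of tightly connected nodes that share a theme. `netannotate`
turns such a network into a visual summary: it identifies clusters, condenses
the textual attributes of each cluster's nodes into a short semantic label,
draws an enclosing shape with the label above it, and can collapse each
cluster into a single labeled group node so only the major themes remain
visible.

## Method

**Clustering.** Either group nodes by a shared attribute value (precomputed
cluster ids, pathway categories, ...) or run Markov clustering (MCL) on the
connectivity: the column-stochastic transition matrix (self-loops of weight 1
added) is alternately expanded (squared) and inflated (entrywise power *r*,
default *r* = 2, then column renormalization) to convergence, and clusters
are read off the attractor rows. MCL never merges disconnected components,
so its partition always refines the connected components.

**Word clouds.** Each cluster's node text is tokenized (lower-cased, split
on punctuation except intra-word hyphens/underscores, stopwords and pure
numbers removed) and every word *w* is scored by blending its within-cluster
frequency with its enrichment over the whole network:

```
score(w) = (1 - k) · f_c(w)' + k · (f_c(w) / f_n(w))'
```

where `f_c` and `f_n` are the word's frequency among the cluster's and the
entire network's tokens, and `'` denotes min–max rescaling over the cloud.
The normalization factor `k ∈ [0, 1]` (default 0.5) controls how strongly
ubiquitous words such as "pathway" or "regulation" are suppressed: at
`k = 0` only cluster counts matter; as `k` grows, words concentrated in the
cluster win. Scores map affinely onto font sizes (1–64), and words that
repeatedly occupy adjacent token positions are joined into *adjacency
groups* — multi-word phrases the label selector can exploit.

**Labels.** Two selection heuristics condense a cloud into a ≤ *N*-word
label (*N* ∈ [1, 10], default 3). *Biggest words* takes the *N* largest-font
words and emits them in their original text order. *Adjacent words* (the
default) first finds the *N* largest words, then grants every word sharing
an adjacency group with them a size bonus (default 8, capped at its group's
largest word size), re-sorts, and takes the top *N* — biasing labels toward
coherent phrases.

**Annotation and collapse.** Every cluster gets a padded bounding shape
(ellipse or rectangle) and its label anchored above; geometry is recomputed
from current coordinates so annotations follow the layout. Collapsing a
cluster replaces its members with one group node named by the label, and
each external neighbor of any member is reconnected by a single *meta-edge*
carrying the count of underlying boundary edges; expansion restores the
original network exactly. A network can hold many annotation sets (different
clusterings, different label options), one active at a time.

## Worked example

```r
library(netannotate)

fx <- make_themed_network(
  theme_vocab = list(
    c("dna", "repair", "damage", "excision", "strand", "break"),
    c("cell", "cycle", "mitotic", "checkpoint", "spindle", "division"),
    c("immune", "response", "interferon", "cytokine", "antigen", "signaling"),
    c("lipid", "metabolism", "fatty", "acid", "oxidation", "synthesis")
  ),
  background_vocab = c("pathway", "regulation", "process", "positive",
                       "negative", "activity", "protein", "gene"),
  words_per_node = 8, seed = 1)

p   <- mcl_clusters(fx$network)
set <- create_annotation_set(fx$network, p,
  cloud_options("desc", normalization = 0.5), label_options(), "MCL themes")
tidy(set)
#> # A tibble: 4 × 4
#>   cluster label                        nodes collapsed
#>   <chr>   <chr>                        <int> <lgl>
#> 1 1       repair strand excision          10 FALSE
#> 2 2       checkpoint division cycle       10 FALSE
#> 3 3       signaling antigen interferon    10 FALSE
#> 4 4       metabolism acid synthesis       10 FALSE
```

The fixture plants four 10-node communities whose node descriptions mix
theme words (80%) with shared fillers; MCL recovers the planted communities
and every 3-word label is built from the planted theme vocabulary — the
fillers ("pathway", "regulation", ...) are suppressed by the normalization
factor. `glance(set)` summarizes the options used; `build_cloud()` exposes
the underlying cloud (word, font size, appearance order, adjacency group);
`autoplot(set, net)` draws the annotated network with ggplot2, and
`render_svg()` writes the production SVG.

The same pipeline runs from a shell via `inst/cli/annotate`:

```sh
annotate net.graphml --attrs attrs.tsv --cluster-source mcl \
  --label-attr desc --max-words 3 --normalization 0.5 \
  --collapse-all --render out.svg --out collapsed.graphml \
  --report clusters.tsv --session session.json
```

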