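---
title: "Inferring disease hierarchies from disease-gene associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring disease hierarchies from disease-gene associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseasetree)
```

## The problem

Disease taxonomies such as the MeSH category C forest or the Disease
Ontology organise disease terms by physiological and anatomical criteria.
`diseasetree` asks how much of that hierarchical structure is recoverable
from molecular data alone — specifically from disease–gene association
tables — and provides the machinery to measure the answer: two inference
algorithms, reference preprocessing, and four comparison metrics.

The package's working assumption is that related diseases share associated
genes, so the Jaccard index of gene sets,
$sim(A, B) = |G_A \cap G_B| / |G_A \cup G_B|$, is a meaningful similarity,
and that more general disease terms accumulate more literature, so citation
counts can orient parent–child relationships that gene overlap alone cannot.

## Parent Promotion

Hierarchical clustering of diseases produces a dendrogram whose internal
nodes are unnamed *sets* of diseases — not usable directly as a taxonomy,
which needs one named term per node. Parent Promotion resolves each cluster
to a single term:

1. Convert similarities to distances ($1 - sim$) and run complete-linkage
   agglomerative clustering.
2. Walk the merges bottom-up. Every cluster carries one *representative*,
   initially the singleton disease itself. When two clusters merge, the two
   representatives compete: the one with more citations is promoted, becomes
   the parent of the losing representative, and represents the merged
   cluster.
3. A disease that has lost once is a child forever — only the most recently
   promoted disease of a cluster competes at the next merge. The last
   representative standing is the root.

The output is always a rooted tree on exactly the input diseases, with
$n - 1$ edges and citations non-increasing along every edge. Note the
promotion contest is strictly between the two current representatives; the
other members of a cluster stay where earlier promotions put them. This is
the only reading under which a previously promoted mid-level term keeps its
own children when its cluster is absorbed by a more-cited term.

### Numerical and tie-breaking choices

* **Clustering engine.** `complete_linkage()` delegates to
  `stats::hclust(method = "complete")`, the standard and deterministic
  implementation of this linkage in R. Equal-height merges are ordered by
  `hclust`'s internal rule; since all remaining choices in the package are
  documented and deterministic, repeated runs on the same input are
  identical.
* **Citation ties.** The larger count wins; on an exact tie the
  lexicographically smaller disease id (radix/byte order, locale
  independent) becomes the parent. Determinism was the only requirement
  here.
* **Spanning-tree ties.** `mwst_infer()` uses Kruskal's algorithm with edges
  sorted by (weight, smaller id, larger id). Ties at weight 1 are pervasive
  in real association data — most disease pairs share no genes — so an
  explicitly documented order matters for reproducibility. Rooting ties
  (equal citation maxima) again go to the smaller id.
* **Weights.** "Minimum weight" is taken over *distances* $1 - sim$, i.e.
  the tree connects all diseases through their highest gene-set
  similarities.
* **Degenerate inputs.** Similarity is undefined for a disease with no
  genes; such terms must be pruned first, and the similarity functions
  raise an error rather than silently scoring $0/0$. Clustering and MWST
  require at least two diseases.

## Reference preprocessing

`read_obo()` reads `is_a` stanzas (obsolete terms skipped, synonyms kept in
a side map); `read_mesh_trees()` reads `(term_name, tree_number)` tables,
merging a name that occupies several tree positions into one node — the
forest becomes a DAG; a merge that would make a term its own parent drops
that edge with a warning.

`prune_and_reconnect()` removes terms with no associated genes. Deleting a
node reconnects each retained descendant to its *nearest retained proper
ancestors*: an edge $(p, x)$ survives exactly when some path $p \to \dots
\to x$ passes only through deleted nodes. The one-level rule ("link a
deleted node's parents to its closest annotated descendants") does not by
itself cover runs of consecutively deleted nodes; the nearest-retained-
ancestor closure is its transitive completion, and it is the unique
definition that both preserves reachability among retained terms exactly
and is idempotent — both properties are tested against a brute-force
transitive-closure oracle.

## Evaluation metrics

With $A(x)$ the proper-ancestor set of term $x$ in a hierarchy:

* **EC** — fraction of directed reference edges present in the inferred
  hierarchy. Direction must match; reversed edges score nothing.
* **Ancestor Jaccard / AC** — $J(A(x_{ref}), A(x_{inf}))$ per term,
  averaged over terms present in both hierarchies; terms that are roots in
  both are excluded (their ratio is $0/0$).
* **AP / AR** — means of $HP(x) = |A(x_{ref}) \cap A(x_{inf})| /
  |A(x_{inf})|$ and $HR(x) = |A(x_{ref}) \cap A(x_{inf})| / |A(x_{ref})|$,
  each averaged over the shared terms where its denominator is non-zero.
* **F** — the harmonic mean $2 \cdot AP \cdot AR / (AP + AR)$ of the two
  *averages* (macro-F), 0 when both are 0.

Three choices here were genuinely open and are worth recording. First, EC
is normalised by the reference edge count only — an inferred edge whose
endpoints the reference lacks is simply a non-match, and no term-universe
restriction is applied. Second, the averaging universe for AC and AP/AR is
the *intersection* of the two node sets; for the tree methods, whose output
nodes are exactly the reference's, the distinction is invisible, but it
makes the metrics total for arbitrary DAG pairs. Third, F aggregates the
averaged AP and AR rather than averaging per-term F values; per-term
HP/HR/F are returned in the report's `per_term` table for users who prefer
the other aggregation.

A structural observation made precise by the tests: any inferred *chain*
following a topological order of the reference has $AR = 1$ exactly (every
true ancestor of a term precedes it in the chain). Tall, thin trees —
which the MWST baseline tends to produce — therefore score well on recall
while being poor taxonomies by the other measures; this is why all four
metrics are reported together.

## The synthetic generator

`generate_taxonomy()` draws a random attachment tree (each new node picks a
uniform parent with spare capacity; `max_children` default 3, typical of
the branching in curated disease trees). `generate_associations()` gives
the root `genes_per_term` fresh genes (default 5, the order of magnitude of
well-annotated diseases); each child inherits a `inherit_fraction` sample
(default 0.7) of its parent's set plus its own fresh genes, so gene-set
similarity decays with tree distance. `noise_swap_rate` reassigns that
fraction of association pairs to uniformly random diseases, leaving every
disease at least one gene. `generate_citations()` emits
`round(citation_base * citation_decay^depth)` (defaults 10000 and 0.5)
minus a jitter bounded so counts never reorder across adjacent depths —
strictly decreasing along every root-to-leaf path, as the promotion signal
assumes. Each stage seeds its own stream from `seed` plus a fixed offset
(0, 1, 2), so stages are reproducible independently as well as jointly.

What the generator emulates: nested gene content along the taxonomy, noisy
annotations, and literature volume growing with generality. What it does
not: source-specific biases (Mendelian versus association-study evidence),
term-vocabulary mismatches between databases, citation counts that violate
the generality assumption (a real failure mode: a specific but heavily
studied disease can out-cite its own parent and be promoted above it), and
the extreme sparsity of real association data. Passing the synthetic suite
therefore shows the algorithms and metrics are implemented correctly, not
that real taxonomies are recoverable at any particular accuracy.

### Separable fixtures

`make_separable_fixture()` produces datasets on which Parent Promotion
provably returns the generating tree (EC = 1). Rather than hoping a
parameter setting of the generative model separates, the fixture constructs
gene sets realizing an exact ultrametric: a dendrogram is planned in which
each parent's singleton cluster absorbs its children's completed subtree
clusters one by one; each planned merge event owns one shared "path gene",
a disease's gene set is the path genes of all events above it, padded with
private genes to a common size $S$. Two diseases then share exactly $C$
genes, where $C$ counts the events above their lowest common merge, giving
Jaccard $C / (2S - C)$ — strictly increasing down every dendrogram path.
Complete linkage on an ultrametric reproduces its dendrogram (equal-height
merges can only involve disjoint clusters, so order is immaterial), and
citations strictly decreasing with depth make the parent win every
promotion contest. Recovery is thus a theorem about the construction; the
tests verify the implementation delivers it across sizes and seeds.

## Problem sizes in the test suite

The suite checks the implementations against independent brute-force
oracles at sizes where enumeration is exact: all five metrics against a
transitive-closure oracle on 200 random DAG pairs of up to 10 nodes;
spanning-tree weight against full Prüfer enumeration ($n^{n-2}$ trees,
$n \le 7$, 100 instances); complete-linkage heights against a naive
$O(n^3)$ agglomeration ($n \le 8$); exact recovery on separable fixtures of
6 and 30 terms over 50 seeds; and structural invariants of Parent Promotion
on 100 random instances. These sizes make enumeration exact and keep the
default suite fast; all scale knobs are plain loop bounds in the tests.

## Limitations

* Citation counts are an imperfect proxy for generality; where a specific
  term out-cites its ancestor, Parent Promotion inverts that branch.
* Both methods output trees, so a DAG reference with multi-parent nodes
  caps achievable EC below 1.
* Term-vocabulary mapping between MeSH and OBO id spaces is out of scope;
  inputs must share an id space (the synonym side map from `read_obo()` is
  provided as raw material).
* Association confidence scores are not modelled; inputs are binary pairs,
  deduplicated across sources.
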