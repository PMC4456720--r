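---
title: "Degree-of-interest analysis of integrated data-knowledge networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-of-interest analysis of integrated data-knowledge networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdoi)
```

## The model

`netdoi` operates on an undirected gene network `G = (V, E)` whose elements
carry two kinds of evidence: numeric attributes measured in an experiment
(p-values of association with a phenotype, expression correlations, fold
changes) and annotation memberships curated in knowledge sources (pathway
and ontology gene sets, supplied as GMT files). Relationships are keyed by
unordered gene pair; an edge supported by several evidence types (a data
correlation *and* a shared pathway) is a single relationship carrying the
set of its evidence labels. Gene identifiers are exact, case-sensitive
strings — the package deliberately does no symbol aliasing, which belongs to
upstream identifier mapping, not to network analysis.

The central abstraction is the *degree-of-interest field*: one value per
node and per edge. Continuous fields live in `[0, 1]`, discrete fields in
`{0, 1}`. Because filtering needs values on both element kinds while any
attribute lives on only one, fields are extended: node-derived values go to
edges with the minimum of the two endpoints (an edge should disappear as
soon as either gene does) and edge-derived values go to nodes with the
maximum over incident edges (a gene should survive while any of its edges
does). Two consequences of this choice are load-bearing and tested as
invariants: a visible edge can never lose an endpoint, and thresholding
commutes with the extension because both `min` and `max` are monotone.

### Conventions at the boundaries

Three situations the formulas leave open are fixed as follows:

- **Isolated node under an edge-derived field.** The maximum over an empty
  edge set is defined as 0: a gene with no relationships carries no
  edge-derived interest.
- **Missing attribute values.** A gene or edge without a value for the
  attribute gets DoI 0. Absence of evidence is treated as absence of
  interest, never as interest; the alternative (dropping the element from
  the field) would break the "every element has a value" contract that the
  combination operators rely on.
- **No filters selected.** An empty list of DoI functions combines to the
  constant-1 field, so "no filter" means "everything visible", not
  "nothing visible".

### Attribute transforms

Raw attributes must reach `[0, 1]` with higher = more interesting before
they become fields; the package validates the range after transforming.
For p-value-like attributes two transforms are offered: `one_minus`
(`doi = 1 − p`), under which the conventional cutoff `p ≤ 0.05` corresponds
to threshold `θ = 0.95`, and `neg_log10_capped`
(`min(−log10 p / c, 1)`, default cap `c = 10`), which spreads small
p-values out instead of compressing them near 1. `one_minus` is the
default used throughout the examples because its thresholds translate
directly to familiar significance levels; every field records which
transform built it in its provenance, so results always declare the choice.
Signed attributes such as correlations are expected to be transformed
upstream (the fixture generator ships `abs_correlation` alongside
`correlation` for exactly this reason).

### Combining fields

Continuous fields are thresholded first — `doi < θ` becomes 0, applied to
both the node and edge values, which by the commutation property equals
thresholding only the native side — and then combined elementwise with fuzzy
logic: AND is `min`, OR is `max`. Discrete fields combine with boolean
logic. The defaults (AND for continuous, OR for discrete) encode the common
analysis posture: every experimental condition must hold, any of the
selected knowledge sources suffices. Importance-weighted knowledge DoI
turns a panel of discrete fields into one continuous field via
`1 − Π(1 − imp_k)` over the sources annotating the element, with weights
normalized to sum to 1; a single annotating source yields exactly `imp_k`
(the implementation special-cases the one-factor product to keep this exact
in floating point). The final field is `min(discrete, continuous)` and an
element is visible iff its final DoI exceeds 0.

## Annotation-based layout

Given a filtered subnetwork and a selection `A′` of annotation groups, every
gene is assigned its *signature*: the exact subset of `A′` containing it.
This is a formal-concept view of the gene × annotation context in which
each gene is placed in exactly one group, so the group member sets partition
the annotated genes. The subset graph has one node per realized non-empty
signature and one edge per covering pair under strict signature inclusion.
Computing the covering relation on *realized* signatures only is what
produces the direct links between groups more than one level apart: if
`{A1} ⊂ {A1,A2,A3}` and neither intermediate signature is realized by any
gene, the pair is covering and gets an edge. Genes matched by no selected
group go to a residual pool that is laid out along the canvas margin rather
than hidden — they are part of the filtered subnetwork and discarding them
silently would misrepresent the filter's result.

Edge weights are `2/(|n₁| + |n₂|)`, inversely proportional to the two group
sizes, bounded in `(0, 1]` (two singletons give weight 1). The sum-based
form is symmetric, never degenerate, and makes small specific groups — the
interesting intersections — sit close to their parents.

Placement is a two-step scheme. Step one runs Fruchterman–Reingold on the
subset graph with the edge weights scaling attraction (heavier edge →
shorter ideal distance; verified as a monotone relationship in the tests).
Step two lays each group's genes out independently with a force-directed
pass restricted to intra-group relationships, recentred and rescaled to fit
strictly inside a disc of radius `r0·√(group size)` around the subset-node
position, so group area is proportional to membership. A singleton's gene
coincides with its subset node. `r0` defaults to 0.3, chosen so discs at
the coordinate scale the FR layout produces rarely overlap for the group
sizes the generator emits; it is a parameter of every layout call. The FR
iteration count (500) and the initial uniform jitter in `[−1, 1]²` are
recorded in the layout's `params`; all randomness is derived from an
explicit integer seed, and coincident initial positions are impossible up
to RNG ties because initialization is a continuous draw. The published
description of this layout names neither the cooling schedule nor the
weight-to-force mapping, so this package fixes both by delegating to
igraph's Fruchterman–Reingold implementation and recording its parameters.

## Comparing subnetworks

The reference for a comparison is the subnetwork with the most genes (ties:
more subset groups, then input order). The super-graph starts as a copy of
the reference subset graph with its positions. Each other subnetwork's
group is then either *deduplicated* — identical signature and identical
member set already present — by tagging the existing node with the
additional subnetwork id, or *added* and connected to every existing node
it shares genes with, the weights being overlap sizes normalized by the
largest overlap of that added node, so they stay in `(0, 1]` like the
subset-graph weights. "Similar sizes of overlaps" is read strictly as exact
equality: among equal overlaps the neighbor ranking uses the number of
subnetwork relationships joining the two member sets, recorded in the edge
table's `conn` column, as a secondary sort key only — it never changes a
weight. A group overlapping nothing attaches to the node it has most
connecting relationships with, or stays isolated if there are none.

Layout again runs in two steps, with the reference frozen: the FR pass pins
every reference node by equality bounds, which keeps the coordinates
bit-identical (asserted after every layout), and the within-group pass runs
only for added groups. A gene placed in both the reference and an added
group keeps its reference position, so each gene is drawn once; its node is
tagged with all the subnetworks it belongs to.

## Figures

Numeric attributes map to color through a diverging scale anchored at zero:
the domain is `(−max|v|, 0, +max|v|)`, so 0 always hits the neutral
midpoint and sign is never ambiguous. The default palettes are ColorBrewer
RdBu (reversed: blue = negative, red = positive) for values and Set2 for
group identities. Missing values render neutral gray.

Group outlines are isocontours of a sum-of-Gaussians field: a bump of unit
height at each member position (bandwidth 0.35 × group-disc radius),
marched at iso-level 0.5. Every member position is therefore strictly
inside a contour — its own bump already exceeds the level. This is a
deliberate simplification of obstacle-avoiding set-outline algorithms:
excluding *non*-members is encouraged by the small bandwidth but not
guaranteed, so the renderer reports the number of enclosed non-members per
group as a metric instead of promising zero. SVG output is written directly
by the package with fixed number formatting, which is what makes repeated
runs byte-identical; the GraphML writer similarly serializes attribute
values with 17 significant digits so subnetwork exports round-trip at full
precision. Heatmaps draw conditions as rows and selected genes as columns
in selection order, with the same color mapping.

## The synthetic generator and what tests do (and do not) show

`generate_fixture()` emulates the statistical shape the method consumes: a
planted block of jointly interesting genes — signature sizes drawn from an
overlap profile over the terms of source `K1`, p-values in (0.001, 0.04)
inside the block versus (0.06, 1) outside, |correlation| in (0.6, 0.95)
inside versus below 0.49 outside — on a uniform background, with additional
random annotation sources and typed evidence labels. The separation is
intentional: thresholding at `θ = 0.95` on `1 − p` and `θ = 0.5` on
|correlation| recovers a non-trivial subnetwork rather than everything or
nothing. The default spec (300 genes, density 0.25, four sources) matches
the mid-hundreds-of-genes, ~10⁴-relationships scale of the analyses this
workflow targets; `case_study_fixture()` pins the two anchor sizes exactly
(711 genes / 74,373 relationships and 328 / 11,081, ten sources each). The
generator computes its ground-truth DoI with `oracle_doi()`, a straight-line
reimplementation that shares no code with the field algebra, and its
expected subset graph with an equally independent double-loop covering
computation — these are the package's oracles, not its implementation.

What the generator does *not* emulate: platform noise models, normalization
artifacts, correlated p-value structure, or the term-size and term-overlap
statistics of real ontologies. Passing tests therefore demonstrate the
correctness of the algebra, the graph constructions and the layout
contracts on data of realistic shape — they do not validate biological
conclusions drawn from any particular real dataset.

Problem sizes used by the test-suite and acceptance checks — oracle
comparisons on networks up to 200 nodes, 200 random annotation contexts up
to 12 terms and 50 genes for the covering-relation check, 20 seeds for
planted recovery and reference immobility, and one full pipeline per
case-study anchor — were chosen as the smallest sets that exercise every
code path with comfortable margins of randomness.

## Known limitations

- Subset-graph construction is quadratic in the number of realized
  signatures; selections of hundreds of terms with thousands of distinct
  signatures would need a smarter covering computation.
- The isocontour simplification can enclose stray non-members in crowded
  layouts (reported, not prevented).
- Networks are consumed pre-built; constructing integrated networks from
  live knowledge bases, network subtraction, and interactive
  brushing-and-linking are out of scope — the batch artifacts (positions,
  intersection tables, manifest) are designed to feed interactive tools
  instead.
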