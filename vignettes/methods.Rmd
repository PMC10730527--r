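---
title: "Methods: ontology-integrated networks and cross-species module comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-integrated networks and cross-species module comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modcompare)
```

`modcompare` compares the protein modules that underlie homologous
anatomical structures in two species. This vignette explains the models and
procedures it implements, the parameters that matter, the design choices
that were genuinely open, and what the simulation-based validation does and
does not establish.

## 1. Ontology-integrated networks

### Information content

The anatomy ontology is a typed DAG: child-to-parent edges labelled
`is_a`, `part_of` or `develops_from`. Annotations are propagated up the
hierarchy before counting (the true-path rule): a protein annotated to a
fin's radial skeleton also counts for the fin. A term's information content
is

$$IC(t) = -\ln p(t), \qquad
  p(t) = \frac{\mathrm{count}(t) + c}{\mathrm{total}},$$

with `count(t)` the propagated protein count, `total` the number of
distinct annotated proteins, and `c` a pseudocount.

Three choices here were open and are resolved as follows.

* **Pseudocount `c`** (`constant` in `compute_ic()`): default 1. Any
  positive value prevents $\log 0$ for unannotated terms; 1 is the smallest
  integer choice and its effect vanishes as corpora grow. It is
  configurable, and `c = 0` on a term with no annotations is rejected with
  an error rather than silently producing an infinite IC.
* **Logarithm base**: natural log. Downstream quantities are ratios of ICs
  (Lin similarity) or orderings, both invariant to the base.
* **Propagation relations**: IC counting and similarity closures use
  `is_a` and `part_of` only. `develops_from` is *not* a subsumption
  relation — a fin bud is not a kind of, nor a part of, a fin — so it
  participates only in the collection of original annotations (below),
  where developmental precursors are explicitly wanted.

Because `p` is capped at 1, IC is non-negative, and a term carrying every
protein has IC 0. IC is anti-monotone in the propagated count; this is a
tested invariant.

### Term and protein similarity

Term similarity maximises over the common-ancestor set $S(t_1,t_2)$:

$$sim_L(t_1,t_2) = \max_{t \in S(t_1,t_2)}
   \frac{2\,IC(t)}{IC(t_1)+IC(t_2)}$$

(Lin), or the same candidate multiplied by $(1 + IC(t))$ for the
relevance-weighted variant (`schlicker_printed`). The latter form is
retained exactly as commonly printed even though it is unbounded above;
because network weights must live in $[0,1]$, semantic networks built with
it are min–max rescaled before use. The classical relevance factor
$(1 - p(t))$, which is bounded, is available as `schlicker_classic`. When
$IC(t_1) + IC(t_2) = 0$ the similarity is defined as 0.

Protein similarity aggregates term similarity over the cross product of two
proteins' annotation sets. The aggregation is not canonical; the default is
the **maximum** (order-preserving, reduces to term similarity for
single-annotation proteins), with best-match-average (`bma`) available. A
protein with no annotations has *undefined* similarity (`NA` with a
warning), not zero — the distinction matters at integration time.

### Network integration

STRING-style confidences (0–1000, normalised to $[0,1]$; a unit-scale
dialect is auto-detected) form the edge backbone. For each PPI edge whose
endpoints both have defined semantic similarity, the integrated weight is
the convex combination

$$w = \alpha\, w_{\mathrm{ppi}} + (1-\alpha)\, w_{\mathrm{sem}},$$

with `alpha = 0.5` by default; PPI edges without a semantic counterpart
keep their PPI weight, and semantic-only pairs are **not** added as edges
(the interaction evidence is what makes a pair an edge; the ontology only
re-weights it). The exact combination rule used in prior integrated-network
work is not recoverable, so the symmetric convex form was chosen: it is
order-preserving in both inputs and reproduces each network at
$\alpha \in \{1, 0\}$ — both tested invariants. A `min_weight` filter
(default 0, i.e. off) drops low-confidence integrated edges; no published
cutoff exists, so filtering is opt-in.

## 2. Candidate prediction and cross-validation

A candidate protein's score is the signed chi-square neighbourhood
statistic: with $n$ the annotated-neighbour mass of protein $u$ and
$e = (\text{total incident mass}) \times \frac{|A \cap V|}{|V|}$ its
expectation under the background annotation frequency,

$$\mathrm{score}(u) = \mathrm{sign}(n-e)\,\frac{(n-e)^2}{e},
  \qquad \mathrm{score}(u) = 0 \text{ if } e = 0.$$

Two deliberate choices:

* **Weighted by default.** On an integrated network the edge weights carry
  the evidence, so `n` and the incident mass are weight sums
  (`mode = "weighted"`); the original count-based formulation is kept as
  `mode = "count"`, and is weight-scale invariant by construction.
* **Signed.** The unsigned statistic ranks strongly *depleted*
  neighbourhoods spuriously high; the sign sends them to the bottom.

Leave-one-out cross-validation scores each annotated protein with its own
annotation hidden — the held-out protein leaves both the neighbour sets and
the background count, so its expected mass uses $(|A|-1)/|V|$ — while
non-annotated proteins are scored once against the full set (scoring
negatives with each reduced set would change their scores by a factor
common to all of them, at |A| times the cost). ROC and precision–recall
curves come from a threshold sweep over the distinct scores with ties
grouped, which makes the trapezoid ROC AUC exactly the Mann–Whitney
pair-counting statistic with ties scored ½ — a tested identity. Candidates
are then called at the *lowest* cutoff (maximal recall) whose
cross-validated precision reaches the requested threshold; if the precision
is never reached no cutoff exists and no candidates are called.

## 3. Modules and cross-species comparison

A module for an anatomical entity combines proteins with original
annotations — directly to the entity, or to any term reaching it through
`is_a`/`part_of`/`develops_from` (parts and developmental precursors) —
with the predicted candidates, under the induced subgraph of the integrated
network. Original proteins absent from the network are reported as *lost*,
never silently dropped.

Members are ranked by weighted degree computed **within the module's
induced subgraph** (a hub of the module, not of the proteome; a
`degree_scope = "network"` flag restores the global notion), with exact
ties broken lexicographically so rank files are reproducible. For
comparison across modules of different sizes each weighted degree is
normalized by the module's protein count.

The ortholog map may be one-to-many in either direction. A protein is
*conserved* if at least one ortholog lies in the homologous module, and all
such co-orthologs are retained; per-side conserved sets are reported rather
than a single collapsed count, since the two sides genuinely differ after a
genome duplication (the one-copy species' count is the natural headline
number). Conserved vs module-specific normalized weighted degrees are
compared per species with a Wilcoxon rank-sum test — two-sided by default,
since the direction of the hub effect is the hypothesis under test, not an
assumption; one-sided alternatives are available.

The rank-sum test delegates to `stats::wilcox.test`: exact enumeration when
the pooled sample is at most 14 and tie-free, otherwise the normal
approximation with tie and continuity corrections. Ties force the
approximation (the exact distribution assumes distinct values); a fully
tied comparison is degenerate and returns p = 1. The exact route is
verified against exhaustive permutation enumeration in the tests.

## 4. Enrichment

Over-representation uses the one-sided Fisher (hypergeometric upper-tail)
test on propagated annotations. Following the over-representation
convention of DAVID-style tools, the `enriched` flag uses the **raw**
p-value at `alpha = 0.05`; Benjamini–Hochberg adjusted p-values are always
reported alongside so users can apply modern multiplicity hygiene. The
background defaults to all proteins of the species' annotation corpus and
is configurable (e.g. network nodes only). The same engine serves anatomy
terms and GO-style annotation tables — an annotation corpus is just an
ontology plus a protein–term table. Fate/role reports map module-specific
proteins through the ortholog table (every target of a one-to-many mapping
retained, unmapped proteins counted and reported) and enrich the mapped set
against the other species' annotations.

## 5. The synthetic worlds

`generate_world()` builds a seeded world: an ontology (complete `is_a` tree
plus a `part_of` part and `develops_from` precursor for each of two
designated target entities), two species of `n_proteins = 500` proteins,
one planted module per species, annotations, and an ortholog map.

What it emulates, and the defaults:

* **Module structure**: a planted partition — within-module edge
  probability `p_in = 0.3` with weights $U(0.6, 0.9)$, background
  `p_out = 0.01` with weights $U(0.05, 0.2)$. Modules are dense and
  heavy; the background is sparse and light, the premise of
  guilt-by-association prediction. Prediction benchmarks use a module of
  40 with `annotated_fraction = 0.75` (30 visible members, 10 hidden as
  recoverable ground truth).
* **Conservation and duplication**: `conserved_fraction = 0.3` of the
  species-B module maps into the species-A module;
  `duplication_rate = 0.25` of conserved B genes receive two A
  co-orthologs, emulating a teleost-style whole-genome duplication.
  Module-specific members receive background orthologs only outside the
  other species' module, so the planted conservation labels are exact.
* **The hub effect**: within-module pairs touching a conserved member gain
  `hub_bias = 0.1` extra edge probability. This plants, as a recoverable
  effect, the hypothesis that conserved proteins are the module's hubs —
  recovery is what the tests assert, not the biological truth of the
  hypothesis.
* **Default module size 80**: real anatomical-entity modules run to
  hundreds of proteins; 80 is a scaled-down analogue of the smallest, and
  a design-time power analysis showed the planted `hub_bias = 0.1` effect
  is reliably detectable by the rank-sum test at this size
  (per-replicate power ≈ 0.97, vs ≈ 0.67 at size 40), so comparison
  studies run at the default while prediction benchmarks configure the
  smaller module explicitly.
* Edge weights are uniform on their ranges — the simplest parameterisation
  with controllable separation; no attempt is made at Beta-shaped
  confidence distributions.

What it does **not** emulate: scale-free degree distributions, correlated
annotation noise, missing or erroneous interactions beyond the optional
`noise_edges` fraction, more than one module per species, or more than two
species. Passing the simulation studies therefore demonstrates that the
implementation recovers the effects it is designed to detect under the
stated generative model — it does not certify performance on real
STRING/Monarch-scale data, whose snapshot-dependent numbers are outside
desk-scale reproduction.

All generation is seeded (per-stage sub-seeds derived from the world seed
by fixed offsets), and identical seeds produce byte-identical files via
`write_world()`.

## 6. The pipeline

`run_pipeline()` chains the stages — simulate (optional), read, integrate,
cross-validate, predict, assemble, compare, enrich, homology-validate —
from one configuration (an R list or a YAML file), writing every result
table as TSV, the module networks as SIF and GraphML (weights printed at
full double precision so round-trips are exact), and a `manifest.json`
recording the package version, every parameter and seed, and the headline
counts. Input paths in the manifest are stored relative to the output
directory, so two runs with the same seed are byte-identical wherever they
are placed — a tested property. Homology validation reports, for each
predicted protein, whether an ortholog lies in the other species' module
and under which origin label (direct annotation, part/precursor, or itself
predicted).

Typical problem sizes in the test-suite studies — 500-protein worlds,
modules of 40–80, 20 seeded replicates per study — were chosen so each
study is a few tens of seconds while the binomial error on the reported
rates stays small.

## 7. Known limitations

* The OBO reader covers the subset used by anatomy ontologies (`[Term]`,
  `id`, `name`, `is_a`, `part_of`/`develops_from` relationships,
  `is_obsolete`); intersections, xrefs and logical axioms are ignored.
* The semantic-network construction is quadratic in the number of
  annotated proteins; it is intended for annotation corpora up to a few
  thousand proteins, not proteome-scale all-vs-all similarity.
* The integration rule is an explicit stand-in for an unrecoverable
  original; `alpha` is exposed rather than hidden.
* Exact Wilcoxon p-values under ties are out of scope (the tie-corrected
  normal approximation is used, as in `stats::wilcox.test`).
* Precision-threshold selection is a user choice per entity; the package
  does not automate the search for thresholds giving comparable module
  sizes across entities.
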