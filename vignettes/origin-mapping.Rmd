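---
title: "Mapping orthogroup origins on a clade ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping orthogroup origins on a clade ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnovel)
```

## The problem and the model

Comparative genomics of a kingdom-scale species sample asks, for every gene
family (orthogroup), *where on the phylogeny it first appeared*. funnovel
answers this with a threshold rule on the family's presence–absence pattern
rather than a probabilistic gain–loss model. The phylogeny is reduced to a
*clade ladder*: an ordered, nested sequence of evaluation clades from the
kingdom root towards the tips, each defined by its member phyla. An
orthogroup is called **novel at clade C** when

* its presence fraction is at least the cutoff (default 0.5) in **every**
  member phylum of C — in every member *subphylum* for clades flagged
  terminal, where within-phylum sampling is dense enough to resolve finer
  structure — and
* at most `outgroup_tolerance` species (default 1) **outside** C carry it.
  The outside set is everything not descending from C: non-member ingroup
  phyla *and* all designated outgroup species.

The per-phylum (rather than pooled) requirement protects poorly sampled
early-diverging phyla: a family present in one large derived phylum alone
cannot masquerade as an ancient gain. The one-species outside tolerance
absorbs occasional horizontal transfer and annotation/database errors without
letting genuinely widespread families through. Both thresholds are inclusive:
exactly 50 % presence qualifies, exactly one outside presence qualifies.

The rule deliberately ignores copy number — presence means at least one gene
copy — because duplicates of an old family inherit the parent's taxonomic
distribution and would otherwise inflate young nodes.

### Assumptions

* The backbone ladder is taken as known; the rule does not infer topology.
* Retention after emergence is substantial: a family kept in under half of
  each descendant phylum is invisible to the rule (a known source of
  undercounting; a laxer cutoff trades this against false positives).
* Every member phylum of every node has at least one sampled species; a node
  over an unsampled phylum is a configuration error, not a silent skip.

## Origin assignment and tie-breaking

`assign_origin()` walks the ladder root-to-tip and assigns each orthogroup to
the **first** (deepest, most inclusive) qualifying node; families qualifying
nowhere are `unassigned`. Several nested nodes can qualify simultaneously only
with tiny phyla and a nonzero tolerance; the deepest-node convention is a
parsimony argument — one older gain explains the data with fewer events than
a younger gain plus a transfer — and is documented rather than derived, since
a threshold rule has no likelihood to compare. Species relabeling and row
order do not affect calls, and raising the cutoff (or lowering the tolerance)
can only shrink the called set; both properties are under test.

A second pass, `validate_calls()`, consumes per-orthogroup counts of
non-fungal eukaryote organisms with homologs (from an external database
search, supplied as a table): a candidate with fewer than
`max_hit_organisms` (default 10, strict) such organisms is confirmed;
at or above it, the family is evidently older than the sampled taxa suggest
and is demoted to `unassigned`, keeping the pre-validation call in a
`candidate_node` audit column. Candidates with no hit count are reported as
pending rather than silently passed (`strict = TRUE` demotes them). A third
pass, `core_orthogroup_flags()`, marks families retained in at least half of
*all* species descending from the origin node — the "kept after emergence"
census — which can use a different cutoff than assignment.

## Enrichment statistics

`label_enrichment()` always builds a **disjoint** 2×2 table — novel vs
non-novel crossed with labeled vs unlabeled — even when the labeled census is
published as a fraction of the whole universe (which silently includes the
novel overlap). The disjoint construction is the statistically valid one;
on the bundled example margins (28/139 labeled novel, 882/6681 labeled
overall) both constructions are significant at 0.05, so the choice does not
change the qualitative call there.

`fisher_exact_two_sided()` uses the probability-mass two-sided convention:
conditional on the margins, sum the hypergeometric probability of every table
at most as probable as the observed one (relative tie tolerance 1e-7, the
convention of the common implementations). The enumeration runs in log space,
so large tables (totals in the thousands) lose no precision; the unit tests
hold it to an independent `lchoose` enumeration within 1e-12 and to the
reference implementation in `stats`. Degenerate margins (an empty row or
column) admit a single table and return p = 1. The odds ratio is the sample
ratio *ad/bc*, with 0 and ∞ permitted and `NA` when both products vanish.

`term_enrichment()` is a one-sided hypergeometric test per term, with an
EASE-style mode that decrements the foreground overlap by one before taking
the tail probability — a conservative convention (default flag cutoff 0.1)
that nullifies single-protein overlaps entirely (p = 1). Raw p-values are
reported with an optional Benjamini–Hochberg column; no correction is applied
to the flag by default.

Printed percentages round half *up* (`percent_summary()`), so 12.5 % prints
as 13 %; published summaries that truncate instead (e.g. 65/139 reported as
"~46 %") differ by at most one unit in the last place.

## Interaction connectivity

The interaction graph keeps an explicit node set, so proteins that lose all
edges at the score threshold remain as isolates in every census. Score
filtering is inclusive at the boundary (≥ 0.4 by default, the STRING
convention). Components are reported in a deterministic order (size, then
lexicographically smallest member) so output files are diff-stable.
`edge_enrichment_permutation()` is an explicitly labeled stand-in for
database-internal enrichment models: it samples equal-sized node sets from a
background universe and counts induced edges, returning
(1 + #{perm ≥ obs})/(n_perm + 1), reproducible under its seed. It applies no
degree correction, which database models do; its p-values are therefore
comparable only within one analysis.

## Dual-origin classification

`classify_dual_origin()` reduces a species to the joint presence of two
orthogroups encoding the same function but of different phylogenetic origin
(prokaryote-derived vs eukaryote-derived, e.g. the two dihydroorotate
dehydrogenase families): `both` (coexistence), `prokaryotic_only`
(replacement of the vertical copy by the horizontally acquired one),
`eukaryotic_only`, `neither` (full loss). Which family is the prokaryotic one
is caller-supplied knowledge established upstream by homology searches and
gene trees; the package consumes that conclusion and does no inference of its
own. The per-phylum summary conserves species counts by construction, and
`replacement_count` is simply the `prokaryotic_only` census — no claim is
made about ancestral presence of the eukaryotic copy in each lineage.

## The synthetic-data generator

`simulate_presence()` plants orthogroups at chosen ladder nodes: descendant
species carry the family independently with retention probability *r*
(default 0.9), outside species with noise rate *ε* (default 0.005), and
ubiquitous background families are present everywhere with probability *r*.
Present families carry 1 or 2 copies at random so binarization is exercised.
Per-species independence is a deliberate simplification of branch-correlated
loss: the detection rule only sees marginal per-group fractions, so
independence suffices to exercise every branch of it — but passing tests on
these fixtures say nothing about lineage-specific loss bursts, ancient
paralogy merging families, or annotation quality gradients in real data.
Defaults mirror a realistically uneven sample: seven phyla with 3–8 species
each, two subphyla per terminal phylum, six non-fungal outgroup species.

All generators derive a private substream from the single user seed, so
adding a generator call never perturbs earlier outputs, and each output is
byte-identical under a fixed seed. `simulate_annotations()` realises an exact
2×2 margin; `simulate_ppi()` realises an exact degree ≥ 1 census with planted
internally connected components (random spanning tree plus extra edges) and
dyads for the remainder — an odd remainder joins a planted component, or
forms a triangle when nothing is planted, keeping the census exact.

## Problem sizes and verification

The test suite checks `assign_origin()` against a brute-force evaluator that
re-derives every (orthogroup, node) decision with explicit loops, over 50
random matrices of up to 200 orthogroups × 40 species with randomized
cutoffs and tolerances; recovery experiments use four nested clades of 8
species with 50 planted orthogroups per node over 20 seeds (the noiseless
limit must be recovered exactly); the Fisher test is enumerated independently
for random tables with totals up to 1000. These sizes keep the default suite
in seconds while covering every rule branch; the statistics are
size-independent beyond that.

## Known limitations

* No ancestral-state reconstruction (Dollo or ML gain–loss): the rule is
  threshold-based and reports no uncertainty.
* Origin calls inherit any error in the supplied ladder; only an optional
  monophyly check against a Newick tree (`check_ladder_tree()`) guards it.
* Copy-number variation, sequence evolution and the clustering step that
  produces orthogroups are all upstream of this package.
* The permutation edge-enrichment is not degree-corrected (see above).
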