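---
title: "Scoping semantics, mapping audits and enrichment comparisons with goscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoping semantics, mapping audits and enrichment comparisons with goscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goscope)
```

## The traversal model

goscope models an ontology as a directed graph of terms connected by typed
relation edges, parsed verbatim from OBO 1.2 `is_a` and `relationship` lines.
A *scoping policy* (`scoping_policy()`) declares which relation labels order
terms by generality and, per label, whether the stored edge subject is the
narrower or the broader term. For `is_a` and `part_of` the subject is
narrower, so the stored direction already points toward the root. `has_part`
is stored whole-to-part; treating it axiomatically would either force its
omission (losing mappings) or, if followed blindly, let broad terms map onto
narrow ones and even create directed cycles with `part_of`. The corrected
policy reads each `has_part` edge as `part_of_some` — traversed from its
object (the part) up to its subject (the whole) — so that every scoping edge
points from narrower to broader. The key structural assumption, checked
rather than assumed (`check_acyclic()`), is that the scoped subgraph is a DAG
after this reinterpretation; `ancestors()` and `build_ancestor_map()` refuse
to run on a cyclic scoped subgraph and name an explicit cycle instead.

Two named presets cover the analyses: `"gocats"` = `{is_a, part_of,
has_part-reinterpreted}` and `"no_hp"` = `{is_a, part_of}` (the traditional
map). `"go-basic-scoping"` is the same relation set as `"no_hp"` under a
different provenance label: it denotes emulating a go-basic style graph from
a go-core file. Because the corrected policy only ever adds parent edges,
`no_hp` ancestor sets are entrywise subsets of `gocats` ancestor sets; this
monotonicity is a tested invariant.

Conventions where the field leaves room:

* **Ancestor sets exclude the term itself**; `category_map()` nevertheless
  assigns a root to its own category, matching slim-mapping practice so genes
  annotated directly to a category root still count for it.
* **Obsolete terms** are kept as nodes for bookkeeping but detached from all
  edges and excluded from maps.
* **Cross-namespace scoping edges are traversed by default** (go-core
  contains them); per-namespace restriction is available for per-sub-ontology
  audits.
* **Determinism**: all outputs (maps, pair sets, reports) are sorted, so
  identical inputs give byte-identical files.

## The mapping audit

The audit quantifies two hypothetical failure modes of `has_part` handling.
For one `has_part` edge with whole $w$ and part $p$, the problematic
ancestors and descendants are the set differences

$$PA = (\mathrm{anc}(p) \cup \{p\}) \setminus (\mathrm{anc}(w) \cup \{w\}),
\qquad
PD = (\mathrm{desc}(w) \cup \{w\}) \setminus (\mathrm{desc}(p) \cup \{p\}),$$

and the edge's potential false pairs are the Cartesian product $PD \times
PA$ (self-pairs removed): exactly the specific-to-general mappings the native
whole-to-part direction would wrongly license. The estimated potential false
mappings of a relation, `epM_F`, are the union of these products over its
edges; the true mappings `M_T` are all ordered (descendant, ancestor) pairs
of the corrected graph; `pM_F = epM_F - |M_T ∩ epM_F|` removes coincidentally
valid pairs; and the information lost by dropping the relation is `M_T -
IA_PO_M_T`, where `IA_PO_M_T` is the pair count of the `is_a`/`part_of`-only
graph. One genuinely open choice: the ancestor/descendant sets inside $PA$
and $PD$ are computed over the *corrected* scoping graph, because `pM_F`
intersects the resulting pairs with `M_T` from that same graph; computing
them over `{is_a, part_of}` only is possible by passing that policy
explicitly, for sensitivity analysis.

The blind-mapper emulation (`naive_mapping_pairs()`) follows **every** stored
edge in its subject-to-object direction regardless of label, with visited-set
reachability so cycles are tolerated, and ignores self-mappings. Its error
report counts, per scope, the naive pairs absent from the corrected
whole-graph pair set. Two conventions here were decided from internal
consistency of the published tallies: (i) the error fraction's denominator is
the naive pair count in scope (the alternative ratio over the corrected pair
count is reported alongside as `error_fraction_alt`); (ii) a pair belongs to
a sub-ontology scope only when *both* endpoints carry that namespace, while
the correctness reference is always the whole-graph corrected pair set — this
is the only reading under which a sub-ontology's "correct" count can exceed
its own within-namespace `M_T`, as the published per-sub-ontology tables
require.

## Enrichment and the paired policy comparison

Annotation sets are built from GAF 2.x records (NOT-qualified records
excluded; evidence filtering available but off by default, since the analyses
this package mirrors used all annotations; gene identity is the GAF column-2
object id). `expand_annotations()` unions each gene's terms with their
ancestors under a chosen policy; because ancestor maps are transitively
closed, expansion is idempotent.

`enrich()` tests every term annotated to at least one universe gene with the
one-sided hypergeometric tail $P(X \ge k)$ and adjusts across all tested
terms with Benjamini–Hochberg. The universe defaults to all annotated genes
— the standard over-representation choice; it is configurable, and
unannotated universe genes are dropped with a warning. Significance is
`padj <= alpha` with `alpha = 0.01` by default (the inclusive comparison was
adopted; published wording uses both forms). Depletion is out of scope.

`compare_enrichments()` mirrors the paired-improvement design: restrict to
reference-significant terms, drop exact adjusted-p ties, count terms whose
alternate adjusted p is strictly lower (terms untested in the alternate count
as not improved), and apply the exact one-sided binomial tail at $p = 1/2$ to
(improved, compared). With zero comparable terms the test is undefined and an
error is raised rather than a fabricated p-value. Terms significant on one
side only are reported as unique, not improved.

For two-interval time series, genes are classed as early / late / transient /
consistent by which intervals are significant and whether the fold-change
signs agree; signed variants take the first-interval sign except `late`,
which can only take its sign from the second interval. The derived term sets
are plain set algebra: `early_unique = interval1_gocats - interval1_no_hp -
transient_no_hp` and `early_supported = early_unique ∩ consistent_no_hp`
(late analogously). The "supported" definition admits a second reading with
the full corrected-policy interval set as left operand; both are computed
(`early_supported`, `early_supported_full`) so neither interpretation is
silently imposed.

A note on the binomial reproduction: of the published paired-improvement
p-values this package reproduces, six match the exact one-sided tail to three
significant figures, while the anlagen early comparison (183 of 228) matches
the *two-sided* tail exactly (which at $p = 1/2$ is exactly twice the
one-sided value). `binomial_improvement_test()` therefore exposes a
`two_sided` argument, and both values are reported for that comparison.

## What the synthetic generators emulate

`generate_ontology()` builds namespaced term sets in creation order and draws
scoping edges only from later-created to earlier-created terms — `has_part`
stored in the opposite (whole-to-part) direction per GO convention — so the
corrected scoped subgraph is acyclic by construction while the *stored* edge
set genuinely exercises the reinterpretation. The default relation mix
(0.70 / 0.15 / 0.10 / 0.05 for `is_a` / `part_of` / `has_part` / `regulates`)
echoes the relative ordering of relation frequencies in real GO releases,
with `has_part` deliberately over-represented relative to GO (where it is
below 1%) so that small fixtures contain enough reinterpreted edges to test.
The planted category root is chosen as the term whose scoped descendant set
is closest to 15% of its namespace — large enough to receive annotation mass,
small enough to stay a meaningful category.

`generate_gaf()` annotates background genes uniformly at random (3 direct
annotations per gene by default). The planted odds ratio acts **per
annotation**: each draw of a signal gene lands inside the category with
probability $q$ where $\mathrm{odds}(q) = \mathrm{OR} \cdot \mathrm{odds}(f)$
and $f$ is the category's share of terms. This is the natural reading of an
annotation-level planting and gives the hypergeometric recovery experiment
(odds ratio 8, 30 signal genes in a 300-gene universe) an analytic detection
probability near 0.99 at adjusted $p \le 0.01$ — comfortably above the 95%
the recovery property requires, without being trivially saturated.

`generate_de_table()` plants adjusted p-values strictly below (significant)
or above (non-significant) the threshold with a small guard band, so planted
truth is never boundary-ambiguous, and guarantees nonzero fold changes on
significant rows. The two-contrast mode assigns each gene one of the eight
signed time-series classes or "null" and builds both interval tables to
match.

What the generators do **not** emulate — and hence what passing tests do not
show about real data: realistic GO topology (term-depth and fan-in
distributions, the extreme sparsity of `has_part` in real releases),
annotation biases (evidence-code structure, hub genes, shallow-annotation
bias), correlated p-values from actual count data, and cross-namespace
edges. Conclusions about real GO releases require running the audit on the
pinned release file itself; the test suite contains that audit, gated only on
the presence of the (non-redistributable, ~30 MB) release file.

## Numerical and degenerate-input choices

* Hypergeometric and binomial tails use the exact distribution functions;
  no approximations anywhere in the statistics path.
* BH adjustment is the standard step-up, order-preserving, capped at 1.
* Tie detection in the paired comparison uses exact floating-point equality
  of adjusted p-values — deliberate, since ties arise there from identical
  (k, K, n, N) configurations, not from rounding.
* Empty gene sets, gene sets outside the universe, inconsistent
  hypergeometric counts, a zero fold change on a significant DE row, and a
  zero-comparison binomial test are errors, not silent results; NA adjusted
  p-values and genes present in only one time-series interval are skipped
  with warnings.
* Parsing: duplicate relation triples are deduplicated with a warning;
  unresolved edge targets are dropped onto a `dangling` list; `alt_id`
  aliases are resolved to primary ids before edge validation.

## Problem sizes

The property suites run on 50-seed fixture families of ~75-term ontologies
(three namespaces), 100 enrichment-recovery replicates (300 genes each), and
200 null-calibration replicates (60 genes, one namespace); these sizes make
the brute-force oracles exact and keep the whole suite to a few minutes while
leaving the statistical checks well-powered. The same sizes are used by
`scripts/acceptance.R`.

## Known limitations

* OWL / go-plus inputs are not parsed; OBO 1.2 only.
* Relation correspondence classes beyond the scoping set are metadata only;
  regulatory and spatiotemporal relations are never traversed by scoping
  policies (they are, intentionally, by the blind-mapper emulation).
* GPAD/GPI formats and identifier-mapping services are out of scope.
* The per-term slim-mapper GAF round-trip used to extract a black-box
  mapper's pairs is emulated directly by `naive_mapping_pairs()` (the
  `identity_gaf()` helper is provided for driving external mappers, but no
  external mapper is wrapped).
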