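---
title: "Ontology semantic similarity, enrichment and similarity networks with ontosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology semantic similarity, enrichment and similarity networks with ontosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosim)
```

## The model

Biomedical ontologies — the Gene Ontology, the Human Phenotype Ontology,
the Disease Ontology and their relatives — are directed acyclic graphs of
terms connected by subsumption edges. An annotation corpus attaches
ontology terms to biomedical entities (genes, diseases, phenotypes).
`ontosim` treats both as abstract inputs: any OBO flat file and any
`EntityID<tab>TermID[<tab>EvidenceCode]` corpus define a similarity
structure over terms and entities, and every measure in the package is
computed from that structure alone.

Two modelling rules underlie everything else:

* **Traversal edges are `is_a` and `part_of`.** These are the two
  relations the major bio-ontologies use for subsumption. Other
  relationship types (`regulates`, …) are parsed and retained but take no
  part in ancestor sets, depth, or information content. Each namespace
  must have exactly one root, and cross-namespace comparisons are
  rejected rather than silently returning zero — the three GO
  sub-ontologies, for example, are three separate similarity structures.
* **The true-path rule.** An annotation to a term implies annotation to
  every ancestor of that term. Propagated ("extended") annotation sets
  are the ancestor closures of the direct sets, and all corpus statistics
  count *distinct entities*, never annotation records, so an entity
  reaching an ancestor along two paths (multiple inheritance) is counted
  once. Annotation records are also deduplicated on (entity, term).

### Information content

For a namespace with root `r`, `count(t)` is the number of distinct
entities whose propagated set contains `t`, `p(t) = count(t)/count(r)`
and `IC(t) = -ln p(t)` in nats. The natural logarithm is the package's
fixed choice: the measures built on IC are either scale-invariant
ratios (Lin, Rel, GIC) or are conventionally reported in nats. By
construction `IC(r) = 0` and IC is monotone non-decreasing along every
child-to-parent edge. A term that annotates no entity has *undefined* IC:
measures that need it raise an error naming the term, because a silent
`Inf` propagates NaNs into exported matrices.

### Between-term measures

Eight node-based measures use common ancestors. The MICA family (Resnik,
Lin, Jiang–Conrath, Rel) uses the single common ancestor with maximal IC;
common-ancestor sets are *inclusive* (a term is its own ancestor) so that
self-similarity is well defined and `Lin(t, t) = 1`. The GraSM family
replaces `IC(MICA)` with the arithmetic mean IC over the disjoint common
ancestors — the common ancestors that do not subsume any other common
ancestor. With a single disjoint common ancestor every GraSM variant
collapses onto its base measure, a property the test suite checks on
random fixtures. MICA ties (equal IC) are broken by lexicographically
smallest id so exports are reproducible.

Two points were genuinely open and are fixed as package policy:

* **Jiang–Conrath is a distance**, `IC(t1) + IC(t2) - 2·IC(MICA)`. It is
  mapped to a similarity by `1/(1 + d)` — bounded, monotone and standard
  across GO toolkits.
* **The edge-based pair.** The depth-ratio measure picks the deepest
  common ancestor `a` (ties: smaller summed path length, then smaller id)
  and returns `2·depth(a) / (len(t1,a) + len(t2,a) + 2·depth(a))`; the
  path-length measure returns `1/(1 + d)` with `d` the minimum over
  common ancestors of `len(t1,a) + len(t2,a)`. Both use shortest directed
  path lengths in traversal edges, consistent with their edge-counting
  origin.

The Wang hybrid measure propagates a semantic contribution
`S_t(t) = 1`, `S_t(a) = max over children c of w(rel) · S_t(c)` through
the ancestor subgraph of each term, with per-relation contribution
factors defaulting to the measure's published values 0.8 (`is_a`) and
0.6 (`part_of`), user-overridable. Resnik scores are left unnormalized by
default — they are ICs, in nats — with an optional normalization by the
namespace's maximum IC for `[0, 1]` thresholding.

### Between-entity measures

Pairwise modes (`avg`, `max`, `bma`, `rcmax`) reduce the term-term
matrix between the two *direct* annotation sets. Groupwise graph-based
measures (TO, NTO, UI, LP, GIC) compare *extended* sets, following the
definition of these measures over "annotating terms and their
ancestors". Vector-based measures (cosine, kappa) use binary vectors of
the direct sets over the corpus term universe — the terms actually used
in the corpus, not the whole ontology, since a whole-ontology universe
makes kappa's chance agreement degenerate (both vectors nearly all
zero). Each default can be overridden per call via `annotation_view`.
TO and LP are reported raw (a count and a depth); the network tools can
threshold on any scale, and rescaling before thresholding is left to the
caller so the measure itself is preserved.

### Enrichment

For a query set, candidate terms are every term in the propagated
annotation of at least one query entity, excluding the namespace root
(whose overlap is certain and would always be "significant"). Tests are
one-sided over-representation tests: the hypergeometric upper tail
`P(X ≥ k)` for Fisher's exact test, or the binomial tail with
`p0 = K/N`. The correction multiplicity `m` is the number of candidate
terms actually tested, matching the candidate definition. The background
defaults to all annotated entities in the namespace and can be replaced
by an explicit entity list. Significance is `p_adj ≤ α` with `α = 0.05`
by default.

## Numerical and degenerate-case choices

* `Lin(root, root)` is the 0/0 case and is defined as 1 (identical
  terms); when exactly one argument has IC 0 the MICA is the root and the
  score is 0 without special-casing.
* GIC of two entities whose extended sets are both `{root}` is 1
  (identical sets); sharing *only* the root gives 0 (the numerator is a
  sum of zero ICs).
* Kappa with chance agreement 1 (both entities annotated with the entire
  universe) is defined as 1 when the sets are identical.
* Similarity-network thresholds are inclusive at both ends (`Min`/`Max`
  naming implies a closed window); self-loops in imported edge lists are
  dropped with a warning; undirected edges are stored with
  lexicographically ordered endpoints and sorted, and all TSV scores are
  written with six decimals, so identical runs are byte-identical.
* Set-vs-set similarity reduces the cross entity matrix with the
  best-match average by default — the balanced choice between `avg`
  (diluted by unrelated pairs) and `max` (dominated by one good pair) —
  with the other combiners available behind a flag.
* Evidence-code filtering keeps records that carry no evidence column:
  evidence is an optional annotation attribute, and a filter should not
  silently empty an evidence-free corpus. Annotations to obsolete terms
  are dropped with a warning; obsolete ids remain recognisable through
  the alt-id index.

## What the synthetic fixtures emulate

`make_dag()` grows a single-rooted DAG in topological order (each new
term draws 1–`max_parents` earlier terms as parents, each edge `part_of`
with a configurable probability) and serializes it as OBO text that
round-trips through the parser; `make_corpus()` annotates entities to
uniformly drawn non-root terms. Both are pure functions of their seed, so
every test fixture is reproducible to the byte.

These generators emulate the *structural* properties the measures depend
on — DAG shape, multiple inheritance, mixed edge types, sparse
annotation — and deliberately not the statistics of real ontologies:
power-law branching, depth-correlated annotation density, hierarchical
evidence-code structure. Passing property tests on them therefore
demonstrates correctness of the algorithms (symmetry, bounds,
monotonicity, agreement with brute-force oracles), not biological
validity of any particular measure on GO or HPO.

Test and verification sizes are chosen to make the properties sharp but
cheap: property sweeps run on 200 seeded fixtures of 10 terms and 5
entities, the exhaustive Fisher check enumerates every contingency
configuration up to background size 25, and the correction check runs
1,000 random p-vectors — all against independent oracles (naive DFS/BFS
closures, O(n²) subsumption filters, full-support enumeration, the
direct step-up formula).

## Known limitations

* OBO flat files only; OWL/RDF inputs and GAF/GPAD annotation dialects
  are out of scope.
* IC is corpus-based only; intrinsic (topology-only) IC variants are not
  implemented.
* Enrichment is over-representation only; topology-aware (elim/weight)
  and ranked (GSEA-style) tests are out of scope.
* The Wang measure recomputes S-values per term pair; for very large
  batch jobs a cached or parallel evaluation would be the natural
  extension.
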