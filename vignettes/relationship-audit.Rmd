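---
title: "Auditing subsumption in a ClaML classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing subsumption in a ClaML classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamlkit)
```

## The problem

Health classifications such as ICF are exchanged as ClaML XML and read,
by construction, as subsumption hierarchies: every `SuperClass` link says
"the child is a kind of the parent". For activity concepts this reading
is often wrong. A child may name a *stage* of the parent activity, a
variant distinguished by the *number of agents*, by the *object* acted
on, by the *instrument* used, or by bare task *complexity*. Treating all
of these as is-a confuses classes with their properties and inflates the
hierarchy with subclasses that a formal model would express as process
properties.

clamlkit makes that diagnosis quantitative. It parses the classification,
enumerates its logical parent–child edges, lets a curator (or a cue-based
suggester) assign each edge one of six relationship types, tabulates the
assignments per chapter and per hierarchy level, and renders the result
as summary percentages, as a publishable table, and as an OWL ontology in
which the proposal can be either annotated onto or substituted for the
subsumption axioms. A separate module measures how much of the
classification can be anchored to an upper ontology (SUMO) at all.

## The data model and its invariants

A `classification` is a forest: chapters are roots; blocks, categories
and subcategories hang below them. Hard invariants, checked on
construction and before any serialization: unique codes; mutual
parent/child consistency; exactly one parent per non-root; no cycles;
exactly one preferred rubric per concept. Code shape determines kind
positionally — one digit after the component letter is a chapter, three a
category, four or more a subcategory, `dNNN-dNNN` a block — and the
parser re-kinds any deeper concept as a subcategory regardless of the
file's `kind` attribute, because files in the wild are inconsistent about
the category/subcategory split while the code shape never is.

Two modelling decisions shape everything downstream:

* **Blocks are transparent for edge analysis.** Blocks are groupings of
  consecutive categories, not a coding level: a chapter → block →
  category chain contributes a single logical chapter → category edge,
  and an edge counts as *top*-level iff its effective parent is a
  chapter. OWL export can either keep blocks as classes (faithful to the
  file) or collapse them to `ck:block` annotations (faithful to the
  analysis); annotated export uses the collapsed form so that axioms
  correspond one-to-one to logical edges.
* **Residual classes are excluded before annotation.** "Other specified"
  and "Unspecified" catch-alls carry no relationship information.
  Detection is by title prefix, case-insensitively, because residuals
  are named by title; a stricter mode additionally accepts the `.8`/`.9`
  code-suffix convention, off by default since suffix digits are also
  used by ordinary subcategories.

## Relationship typology and suggestion

The six-way vocabulary is `Subsumption` plus four process predicates
taken from the upper ontology — `SubProcess` (stages), `Agent` (number of
participants), `Patient` (object involved), `Instrument` (tool/means) —
and `Complexity`, which has no upper-ontology counterpart and is flagged
as such; in OWL it is only ever an annotation with values
`simple`/`complex`, never an object property.

Each edge carries exactly one relation. Curated TSV tables are the
primary input; `suggest_relationship()` is advisory only, driven by an
editable regex lexicon over child titles
(`inst/extdata/relation_lexicon.tsv`). When several cues fire, precedence
is SubProcess > Agent > Patient > Instrument > Complexity — stage cues
("starting …") are more specific than participant-count cues ("… with one
person"), which beat the weaker object/instrument/complexity vocabulary.
The lexicon ships as data, not code, because the underlying criteria are
semantic and any word list is an approximation a curator should be able
to edit.

## Statistics

`tabulate_relationships()` produces one row per (chapter, level) with a
count per relation; the chapter is derived from the edge's codes, which
must agree between parent and child. `summarize_relationships()` then
reports, as integer percentages: top-level subsumption share, lower-level
non-subsumption share, the same per chapter, the chapters where
non-subsumption is the strict majority (> 1/2; an exact tie does not
qualify), and the chapters that rely on subsumption for every edge.

Numerical choices:

* **Rounding is half-away-from-zero** (`round_half_away()`), not base R's
  banker's rounding. The package's fixture percentages (90, 41, 93, 56,
  100) all reproduce under this rule, and 92.86 → 93 would fail under
  `round()` only for half-values, but the rule is fixed once rather than
  matched per case.
* **Zero denominators are "undefined"**, surfaced as `NA` / the JSON
  string `"undefined"`, never as 0%: a chapter with no lower-level edges
  has no lower-level subsumption share.
* Row totals are always recomputed from relation counts, and the Total
  row from chapter rows; stored totals are never trusted (the count-table
  TSV does not even have a place for them).

## OWL export

Class IRIs are `<base>#<code>`: codes are unique, stable and short, so
nothing better is available and round-tripping is trivial. Rubrics become
annotations (`rdfs:label` for the preferred title; distinct properties
for definition/inclusion/exclusion/coding-hint). Exclusions are *not*
translated into `owl:disjointWith`: an exclusion note is a coding
instruction, not a logical claim.

Two export modes reflect that the reformed model is a proposal, not a
commitment. The default keeps every hierarchy edge as a subclass axiom
and adds `ck:proposedRelation` annotations — monotone, so consumers lose
nothing. Strict mode operationalizes the proposal: a non-subsumption edge
loses its subclass axiom and the child instead gets
`rdfs:subClassOf [ owl:onProperty ck:<relation> ; owl:someValuesFrom
<parent> ]` (or a `ck:complexity` annotation). Upper-ontology mappings
are exported as SKOS match annotations (`broadMatch` / `exactMatch` /
`relatedMatch` for broader/equivalent/partial), never as cross-ontology
subclass axioms, because the mappings are tentative by nature.

Serialization is deterministic (classes sorted by code) in RDF/XML and
Turtle. No RDF library is available in the target environment, so the
package carries its own independent re-parser (`owl_triples()`) for
exactly the syntax subset the writers emit, plus blank-node-canonical
graph comparison (`graphs_isomorphic()`); the test suite uses it to check
class-count conservation and cross-dialect isomorphism. The re-parser
shares no code with the writers, which is what makes those tests
meaningful; it is *not* a general RDF parser.

## The synthetic generator

`make_synthetic_classification()` emulates the *structure* of a ClaML
classification: chapter/block/category/subcategory counts, code shapes,
residual titles at a per-sibling-group fraction (rounded down; the last
group member becomes "Unspecified", earlier residuals "Other specified
…"), and deterministic output bytes for fixed parameters. It does not
imitate real textual definitions, realistic title vocabulary, or the
skewed per-chapter size distribution of real classifications —
`icf_shape_params()` reproduces the published level totals (9 chapters,
18 blocks, 118 categories, 266 subcategories) but spreads them evenly
across chapters, because the per-chapter breakdown is not part of the
encoded tables. A green round-trip or conservation test therefore
establishes structural correctness of the I/O and export paths, not
fidelity to any real classification's content.

`make_synthetic_annotations()` draws one relation per non-residual edge
i.i.d. from a stated distribution under `withr::with_seed`, so annotation
sets are reproducible and the tabulated frequencies can be tested against
binomial standard errors (the suite uses a 3·SE band).

## Degenerate inputs and edge cases

* Empty ClaML documents parse to an empty classification; validation
  reports "no chapters" as an advisory, not an error.
* An all-zero count table refuses to summarize ("empty report") rather
  than emit 0/0 percentages.
* Duplicate codes, duplicate edge annotations, duplicate
  (source, target) mapping pairs, unknown relation names and unknown
  match kinds are all hard errors at load time, with the legal
  vocabulary in the message.
* Annotations referring to edges that do not exist in the classification
  are integrity errors in both the loader (when a classification is
  supplied) and the annotated exporter.
* Mapping sources absent from the classification are errors by default
  and warnings under the lenient flag, since audit tables often outlive
  classification versions.

## Known limitations

* The packaged relationship counts are *counts*, not per-edge
  assignments: the underlying edge-by-edge analysis exists only
  graphically upstream, so per-edge ground truth cannot be packaged and
  edge-level conclusions can only be tested on synthetic or curated
  data.
* Only four chapter-wide and a handful of block/category mappings are
  stated in prose upstream; the packaged mapping fixtures encode exactly
  those, so block/category/subcategory coverage of the full published
  mapping (11/18, 22/118, 21/266) is reproducible only from a user's
  complete mapping table.
* The Turtle/RDF-XML readers cover the emitted subset only; they are an
  oracle for this package's writers, not a general-purpose RDF stack.
* Parsing the real, full ICF ClaML export is supported in principle
  (the dialect accepts WHO-FIC ClaML) but untested here, since the file
  cannot be redistributed and the environment is offline; level totals
  there are subject to version drift.
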