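# clamlkit

Tools for auditing the hierarchy of WHO-family health classifications
distributed in **ClaML** (Classification Markup Language), with the ICF
*Activities and Participation* component (codes `d1`–`d9`) as the worked
case.

Classifications like ICF present every parent–child link as subsumption
(is-a). In practice many links encode something else: a *stage* of the
parent activity ("Starting a conversation" under "Conversation"), the
*number of agents* involved ("Discussion with one person" vs. "with many
people"), the *object* acted on, the *instrument* used, or a plain
simple-vs-complex contrast. clamlkit supports the whole audit workflow:

- **ClaML I/O** — parse ClaML XML into a typed in-memory model (chapters,
  blocks, categories, subcategories; rubrics; residual-class detection),
  validate its invariants, and write it back losslessly.
- **Edge annotation** — a six-way relationship vocabulary over
  parent–child edges (`Subsumption`, `SubProcess`, `Agent`, `Patient`,
  `Instrument`, `Complexity`; the middle four are the standard upper
  ontology's process predicates), TSV load/store, and rule-based
  suggestions from lexical cues in titles.
- **Statistics** — per-chapter, per-level tabulation of relationship
  usage, and summary percentages: for each (chapter, level) cell with
  Subsumption count *s* and total *t*, the "other" share is
  100·(t−s)/t, rounded half-away-from-zero; chapters with t = 0 are
  *undefined*, never 0%.
- **OWL export** — RDF/XML or Turtle, either non-destructive (hierarchy
  kept, proposed relations as annotations) or strict (non-subsumption
  edges become existential restrictions on declared object properties).
- **Upper-ontology mapping coverage** — load code→SUMO-concept mapping
  tables, compute mapped/total per level, export SKOS match annotations.
- **Synthetic generator** — deterministic ClaML classifications and
  annotation sets of any shape, for property-based testing.

Packaged fixtures encode the published chapter list, the full
relationship count table for Activities and Participation, and the
chapter/block/category mappings to SUMO, so everything runs offline.

## Worked example

```r
library(clamlkit)
tab <- read_count_table(system.file("extdata", "table2_counts.tsv",
                                    package = "clamlkit"))
summarize_relationships(tab)
```

```
Relationship usage summary
  top-level subsumption:        90% (88/98)
  lower-level non-subsumption:  41% (72/175)
  per-chapter lower non-subsumption:
    d1: 100%
    d2: 93%
    d3: 100%
    d4: 34%
    d5: 11%
    d6: 8%
    d7: 56%
    d8: 38%
    d9: 0%
  majority non-subsumption chapters: d1 d2 d3 d7 
  all-subsumption chapters: d9 
```

Reading: at the top level (chapter → category) 90% of links really are
subsumption, but one level down 41% of links encode something else, and
in four chapters (d1, d2, d3, d7) the non-subsumption links are the
majority; only d9 uses pure subsumption throughout.

Mapping coverage against the nine-chapter list:

```r
maps <- read_mappings(system.file("extdata", "chapter_mappings.tsv",
                                  package = "clamlkit"))
chapters <- read.delim(system.file("extdata", "table1_chapters.tsv",
                                   package = "clamlkit"), comment.char = "#")
mapping_coverage(maps, chapters)
#> Upper-ontology mapping coverage
#>   chapter      4/9
#>   ...
#>   unmapped codes: d1 d3 d7 d8 d9
```

Strict OWL export of the packaged Conversation/Discussion extract:

```r
cl  <- read_claml(system.file("extdata", "conversation_subtree.xml",
                              package = "clamlkit"))
ann <- suggest_annotations(cl)   # 3 SubProcess + 2 Agent under d350, etc.
doc <- to_owl_annotated(cl, ann, mode = "strict")
write_owl(doc, "conversation.ttl", dialect = "turtle")
```

## Command line

```sh
Rscript inst/scripts/clamlkit stats --counts inst/extdata/table2_counts.tsv --format json
Rscript inst/scripts/clamlkit coverage --mappings inst/extdata/chapter_mappings.tsv \
        --levels inst/extdata/table1_chapters.tsv
Rscript inst/scripts/clamlkit convert --input mycls.xml --dialect turtle \
        --annotations edges.tsv --strict-relations
Rscript inst/scripts/clamlkit synth --chapters 3 --categories 4 --subcategories 2
```

Exit codes: 0 success, 1 validation/input failure, 2 usage error. Logs go
to stderr, data to stdout or `--output`.

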