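test_that("an empty classification exports to a header-only ontology", {
  doc <- to_owl(classification(name = "empty", version = "0"))
  for (dialect in c("rdfxml", "turtle")) {
    t <- owl_triples(write_owl(doc, dialect = dialect), dialect)
    expect_identical(n_of_type(t, "Class"), 0L)
    expect_identical(n_of_type(t, "Ontology"), 1L)
  }
})

test_that("a 3-concept chain yields 3 class declarations and 2 subclass axioms on re-parse", {
  doc <- to_owl(chain_classification())
  for (dialect in c("rdfxml", "turtle")) {
    t <- owl_triples(write_owl(doc, dialect = dialect), dialect)
    expect_identical(n_of_type(t, "Class"), 3L)
    expect_identical(n_named_subclass(t), 2L)
  }
})

test_that("rubric annotations are carried one-to-one into the export", {
  cl <- block_classification()   # d450 has 2 inclusion + 1 exclusion rubrics
  doc <- to_owl(cl)
  t <- owl_triples(write_owl(doc, dialect = "rdfxml"), "rdfxml")
  base <- "http://example.org/clamlkit/classification#"
  d450 <- paste0(base, "d450")
  rub <- t[t$s == d450 &
             t$p %in% paste0(base, c("inclusion", "exclusion")), ]
  expect_identical(nrow(rub), 3L)
  expect_identical(sum(endsWith(rub$p, "inclusion")), 2L)
  # labels come from the preferred rubric
  expect_true(any(t$s == d450 & t$lit & t$o == "Walking"))
})

test_that("class-count conservation holds under residual/block options", {
  cl <- block_classification()
  n_all <- length(cl$concepts)
  n_res <- sum(vapply(cl$concepts, `[[`, logical(1), "residual"))
  n_blk <- sum(vapply(cl$concepts, function(k) k$kind == "block", logical(1)))
  count <- function(doc)
    n_of_type(owl_triples(write_owl(doc, dialect = "turtle"), "turtle"),
              "Class")
  expect_identical(count(to_owl(cl)), n_all)
  expect_identical(count(to_owl(cl, include_residuals = FALSE)),
                   n_all - n_res)
  expect_identical(count(to_owl(cl, blocks = "annotation")), n_all - n_blk)
  # block membership survives as an annotation when blocks are collapsed
  t <- owl_triples(write_owl(to_owl(cl, blocks = "annotation"),
                             dialect = "turtle"), "turtle")
  expect_identical(sum(t$lit & t$o == "d450-d469"), 2L)
})

test_that("RDF/XML and Turtle serializations re-parse to isomorphic graphs", {
  cl <- conversation_fixture()
  ann <- suggest_annotations(cl)
  for (doc in list(to_owl(cl),
                   to_owl_annotated(cl, ann),
                   to_owl_annotated(cl, ann, mode = "strict"))) {
    t1 <- owl_triples(write_owl(doc, dialect = "rdfxml"), "rdfxml")
    t2 <- owl_triples(write_owl(doc, dialect = "turtle"), "turtle")
    expect_true(graphs_isomorphic(t1, t2))
  }
})

test_that("an all-Subsumption annotation set leaves the export unchanged", {
  cl <- chain_classification()
  e <- classification_edges(cl)
  ann <- edge_annotations(e$parent, e$child,
                          rep("Subsumption", nrow(e)))
  plain <- write_owl(to_owl(cl, blocks = "annotation"), dialect = "turtle")
  annotated <- write_owl(to_owl_annotated(cl, ann), dialect = "turtle")
  expect_true(graphs_isomorphic(owl_triples(plain, "turtle"),
                                owl_triples(annotated, "turtle")))
})

test_that("default annotated mode is non-destructive: axioms kept, one annotation per non-subsumption edge", {
  cl <- conversation_fixture()
  ann <- suggest_annotations(cl)
  n_nonsub <- sum(ann$relation != "Subsumption")
  t_plain <- owl_triples(write_owl(to_owl(cl, blocks = "annotation"),
                                   dialect = "rdfxml"), "rdfxml")
  t_ann <- owl_triples(write_owl(to_owl_annotated(cl, ann),
                                 dialect = "rdfxml"), "rdfxml")
  expect_identical(n_named_subclass(t_ann), n_named_subclass(t_plain))
  prop <- "http://example.org/clamlkit/classification#proposedRelation"
  expect_identical(sum(t_ann$p == prop), n_nonsub)
  # monotonicity: every plain triple is still present
  key <- function(t) paste(t$s, t$p, t$o, t$lit)
  expect_true(all(key(t_plain) %in% key(t_ann)))
})

test_that("strict mode swaps non-subsumption axioms for restrictions (published 3+2 example)", {
  cl <- conversation_fixture()
  ann <- suggest_annotations(cl)
  # the Conversation category: 3 SubProcess + 2 Agent children
  under <- ann[ann$parent == "d350", ]
  expect_identical(nrow(under), 5L)
  doc <- to_owl_annotated(cl, ann, mode = "strict")
  t <- owl_triples(write_owl(doc, dialect = "rdfxml"), "rdfxml")
  t_plain <- owl_triples(write_owl(to_owl(cl, blocks = "annotation"),
                                   dialect = "rdfxml"), "rdfxml")
  n_nonsub <- sum(ann$relation != "Subsumption")
  expect_identical(n_named_subclass(t_plain) - n_named_subclass(t),
                   n_nonsub)
  expect_identical(n_of_type(t, "Restriction"), n_nonsub)
  base <- "http://example.org/clamlkit/classification#"
  on_prop <- t[t$p == "http://www.w3.org/2002/07/owl#onProperty", "o"]
  expect_identical(sum(on_prop == paste0(base, "subProcess")), 3L)
  expect_identical(sum(on_prop == paste0(base, "agent")), 4L)
})

test_that("annotations for nonexistent edges are rejected", {
  cl <- chain_classification()
  ann <- edge_annotations("d1", "d1100", "Agent")  # skips a level
  expect_error(to_owl_annotated(cl, ann), "nonexistent edge")
})

test_that("IRI-hostile codes are refused", {
  cl <- classification(list(
    concept("d 1", "chapter", rubric("preferred", "Bad code"))))
  expect_error(to_owl(cl), "IRI")
})
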