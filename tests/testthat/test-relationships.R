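test_that("the relationship vocabulary has exactly six values and flags Complexity", {
  types <- relationship_types()
  expect_length(types, 6)
  uo <- attr(types, "upper_ontology")
  expect_false(uo[types == "Complexity"])
  expect_true(all(uo[types != "Complexity"]))
})

test_that("edge enumeration makes blocks transparent and drops residual children", {
  cl <- block_classification()
  e <- classification_edges(cl)
  # chapter -> block -> category collapses to one logical chapter -> category
  expect_true(all(e$parent != "d450-d469"))
  expect_true(all(e$child != "d450-d469"))
  expect_identical(e$level[e$parent == "d4"], rep("top", 2))
  expect_identical(e$level[e$parent == "d450"], "lower")
  expect_false("d4508" %in% e$child)           # residual excluded
  er <- classification_edges(cl, include_residual = TRUE)
  expect_true("d4508" %in% er$child)
  # forest property on the raw hierarchy: edges = concepts - roots
  raw_edges <- sum(!vapply(cl$concepts, function(k) is.na(k$parent),
                           logical(1)))
  expect_identical(raw_edges, length(cl$concepts) - length(cl$roots))
})

test_that("annotation TSV loading parses relations case-insensitively and validates", {
  expect_length(read_annotations(character())$parent, 0)
  ann <- read_annotations(c("# comment", "d355\td3550\tagent\t"))
  expect_identical(ann$relation, "Agent")
  expect_error(read_annotations("d355\td3550\tHasPart"),
               "Subsumption.*SubProcess.*Agent.*Patient.*Instrument.*Complexity")
  expect_error(
    read_annotations(c("d355\td3550\tAgent", "d355\td3550\tPatient")),
    "duplicate")
  cl <- conversation_fixture()
  expect_error(read_annotations("d355\td9999\tAgent", cl), "nonexistent")
})

test_that("annotation round trip through TSV preserves the tabulation", {
  cl <- conversation_fixture()
  ann <- suggest_annotations(cl)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, tmp)
  back <- read_annotations(tmp, cl)
  expect_identical(tabulate_relationships(back), tabulate_relationships(ann))
})

test_that("suggestions follow the cue lexicon with the documented precedence", {
  expect_identical(suggest_relationship("Discussion", "Discussion with one person"),
                   "Agent")
  expect_identical(suggest_relationship("Discussion", "Discussion with many people"),
                   "Agent")
  expect_identical(suggest_relationship("Tasks", "Undertaking a simple task"),
                   "Complexity")
  expect_identical(suggest_relationship("Tasks", "Undertaking a complex task"),
                   "Complexity")
  expect_identical(suggest_relationship("Conversation", "Starting a conversation"),
                   "SubProcess")
  # no cue -> NA (caller defaults to Subsumption)
  expect_identical(suggest_relationship("Walking and moving", "Walking"),
                   NA_character_)
  # precedence: a subprocess cue beats an agent cue in the same title
  expect_identical(
    suggest_relationship("x", "Starting a conversation with one person"),
    "SubProcess")
})

test_that("suggest_annotations covers every logical edge exactly once", {
  cl <- conversation_fixture()
  ann <- suggest_annotations(cl)
  e <- classification_edges(cl)
  expect_identical(nrow(ann), nrow(e))
  expect_setequal(paste(ann$parent, ann$child), paste(e$parent, e$child))
  # the published example children: 3 SubProcess + 2 Agent under d350
  under <- ann[ann$parent == "d350", ]
  expect_identical(sum(under$relation == "SubProcess"), 3L)
  expect_identical(sum(under$relation == "Agent"), 2L)
})

test_that("tabulation counts by chapter and level, with hand-counted cells", {
  ann <- edge_annotations(
    parent = c("d5", "d510", "d510"),
    child = c("d510", "d5100", "d5101"),
    relation = c("Subsumption", "Patient", "Patient"))
  tab <- tabulate_relationships(ann)
  d5top <- tab[tab$chapter == "d5" & tab$level == "top", ]
  d5low <- tab[tab$chapter == "d5" & tab$level == "lower", ]
  expect_identical(d5top$total, 1L)
  expect_identical(d5low$total, 2L)
  expect_identical(d5top$Subsumption, 1L)
  expect_identical(d5top$Patient, 0L)
  expect_identical(d5low$Patient, 2L)
  expect_identical(d5low$Subsumption, 0L)
})

test_that("tabulation rejects edges whose codes disagree on chapter", {
  ann <- edge_annotations("d5", "d610", "Subsumption")
  expect_error(tabulate_relationships(ann), "disagree on chapter")
})

test_that("empty annotation lists give an all-zero table", {
  tab <- tabulate_relationships(edge_annotations(), chapters = "d1")
  expect_identical(sum(tab$total), 0L)
  expect_identical(nrow(tab), 2L)  # top + lower rows for d1
})

test_that("row and column consistency hold for the encoded published table", {
  tab <- table2_fixture()
  validate_relation_table(tab)   # row totals = sum over relations
  types <- relationship_types()
  tot <- relation_table_totals(tab)
  for (lv in c("top", "lower")) {
    rows <- tab[tab$level == lv, types]
    expect_identical(unname(colSums(rows)),
                     unname(as.numeric(tot[tot$level == lv, types])))
  }
})

test_that("count-table TSV round trips", {
  tab <- table2_fixture()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, tmp)
  expect_identical(read_count_table(tmp), tab)
})
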