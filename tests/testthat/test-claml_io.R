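test_that("an empty ClaML document parses to an empty classification", {
  xml <- "<ClaML version=\"2.0.0\"><Title name=\"empty\" version=\"0\"/></ClaML>"
  cl <- read_claml(xml)
  expect_length(cl$concepts, 0)
  expect_match(validate_classification(cl), "no chapters", all = FALSE)
})

test_that("a synthetic chapter/category/subcategory document parses to the hand-built model", {
  expected <- chain_classification()
  xml <- paste0(
    "<ClaML version=\"2.0.0\"><Title name=\"chain\" version=\"1.0\"/>",
    "<Class code=\"d1\" kind=\"chapter\">",
    "<Rubric kind=\"preferred\"><Label>Learning</Label></Rubric></Class>",
    "<Class code=\"d110\" kind=\"category\"><SuperClass code=\"d1\"/>",
    "<Rubric kind=\"preferred\"><Label>Watching</Label></Rubric></Class>",
    "<Class code=\"d1100\" kind=\"category\"><SuperClass code=\"d110\"/>",
    "<Rubric kind=\"preferred\"><Label>Watching closely</Label></Rubric>",
    "</Class></ClaML>")
  cl <- read_claml(xml)
  expect_length(cl$concepts, 3)
  expect_identical(cl$roots, "d1")
  # file said kind="category" for the 4-digit code; parser re-kinds it
  expect_identical(cl$concepts[["d1100"]]$kind, "subcategory")
  expect_true(classification_identical(cl, expected))
})

test_that("parse errors are reported: malformed XML, duplicate codes, cycles, multiple parents", {
  expect_error(read_claml("<ClaML><unclosed></ClaML>"), "parse error")
  dup <- paste0(
    "<ClaML version=\"2.0.0\">",
    "<Class code=\"d1\" kind=\"chapter\">",
    "<Rubric kind=\"preferred\"><Label>A</Label></Rubric></Class>",
    "<Class code=\"d1\" kind=\"chapter\">",
    "<Rubric kind=\"preferred\"><Label>B</Label></Rubric></Class></ClaML>")
  expect_error(read_claml(dup), "duplicate code")
  cyc <- paste0(
    "<ClaML version=\"2.0.0\">",
    "<Class code=\"d110\" kind=\"category\"><SuperClass code=\"d120\"/>",
    "<Rubric kind=\"preferred\"><Label>A</Label></Rubric></Class>",
    "<Class code=\"d120\" kind=\"category\"><SuperClass code=\"d110\"/>",
    "<Rubric kind=\"preferred\"><Label>B</Label></Rubric></Class></ClaML>")
  expect_error(read_claml(cyc), "cycle")
  multi <- paste0(
    "<ClaML version=\"2.0.0\">",
    "<Class code=\"d110\" kind=\"category\">",
    "<SuperClass code=\"d1\"/><SuperClass code=\"d2\"/>",
    "<Rubric kind=\"preferred\"><Label>A</Label></Rubric></Class></ClaML>")
  expect_error(read_claml(multi), "exactly one parent")
})

test_that("write_claml round-trips structure and rubric counts", {
  for (cl in list(chain_classification(), block_classification(),
                  conversation_fixture())) {
    back <- read_claml(write_claml(cl))
    expect_true(classification_identical(cl, back))
    n_rub <- function(x) sum(vapply(x$concepts, function(k)
      length(k$rubrics), integer(1)))
    expect_identical(n_rub(back), n_rub(cl))
  }
  # empty classification gives a minimal valid skeleton
  empty <- classification(name = "empty", version = "0")
  expect_length(read_claml(write_claml(empty))$concepts, 0)
})

test_that("write_claml refuses an invariant-violating model before output", {
  bad <- chain_classification()
  bad$concepts[["d110"]]$parent <- "d9"   # dangling parent
  expect_error(write_claml(bad), "integrity")
})

test_that("residual detection is title-based, with an optional strict code mode", {
  expect_true(is_residual_title("Other specified self-care"))
  expect_true(is_residual_title("Unspecified"))
  expect_true(is_residual_title("unspecified walking"))
  expect_false(is_residual_title("Walking"))
  expect_false(is_residual_title("Brother specified"))
  walk <- concept("d4509", "subcategory", rubric("preferred", "Walking, other"))
  expect_false(detect_residual(walk))
  expect_true(detect_residual(walk, strict = TRUE))  # .9 suffix heuristic
  expect_false(detect_residual(
    concept("d4501", "subcategory", rubric("preferred", "Walking, other")),
    strict = TRUE))
})

test_that("classify_code handles chapters, categories, subcategories and block ranges", {
  r <- classify_code("d3550")
  expect_identical(r$component, "d")
  expect_identical(r$chapter, "d3")
  expect_identical(r$kind, "subcategory")
  expect_identical(r$depth, 4L)
  b <- classify_code("d450-d469")
  expect_identical(b$kind, "block")
  expect_identical(b$chapter, "d4")
  ch <- classify_code("d1")
  expect_identical(ch$kind, "chapter")
  expect_identical(ch$depth, 1L)
  expect_error(classify_code("470"), "unparseable")
  expect_error(classify_code("d45"), "unparseable")
  expect_error(classify_code("d450-e469"), "unparseable")
})

test_that("flat TSV export/import preserves codes, kinds, links and residual flags", {
  cl <- block_classification()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_classification_tsv(cl, tmp)
  back <- read_classification_tsv(tmp)
  a <- as.data.frame(cl); b <- as.data.frame(back)
  expect_identical(a[order(a$code), ], b[order(b$code), ])
})

test_that("rubrics with unknown kinds are kept as 'other' with the original kind noted", {
  r <- rubric("footnote", "some text")
  expect_identical(r$kind, "other")
  expect_match(r$note, "footnote")
  expect_error(rubric("preferred", ""), "non-empty")
})
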