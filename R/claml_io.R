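#' Read a ClaML classification document
#'
#' Parses a ClaML (Classification Markup Language) XML document into a
#' [classification()]. Every `Class` element becomes one concept;
#' `SuperClass`/`SubClass` elements populate the hierarchy links; `Rubric`
#' elements populate the rubrics. Class kinds are taken from the `kind`
#' attribute where present and inferred from the code shape otherwise;
#' concepts with codes deeper than three digits are re-kinded
#' `"subcategory"` regardless of the file's attribute, so the
#' category/subcategory split is purely positional.
#'
#' @param x Path to a ClaML file, or a single string of ClaML XML.
#' @return A `classification`.
#' @examples
#' cl <- read_claml(system.file("extdata", "conversation_subtree.xml",
#'                              package = "clamlkit"))
#' cl
#' @export
read_claml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x, encoding = "UTF-8"),
    error = function(e) stop("ClaML parse error: ", conditionMessage(e),
                             call. = FALSE))
  root <- xml2::xml_name(doc)
  if (root != "ClaML")
    stop("ClaML parse error: root element is <", root, ">, expected <ClaML>",
         call. = FALSE)
  title <- xml2::xml_find_first(doc, "./Title")
  name <- if (inherits(title, "xml_missing")) "classification"
          else xml2::xml_attr(title, "name")
  version <- if (inherits(title, "xml_missing")) "1.0"
             else xml2::xml_attr(title, "version")
  if (is.na(name)) name <- "classification"
  if (is.na(version)) version <- "1.0"

  cls <- xml2::xml_find_all(doc, "./Class")
  codes <- xml2::xml_attr(cls, "code")
  if (anyNA(codes)) stop("ClaML integrity error: Class without code attribute",
                         call. = FALSE)
  if (anyDuplicated(codes))
    stop("ClaML integrity error: duplicate code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)

  parents <- stats::setNames(rep(NA_character_, length(codes)), codes)
  children <- stats::setNames(vector("list", length(codes)), codes)
  kinds <- stats::setNames(xml2::xml_attr(cls, "kind"), codes)
  rubrics <- stats::setNames(vector("list", length(codes)), codes)

  for (i in seq_along(cls)) {
    cd <- codes[i]
    sup <- xml2::xml_attr(xml2::xml_find_all(cls[[i]], "./SuperClass"), "code")
    if (length(sup) > 1L)
      stop("ClaML integrity error: ", cd, " declares ", length(sup),
           " SuperClass elements (exactly one parent allowed)", call. = FALSE)
    if (length(sup) == 1L) parents[cd] <- sup
    sub <- xml2::xml_attr(xml2::xml_find_all(cls[[i]], "./SubClass"), "code")
    children[[cd]] <- sub
    rub <- xml2::xml_find_all(cls[[i]], "./Rubric")
    rubrics[[cd]] <- lapply(rub, function(r) {
      kind <- xml2::xml_attr(r, "kind")
      lab <- xml2::xml_find_first(r, "./Label")
      txt <- if (inherits(lab, "xml_missing")) xml2::xml_text(r)
             else xml2::xml_text(lab)
      rubric(if (is.na(kind)) "other" else kind, trimws(txt))
    })
  }
  # children also derivable from SuperClass links, preserving document order
  for (cd in codes) {
    p <- parents[[cd]]
    if (!is.na(p) && p %in% codes && !cd %in% children[[p]])
      children[[p]] <- c(children[[p]], cd)
  }

  concepts <- lapply(codes, function(cd) {
    kind <- kinds[[cd]]
    inferred <- tryCatch(classify_code(cd)$kind, error = function(e) NA_character_)
    if (is.na(kind) || !kind %in% CONCEPT_KINDS)
      kind <- if (is.na(inferred)) "category" else inferred
    # positional re-kinding: anything deeper than 3 digits is a subcategory
    if (!is.na(inferred) && inferred == "subcategory") kind <- "subcategory"
    rubs <- rubrics[[cd]]
    if (!length(rubs) || !any(vapply(rubs, function(r) r$kind == "preferred",
                                     logical(1))))
      stop("ClaML integrity error: ", cd, " has no preferred rubric",
           call. = FALSE)
    concept(cd, kind, rubs, parent = parents[[cd]],
            children = children[[cd]])
  })
  classification(concepts, name = name, version = version)
}

#' Write a classification as ClaML
#'
#' Serializes a [classification()] to ClaML XML. The output re-parses (via
#' [read_claml()]) to a classification structurally equal to the input:
#' codes, kinds, rubrics and hierarchy links round-trip. Invariants are
#' checked before any output is produced.
#'
#' @param x A `classification`.
#' @param path Optional file path; when `NULL` the XML is returned as a
#'   string.
#' @return The XML text (invisibly when written to `path`).
#' @export
write_claml <- function(x, path = NULL) {
  stopifnot(inherits(x, "classification"))
  issues <- validate_classification(x)
  if (length(attr(issues, "fatal")))
    stop("integrity error: ", paste(attr(issues, "fatal"), collapse = "; "),
         call. = FALSE)
  doc <- xml2::xml_new_root("ClaML", version = "2.0.0")
  xml2::xml_add_child(doc, "Title", name = x$name, version = x$version)
  for (cd in names(x$concepts)) {
    k <- x$concepts[[cd]]
    cls <- xml2::xml_add_child(doc, "Class", code = k$code, kind = k$kind)
    if (!is.na(k$parent))
      xml2::xml_add_child(cls, "SuperClass", code = k$parent)
    for (ch in k$children)
      xml2::xml_add_child(cls, "SubClass", code = ch)
    for (r in k$rubrics) {
      rn <- xml2::xml_add_child(cls, "Rubric", kind = r$kind)
      xml2::xml_add_child(rn, "Label", r$text)
    }
  }
  out <- as.character(doc)
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Structural equality of classifications
#'
#' Two classifications are structurally equal when they contain the same
#' codes with the same kinds, parents, child orders, residual flags and
#' rubric (kind, text) sequences. Name/version metadata is compared too.
#'
#' @param a,b `classification` objects.
#' @return Logical.
#' @export
classification_identical <- function(a, b) {
  if (!setequal(names(a$concepts), names(b$concepts))) return(FALSE)
  if (!identical(a$name, b$name) || !identical(a$version, b$version))
    return(FALSE)
  for (cd in names(a$concepts)) {
    ka <- a$concepts[[cd]]; kb <- b$concepts[[cd]]
    if (!identical(ka$kind, kb$kind)) return(FALSE)
    if (!identical(ka$parent, kb$parent)) return(FALSE)
    if (!identical(ka$children, kb$children)) return(FALSE)
    if (!identical(ka$residual, kb$residual)) return(FALSE)
    ra <- lapply(ka$rubrics, function(r) c(r$kind, r$text))
    rb <- lapply(kb$rubrics, function(r) c(r$kind, r$text))
    if (!identical(ra, rb)) return(FALSE)
  }
  TRUE
}
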