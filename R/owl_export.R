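NS <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  skos = "http://www.w3.org/2004/02/skos/core#"
)

DEFAULT_BASE <- "http://example.org/clamlkit/classification"
SUMO_BASE <- "http://www.ontologyportal.org/SUMO.owl"

expand_curie <- function(x, base) {
  ns <- c(NS, ck = paste0(base, "#"))
  vapply(x, function(v) {
    if (grepl("^https?://", v)) return(v)
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% names(ns))
      paste0(ns[[parts[1]]], parts[2])
    else v
  }, character(1), USE.NAMES = FALSE)
}

#' Construct an (empty) ontology document
#'
#' The in-memory form of an OWL rendering: class declarations, subclass
#' axioms, annotation assertions, object/annotation property declarations
#' and existential restrictions. Class IRIs are `<base>#<code>`; custom
#' property IRIs live in the same namespace (curie prefix `ck:`), plus the
#' standard `rdfs:`/`skos:` vocabularies.
#'
#' @param base Ontology IRI (also the namespace of class and custom
#'   property IRIs).
#' @return An object of class `ontology_document`.
#' @export
ontology_document <- function(base = DEFAULT_BASE) {
  structure(list(
    base = base,
    classes = data.frame(code = character(), label = character(),
                         stringsAsFactors = FALSE),
    subclass = data.frame(sub = character(), sup = character(),
                          stringsAsFactors = FALSE),
    annotations = data.frame(code = character(), property = character(),
                             value = character(), resource = logical(),
                             stringsAsFactors = FALSE),
    object_properties = character(),
    annotation_properties = character(),
    restrictions = data.frame(sub = character(), property = character(),
                              filler = character(), stringsAsFactors = FALSE)
  ), class = "ontology_document")
}

#' @export
print.ontology_document <- function(x, ...) {
  cat("<ontology_document>", x$base, "\n")
  cat(sprintf("  %d classes, %d subclass axioms, %d annotations, %d restrictions\n",
              nrow(x$classes), nrow(x$subclass), nrow(x$annotations),
              nrow(x$restrictions)))
  invisible(x)
}

rubric_property <- c(definition = "ck:definition",
                     inclusion = "ck:inclusion",
                     exclusion = "ck:exclusion",
                     "coding-hint" = "ck:codingHint",
                     other = "ck:note")

#' Render a classification as an OWL ontology
#'
#' One OWL class per (non-excluded) concept and one subclass axiom per
#' parent-child edge. The preferred rubric becomes `rdfs:label`;
#' definition, inclusion, exclusion and coding-hint rubrics become distinct
#' annotation properties (never logical axioms - exclusions are not turned
#' into disjointness); the code itself is recorded as an identifier
#' annotation.
#'
#' @param x A `classification`.
#' @param base Ontology IRI; class IRIs are `<base>#<code>`.
#' @param blocks `"class"` keeps block concepts as OWL classes with their
#'   real hierarchy edges; `"annotation"` makes blocks transparent (their
#'   categories attach to the chapter and carry a `ck:block` annotation).
#' @param include_residuals Keep residual ("Other specified"/"Unspecified")
#'   concepts in the export (default `TRUE`; the printed analyses drop
#'   them, but the export is non-destructive by default).
#' @return An `ontology_document`.
#' @export
to_owl <- function(x, base = DEFAULT_BASE,
                   blocks = c("class", "annotation"),
                   include_residuals = TRUE) {
  stopifnot(inherits(x, "classification"))
  blocks <- match.arg(blocks)
  doc <- ontology_document(base)
  keep <- vapply(x$concepts, function(k) {
    (include_residuals || !k$residual) &&
      (blocks == "class" || k$kind != "block")
  }, logical(1))
  kept <- x$concepts[keep]
  codes <- vapply(kept, `[[`, character(1), "code")
  if (any(grepl("[#<>\"{}|\\^`\\\\ ]", codes)))
    stop("integrity error: code(s) not usable in an IRI: ",
         paste(codes[grepl("[#<>\"{}|\\^`\\\\ ]", codes)], collapse = ", "),
         call. = FALSE)
  ord <- order(codes)
  kept <- kept[ord]; codes <- codes[ord]

  cls <- data.frame(code = codes,
                    label = vapply(kept, concept_title, character(1)),
                    stringsAsFactors = FALSE)
  subs <- list(); anns <- list()
  for (k in kept) {
    anns[[length(anns) + 1L]] <-
      data.frame(code = k$code, property = "ck:code", value = k$code,
                 resource = FALSE, stringsAsFactors = FALSE)
    for (r in k$rubrics) {
      if (r$kind == "preferred") next
      anns[[length(anns) + 1L]] <-
        data.frame(code = k$code, property = rubric_property[[r$kind]],
                   value = r$text, resource = FALSE, stringsAsFactors = FALSE)
    }
    p <- k$parent
    if (!is.na(p) && !is.null(x$concepts[[p]])) {
      if (blocks == "annotation") {
        pk <- x$concepts[[p]]
        seen_block <- FALSE
        while (!is.null(pk) && pk$kind == "block") {
          if (!seen_block) {  # record membership in the innermost block
            anns[[length(anns) + 1L]] <-
              data.frame(code = k$code, property = "ck:block",
                         value = pk$code, resource = FALSE,
                         stringsAsFactors = FALSE)
            seen_block <- TRUE
          }
          pk <- if (is.na(pk$parent)) NULL else x$concepts[[pk$parent]]
        }
        p <- if (is.null(pk)) NA_character_ else pk$code
      }
      if (!is.na(p) && p %in% codes)
        subs[[length(subs) + 1L]] <-
          data.frame(sub = k$code, sup = p, stringsAsFactors = FALSE)
    }
  }
  doc$classes <- cls
  doc$subclass <- if (length(subs)) do.call(rbind, subs) else doc$subclass
  doc$annotations <- if (length(anns)) do.call(rbind, anns) else doc$annotations
  doc$annotation_properties <-
    sort(unique(c("ck:code",
                  intersect(unique(doc$annotations$property),
                            unname(c(rubric_property, "ck:block"))))))
  doc
}

relation_object_property <- c(SubProcess = "subProcess", Agent = "agent",
                              Patient = "patient", Instrument = "instrument")

#' Render a classification as OWL with edge-relationship annotations
#'
#' In the default (non-destructive) mode every hierarchy edge stays a
#' subclass axiom and each non-subsumption annotation is recorded as a
#' `ck:proposedRelation` annotation on the child class. In strict mode the
#' proposal is operationalized: a non-subsumption edge loses its subclass
#' axiom and the child instead receives an existential restriction
#' (`owl:someValuesFrom` the parent) on the matching object property
#' (`ck:subProcess`/`ck:agent`/`ck:patient`/`ck:instrument`) - or, for
#' `Complexity`, a `ck:complexity` annotation with value `"simple"` or
#' `"complex"` (complexity could not be grounded in the upper ontology, so
#' it is never an object property).
#'
#' @param x A `classification`.
#' @param annotations An `edge_annotations` data.frame; every annotated
#'   edge must exist among the classification's logical edges.
#' @param mode `"annotate"` (default) or `"strict"`.
#' @param base,include_residuals As in [to_owl()].
#' @return An `ontology_document`.
#' @export
to_owl_annotated <- function(x, annotations, mode = c("annotate", "strict"),
                             base = DEFAULT_BASE, include_residuals = TRUE) {
  mode <- match.arg(mode)
  edges <- classification_edges(x, include_residual = TRUE)
  known <- paste(edges$parent, edges$child)
  key <- paste(annotations$parent, annotations$child)
  if (!all(key %in% known))
    stop("integrity error: annotation(s) for nonexistent edge(s): ",
         paste(key[!key %in% known], collapse = "; "), call. = FALSE)
  # logical-edge rendering so axioms line up with annotated edges
  doc <- to_owl(x, base = base, blocks = "annotation",
                include_residuals = include_residuals)
  nonsub <- annotations[annotations$relation != "Subsumption", , drop = FALSE]
  if (!nrow(nonsub)) return(doc)
  if (mode == "annotate") {
    add <- data.frame(code = nonsub$child, property = "ck:proposedRelation",
                      value = paste(nonsub$relation, nonsub$parent),
                      resource = FALSE, stringsAsFactors = FALSE)
    doc$annotations <- rbind(doc$annotations, add)
    doc$annotation_properties <-
      sort(unique(c(doc$annotation_properties, "ck:proposedRelation")))
    return(doc)
  }
  # strict mode
  for (i in seq_len(nrow(nonsub))) {
    rel <- nonsub$relation[i]
    ch <- nonsub$child[i]; pa <- nonsub$parent[i]
    drop <- doc$subclass$sub == ch & doc$subclass$sup == pa
    doc$subclass <- doc$subclass[!drop, , drop = FALSE]
    if (rel == "Complexity") {
      title <- tolower(concept_title(x$concepts[[ch]]))
      val <- if (grepl("\\b(simple|single)\\b", title)) "simple" else "complex"
      doc$annotations <- rbind(doc$annotations,
        data.frame(code = ch, property = "ck:complexity", value = val,
                   resource = FALSE, stringsAsFactors = FALSE))
      doc$annotation_properties <-
        sort(unique(c(doc$annotation_properties, "ck:complexity")))
    } else {
      prop <- relation_object_property[[rel]]
      doc$object_properties <-
        sort(unique(c(doc$object_properties, prop)))
      doc$restrictions <- rbind(doc$restrictions,
        data.frame(sub = ch, property = paste0("ck:", prop), filler = pa,
                   stringsAsFactors = FALSE))
    }
  }
  rownames(doc$subclass) <- NULL
  doc
}

class_iri <- function(doc, code) paste0(doc$base, "#", code)

#' Serialize an ontology document
#'
#' Deterministic output (classes sorted by code) in RDF/XML or Turtle. The
#' two dialects re-parse (via [owl_triples()]) to isomorphic RDF graphs.
#'
#' @param doc An `ontology_document`.
#' @param path Optional output file; when `NULL` the text is returned.
#' @param dialect `"rdfxml"` or `"turtle"`.
#' @return The serialization text (invisibly when written to `path`).
#' @export
write_owl <- function(doc, path = NULL, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  txt <- if (dialect == "rdfxml") owl_rdfxml(doc) else owl_turtle(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

curie_qname <- function(p) sub("^ck:", "ck:", p)  # curies double as QNames

owl_rdfxml <- function(doc) {
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<rdf:RDF",
    sprintf("    xmlns:rdf=\"%s\"", NS["rdf"]),
    sprintf("    xmlns:rdfs=\"%s\"", NS["rdfs"]),
    sprintf("    xmlns:owl=\"%s\"", NS["owl"]),
    sprintf("    xmlns:skos=\"%s\"", NS["skos"]),
    sprintf("    xmlns:ck=\"%s#\">", doc$base),
    sprintf("  <owl:Ontology rdf:about=\"%s\"/>", doc$base))
  for (p in doc$annotation_properties)
    out <- c(out, sprintf("  <owl:AnnotationProperty rdf:about=\"%s\"/>",
                          expand_curie(p, doc$base)))
  for (p in doc$object_properties)
    out <- c(out, sprintf("  <owl:ObjectProperty rdf:about=\"%s#%s\"/>",
                          doc$base, p))
  ord <- order(doc$classes$code)
  for (i in ord) {
    cd <- doc$classes$code[i]
    out <- c(out, sprintf("  <owl:Class rdf:about=\"%s\">",
                          class_iri(doc, cd)))
    out <- c(out, sprintf("    <rdfs:label>%s</rdfs:label>",
                          xml_escape(doc$classes$label[i])))
    sup <- sort(doc$subclass$sup[doc$subclass$sub == cd])
    for (s in sup)
      out <- c(out, sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>",
                            class_iri(doc, s)))
    res <- doc$restrictions[doc$restrictions$sub == cd, , drop = FALSE]
    if (nrow(res)) {
      res <- res[order(res$property, res$filler), , drop = FALSE]
      for (j in seq_len(nrow(res)))
        out <- c(out,
          "    <rdfs:subClassOf>",
          "      <owl:Restriction>",
          sprintf("        <owl:onProperty rdf:resource=\"%s\"/>",
                  expand_curie(res$property[j], doc$base)),
          sprintf("        <owl:someValuesFrom rdf:resource=\"%s\"/>",
                  class_iri(doc, res$filler[j])),
          "      </owl:Restriction>",
          "    </rdfs:subClassOf>")
    }
    ann <- doc$annotations[doc$annotations$code == cd, , drop = FALSE]
    if (nrow(ann)) {
      ann <- ann[order(ann$property, ann$value), , drop = FALSE]
      for (j in seq_len(nrow(ann))) {
        qn <- curie_qname(ann$property[j])
        if (ann$resource[j])
          out <- c(out, sprintf("    <%s rdf:resource=\"%s\"/>", qn,
                                xml_escape(ann$value[j])))
        else
          out <- c(out, sprintf("    <%s>%s</%s>", qn,
                                xml_escape(ann$value[j]), qn))
      }
    }
    out <- c(out, "  </owl:Class>")
  }
  paste(c(out, "</rdf:RDF>"), collapse = "\n")
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

owl_turtle <- function(doc) {
  iri <- function(cd) paste0("<", class_iri(doc, cd), ">")
  out <- c(
    sprintf("@prefix rdf: <%s> .", NS["rdf"]),
    sprintf("@prefix rdfs: <%s> .", NS["rdfs"]),
    sprintf("@prefix owl: <%s> .", NS["owl"]),
    sprintf("@prefix skos: <%s> .", NS["skos"]),
    sprintf("@prefix ck: <%s#> .", doc$base),
    "",
    sprintf("<%s> a owl:Ontology .", doc$base))
  for (p in doc$annotation_properties)
    out <- c(out, sprintf("<%s> a owl:AnnotationProperty .",
                          expand_curie(p, doc$base)))
  for (p in doc$object_properties)
    out <- c(out, sprintf("<%s#%s> a owl:ObjectProperty .", doc$base, p))
  ord <- order(doc$classes$code)
  for (i in ord) {
    cd <- doc$classes$code[i]
    stmts <- c("a owl:Class",
               sprintf("rdfs:label \"%s\"",
                       ttl_escape(doc$classes$label[i])))
    for (s in sort(doc$subclass$sup[doc$subclass$sub == cd]))
      stmts <- c(stmts, sprintf("rdfs:subClassOf %s", iri(s)))
    res <- doc$restrictions[doc$restrictions$sub == cd, , drop = FALSE]
    if (nrow(res)) {
      res <- res[order(res$property, res$filler), , drop = FALSE]
      for (j in seq_len(nrow(res)))
        stmts <- c(stmts, sprintf(
          "rdfs:subClassOf [ a owl:Restriction ; owl:onProperty <%s> ; owl:someValuesFrom %s ]",
          expand_curie(res$property[j], doc$base), iri(res$filler[j])))
    }
    ann <- doc$annotations[doc$annotations$code == cd, , drop = FALSE]
    if (nrow(ann)) {
      ann <- ann[order(ann$property, ann$value), , drop = FALSE]
      for (j in seq_len(nrow(ann))) {
        pfull <- expand_curie(ann$property[j], doc$base)
        stmts <- c(stmts, sprintf(
          if (ann$resource[j]) "<%s> <%s>" else "<%s> \"%s\"",
          pfull,
          if (ann$resource[j]) ann$value[j] else ttl_escape(ann$value[j])))
      }
    }
    out <- c(out, "", paste0(iri(cd), " ",
                             paste(stmts, collapse = " ;\n    "), " ."))
  }
  paste(out, collapse = "\n")
}
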