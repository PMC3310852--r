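#' Re-parse an OWL serialization into RDF triples
#'
#' Independent reader used to check the serializers: it extracts the triple
#' set from an RDF/XML or Turtle document produced by [write_owl()] (it
#' supports the subset of each syntax the writer emits - typed node
#' elements, `rdf:resource` objects, literals, and one level of blank nodes
#' for `owl:Restriction`). Blank nodes get generated `_:b<n>` ids.
#'
#' @param text Serialization text (single string) or a file path.
#' @param dialect `"rdfxml"` or `"turtle"`.
#' @return A data.frame with columns `s`, `p`, `o`, `lit` (logical: is the
#'   object a literal?).
#' @export
owl_triples <- function(text, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- paste(readLines(text, encoding = "UTF-8"), collapse = "\n")
  if (dialect == "rdfxml") triples_rdfxml(text) else triples_turtle(text)
}

triple_row <- function(s, p, o, lit = FALSE)
  data.frame(s = s, p = p, o = o, lit = lit, stringsAsFactors = FALSE)

triples_rdfxml <- function(text) {
  doc <- xml2::read_xml(text)
  nsmap <- xml2::xml_ns(doc)
  expand <- function(qname) {
    parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% names(nsmap))
      paste0(nsmap[[parts[1]]], parts[2])
    else qname
  }
  rdf_type <- paste0(NS["rdf"], "type")
  bn <- 0L
  rows <- list()
  emit <- function(s, p, o, lit = FALSE)
    rows[[length(rows) + 1L]] <<- triple_row(s, p, o, lit)
  parse_node <- function(node, subject = NULL) {
    qn <- xml2::xml_name(node, nsmap)
    if (is.null(subject)) {
      subject <- xml2::xml_attr(node, "about")
      if (is.na(subject)) {
        bn <<- bn + 1L
        subject <- paste0("_:b", bn)
      }
    }
    emit(subject, rdf_type, expand(qn))
    for (prop in xml2::xml_children(node)) {
      pfull <- expand(xml2::xml_name(prop, nsmap))
      res <- xml2::xml_attr(prop, "resource")
      kids <- xml2::xml_children(prop)
      if (!is.na(res)) {
        emit(subject, pfull, res)
      } else if (length(kids)) {
        bn <<- bn + 1L
        b <- paste0("_:b", bn)
        emit(subject, pfull, b)
        parse_node(kids[[1]], subject = b)
      } else {
        emit(subject, pfull, xml2::xml_text(prop), lit = TRUE)
      }
    }
    subject
  }
  for (node in xml2::xml_children(doc)) parse_node(node)
  if (!length(rows)) return(triple_row(character(), character(), character(),
                                       logical())[0, ])
  do.call(rbind, rows)
}

ttl_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  push <- function(type, value)
    toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("turtle parse error: unterminated IRI", call. = FALSE)
      push("iri", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L; buf <- character()
      while (j <= n) {
        if (chars[j] == "\\") {
          esc <- chars[j + 1L]
          buf <- c(buf, switch(esc, n = "\n", r = "\r", t = "\t",
                               "\"" = "\"", "\\" = "\\", esc))
          j <- j + 2L
        } else if (chars[j] == "\"") break
        else { buf <- c(buf, chars[j]); j <- j + 1L }
      }
      if (j > n) stop("turtle parse error: unterminated literal",
                      call. = FALSE)
      push("literal", paste(buf, collapse = ""))
      i <- j + 1L; next
    }
    if (ch %in% c("[", "]", ";", ",", ".")) {
      push(ch, ch); i <- i + 1L; next
    }
    j <- i
    while (j <= n && !chars[j] %in% c(" ", "\t", "\n", "\r", ";", ",", ".",
                                      "]", "[")) j <- j + 1L
    push("word", paste(chars[i:(j - 1L)], collapse = ""))
    i <- j
  }
  toks
}

triples_turtle <- function(text) {
  toks <- ttl_tokenize(text)
  prefixes <- character()
  rdf_type <- paste0(NS["rdf"], "type")
  pos <- 1L
  bn <- 0L
  rows <- list()
  emit <- function(s, p, o, lit = FALSE)
    rows[[length(rows) + 1L]] <<- triple_row(s, p, o, lit)
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  resolve <- function(tok) {
    if (tok$type == "iri") return(list(v = tok$value, lit = FALSE))
    if (tok$type == "literal") return(list(v = tok$value, lit = TRUE))
    if (tok$type == "word") {
      if (tok$value == "a") return(list(v = rdf_type, lit = FALSE))
      parts <- strsplit(tok$value, ":", fixed = TRUE)[[1]]
      if (length(parts) == 2L && parts[1] %in% names(prefixes))
        return(list(v = paste0(prefixes[[parts[1]]], parts[2]), lit = FALSE))
      if (length(parts) == 1L && "" %in% names(prefixes))
        return(list(v = paste0(prefixes[[""]], parts[1]), lit = FALSE))
      stop("turtle parse error: unresolvable name ", tok$value,
           call. = FALSE)
    }
    stop("turtle parse error: unexpected token ", tok$type, call. = FALSE)
  }
  parse_object <- function(subject, pred) {
    tok <- take()
    if (identical(tok$type, "[")) {
      bn <<- bn + 1L
      b <- paste0("_:b", bn)
      emit(subject, pred, b)
      parse_polist(b, closing = "]")
    } else {
      r <- resolve(tok)
      emit(subject, pred, r$v, lit = r$lit)
    }
  }
  parse_polist <- function(subject, closing = ".") {
    repeat {
      ptok <- take()
      if (is.null(ptok)) stop("turtle parse error: unexpected end",
                              call. = FALSE)
      pred <- resolve(ptok)$v
      repeat {
        parse_object(subject, pred)
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == ",") { take(); next }
        break
      }
      nxt <- take()
      if (is.null(nxt)) stop("turtle parse error: unexpected end",
                             call. = FALSE)
      if (nxt$type == closing) return(invisible(NULL))
      if (nxt$type != ";")
        stop("turtle parse error: expected ';' or '", closing, "', got ",
             nxt$value, call. = FALSE)
      # allow trailing ';' before closing
      nxt2 <- peek()
      if (!is.null(nxt2) && nxt2$type == closing) { take(); return(invisible(NULL)) }
    }
  }
  while (!is.null(peek())) {
    tok <- take()
    if (tok$type == "word" && tok$value %in% c("@prefix", "PREFIX")) {
      pfx <- take()$value
      iri <- take()
      if (iri$type != "iri") stop("turtle parse error: bad @prefix",
                                  call. = FALSE)
      nm <- sub(":$", "", pfx)
      prefixes[nm] <- iri$value
      names(prefixes)[names(prefixes) == nm] <- nm
      end <- take()
      if (!identical(end$type, "."))
        stop("turtle parse error: @prefix not terminated", call. = FALSE)
      next
    }
    subject <- resolve(tok)$v
    parse_polist(subject, closing = ".")
  }
  if (!length(rows)) return(triple_row(character(), character(), character(),
                                       logical())[0, ])
  do.call(rbind, rows)
}

#' Canonicalize blank-node labels in a triple set
#'
#' Replaces each blank node id with a label derived from the node's own
#' sorted outgoing triples, so that triple sets from different
#' serializations of the same graph compare equal.
#'
#' @param t A triples data.frame from [owl_triples()].
#' @return The data.frame with canonical blank-node labels, sorted.
#' @export
canonical_triples <- function(t) {
  bnodes <- unique(c(t$s[startsWith(t$s, "_:")],
                     t$o[!t$lit & startsWith(t$o, "_:")]))
  for (b in bnodes) {
    own <- t[t$s == b, , drop = FALSE]
    key <- paste0("_:{", paste(sort(paste(own$p, own$o)), collapse = "|"), "}")
    t$s[t$s == b] <- key
    t$o[!t$lit & t$o == b] <- key
  }
  t[order(t$s, t$p, t$o, t$lit), , drop = FALSE]
}

#' Are two triple sets isomorphic (up to blank-node relabelling)?
#'
#' @param a,b Triples data.frames from [owl_triples()].
#' @return Logical.
#' @export
graphs_isomorphic <- function(a, b) {
  ca <- canonical_triples(a); cb <- canonical_triples(b)
  key <- function(t) sort(paste(t$s, t$p, t$o, t$lit, sep = "\r"))
  identical(key(ca), key(cb))
}
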