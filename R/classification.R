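#' @keywords internal
"_PACKAGE"

RUBRIC_KINDS <- c("preferred", "definition", "inclusion", "exclusion",
                  "coding-hint", "other")

CONCEPT_KINDS <- c("chapter", "block", "category", "subcategory")

#' Construct a rubric
#'
#' A rubric is one piece of text attached to a classification concept: its
#' preferred title, a definition, an inclusion or exclusion note, or a coding
#' hint. Kinds outside the known vocabulary are mapped to `"other"` and the
#' original kind string is preserved in `note`.
#'
#' @param kind Rubric kind string.
#' @param text Non-empty rubric text.
#' @param note Optional free-text note (used to retain unknown source kinds).
#' @return A list of class `claml_rubric`.
#' @export
rubric <- function(kind, text, note = NA_character_) {
  stopifnot(is.character(kind), length(kind) == 1L,
            is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("rubric text must be non-empty", call. = FALSE)
  if (!kind %in% RUBRIC_KINDS) {
    note <- if (is.na(note)) paste0("original kind: ", kind) else note
    kind <- "other"
  }
  structure(list(kind = kind, text = text, note = note),
            class = "claml_rubric")
}

#' Construct a classification concept
#'
#' One coded node of a classification: a chapter, block, category or
#' subcategory, with its rubrics and hierarchy links.
#'
#' @param code Classification code (e.g. `"d3550"`, or a block range
#'   `"d450-d469"`).
#' @param kind One of `"chapter"`, `"block"`, `"category"`, `"subcategory"`.
#' @param rubrics List of [rubric()] objects; exactly one must have kind
#'   `"preferred"`.
#' @param parent Parent code or `NA` for roots.
#' @param children Character vector of child codes (ordered, no duplicates).
#' @param residual Logical: is this an "Other specified"/"Unspecified"
#'   catch-all class? Defaults to title-based detection.
#' @return A list of class `claml_concept`.
#' @export
concept <- function(code, kind, rubrics, parent = NA_character_,
                    children = character(), residual = NULL) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  kind <- match.arg(kind, CONCEPT_KINDS)
  if (inherits(rubrics, "claml_rubric")) rubrics <- list(rubrics)
  pref <- vapply(rubrics, function(r) r$kind == "preferred", logical(1))
  if (sum(pref) != 1L)
    stop("concept ", code, " must have exactly one preferred rubric",
         call. = FALSE)
  if (anyDuplicated(children))
    stop("concept ", code, " has duplicated child codes", call. = FALSE)
  if (is.null(residual))
    residual <- is_residual_title(rubrics[[which(pref)]]$text)
  structure(list(code = code, kind = kind, rubrics = rubrics,
                 parent = parent, children = children,
                 residual = isTRUE(residual)),
            class = "claml_concept")
}

#' Preferred title of a concept
#' @param x A `claml_concept`.
#' @return The text of its preferred rubric.
#' @export
concept_title <- function(x) {
  for (r in x$rubrics) if (r$kind == "preferred") return(r$text)
  stop("concept ", x$code, " has no preferred rubric", call. = FALSE)
}

#' Construct a classification
#'
#' A classification is a forest of coded concepts: chapters are roots, with
#' blocks, categories and subcategories below them.
#'
#' @param concepts List of [concept()] objects.
#' @param name Classification name.
#' @param version Version string.
#' @param check Validate invariants on construction (default `TRUE`).
#' @return An object of class `classification`.
#' @export
classification <- function(concepts = list(), name = "classification",
                           version = "1.0", check = TRUE) {
  codes <- vapply(concepts, `[[`, character(1), "code")
  if (anyDuplicated(codes))
    stop("duplicate code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  names(concepts) <- codes
  roots <- codes[vapply(concepts, function(x) is.na(x$parent), logical(1))]
  x <- structure(list(name = name, version = version,
                      concepts = concepts, roots = unname(roots)),
                 class = "classification")
  if (check) {
    issues <- validate_classification(x)
    fatal <- attr(issues, "fatal")
    if (length(fatal)) stop(paste(fatal, collapse = "; "), call. = FALSE)
  }
  x
}

#' @export
print.classification <- function(x, ...) {
  kinds <- vapply(x$concepts, `[[`, character(1), "kind")
  cat("<classification> ", x$name, " (version ", x$version, ")\n", sep = "")
  cat("  concepts:", length(x$concepts),
      sprintf("[%s]", paste(sprintf("%d %s", tabulate(factor(kinds, CONCEPT_KINDS),
                                                      nbins = 4L),
                                    CONCEPT_KINDS), collapse = ", ")), "\n")
  cat("  roots:", paste(x$roots, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.claml_concept <- function(x, ...) {
  cat("<concept>", x$code, paste0("(", x$kind, ")"), concept_title(x), "\n")
  invisible(x)
}

#' Validate classification invariants
#'
#' Checks that parent/child links are mutually consistent, that the code index
#' is unique, that the concept graph is a forest (each chapter a tree root, no
#' cycles) and that every non-root concept has exactly one parent. Structural
#' violations are reported as "fatal"; advisory findings (e.g. a
#' classification with no chapters) as plain issues.
#'
#' @param x A `classification`.
#' @return Character vector of issue messages (empty if clean), with a
#'   `"fatal"` attribute listing the subset that violates hard invariants.
#' @export
validate_classification <- function(x) {
  issues <- character()
  fatal <- character()
  codes <- names(x$concepts)
  if (!any(vapply(x$concepts, function(k) k$kind == "chapter", logical(1))))
    issues <- c(issues, "no chapters")
  for (k in x$concepts) {
    if (!is.na(k$parent)) {
      p <- x$concepts[[k$parent]]
      if (is.null(p))
        fatal <- c(fatal, sprintf("parent %s of %s not present", k$parent, k$code))
      else if (!k$code %in% p$children)
        fatal <- c(fatal, sprintf("%s not listed among children of %s",
                                  k$code, k$parent))
    }
    for (ch in k$children) {
      c2 <- x$concepts[[ch]]
      if (is.null(c2))
        fatal <- c(fatal, sprintf("child %s of %s not present", ch, k$code))
      else if (is.na(c2$parent) || c2$parent != k$code)
        fatal <- c(fatal, sprintf("child %s does not point back to %s",
                                  ch, k$code))
    }
  }
  # cycle check: follow parents, must terminate at a root
  for (code in codes) {
    seen <- character()
    cur <- code
    repeat {
      if (cur %in% seen) {
        fatal <- c(fatal, sprintf("cycle in parent links involving: %s",
                                  paste(c(seen, cur), collapse = " -> ")))
        break
      }
      seen <- c(seen, cur)
      par <- x$concepts[[cur]]$parent
      if (is.null(par) || is.na(par)) break
      if (is.null(x$concepts[[par]])) break  # already reported
      cur <- par
    }
  }
  fatal <- unique(fatal)
  structure(unique(c(issues, fatal)), fatal = fatal)
}

#' Export a classification as a flat table
#'
#' @param x A `classification`.
#' @param ... Unused.
#' @return A data.frame with columns `code`, `kind`, `parent`, `title`,
#'   `residual`.
#' @export
as.data.frame.classification <- function(x, ...) {
  data.frame(
    code = names(x$concepts),
    kind = vapply(x$concepts, `[[`, character(1), "kind"),
    parent = vapply(x$concepts, `[[`, character(1), "parent"),
    title = vapply(x$concepts, concept_title, character(1)),
    residual = vapply(x$concepts, `[[`, logical(1), "residual"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write / read the flat TSV debugging form
#'
#' The flat form keeps codes, kinds, parent links and preferred titles only;
#' non-preferred rubrics are not carried.
#'
#' @param x A `classification`.
#' @param path File path.
#' @return `read_classification_tsv` returns a `classification`.
#' @export
write_classification_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_classification_tsv
#' @export
read_classification_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  parent <- df$parent
  parent[is.na(parent) | parent %in% c("", "NA")] <- NA_character_
  concepts <- lapply(seq_len(nrow(df)), function(i) {
    concept(df$code[i], df$kind[i], rubric("preferred", df$title[i]),
            parent = parent[i],
            children = df$code[!is.na(parent) & parent == df$code[i]],
            residual = if ("residual" %in% names(df))
              as.logical(df$residual[i]) else NULL)
  })
  classification(concepts)
}

#' Is a title a residual-class title?
#'
#' Residual classes are the "Other specified" and "Unspecified" catch-alls
#' that classifications append to sibling groups; analyses of the hierarchy
#' conventionally leave them out. Detection is by case-insensitive title
#' prefix. The optional strict mode additionally accepts the `.8`/`.9`
#' code-suffix convention.
#'
#' @param title Preferred title text.
#' @param code Optional code, consulted only when `strict = TRUE`.
#' @param strict Also treat codes whose final digit is 8 or 9 at subcategory
#'   depth as residual.
#' @return Logical.
#' @export
is_residual_title <- function(title, code = NULL, strict = FALSE) {
  hit <- grepl("^(other specified|unspecified)", title, ignore.case = TRUE)
  if (strict && !is.null(code) && grepl("^[A-Za-z][0-9]{4,}$", code))
    hit <- hit || grepl("[89]$", code)
  hit
}

#' @rdname is_residual_title
#' @param x A `claml_concept`.
#' @export
detect_residual <- function(x, strict = FALSE) {
  is_residual_title(concept_title(x), code = x$code, strict = strict)
}

#' Parse a classification code
#'
#' Codes are a component letter followed by digits (`d1` chapter, `d110`
#' category, `d1100`/`d3550` subcategory) or a block range (`d450-d469`).
#' Depth is the digit count (for blocks, of the range start).
#'
#' @param code Character vector of codes.
#' @return A data.frame with columns `code`, `component`, `chapter`, `kind`,
#'   `depth`. `chapter` is the one-digit chapter code (e.g. `"d4"`).
#' @export
classify_code <- function(code) {
  stopifnot(is.character(code))
  parse1 <- function(cd) {
    m <- regmatches(cd, regexec("^([A-Za-z])([0-9]+)$", cd))[[1]]
    if (length(m)) {
      ltr <- m[2]; digits <- m[3]; depth <- nchar(digits)
      kind <- if (depth == 1L) "chapter"
        else if (depth == 3L) "category"
        else if (depth >= 4L) "subcategory"
        else stop("unparseable code (no coding level has ", depth,
                  " digits): ", cd, call. = FALSE)
      return(list(code = cd, component = ltr,
                  chapter = paste0(ltr, substr(digits, 1, 1)),
                  kind = kind, depth = depth))
    }
    m <- regmatches(cd, regexec("^([A-Za-z])([0-9]{3})-([A-Za-z])([0-9]{3})$", cd))[[1]]
    if (length(m)) {
      if (m[2] != m[4])
        stop("unparseable code (block range mixes components): ", cd,
             call. = FALSE)
      return(list(code = cd, component = m[2],
                  chapter = paste0(m[2], substr(m[3], 1, 1)),
                  kind = "block", depth = 3L))
    }
    stop("unparseable code: ", cd, call. = FALSE)
  }
  do.call(rbind, lapply(lapply(code, parse1), as.data.frame))
}

#' Chapter code of a classification code
#' @param code Character vector.
#' @return Chapter codes such as `"d3"`.
#' @export
chapter_of <- function(code) classify_code(code)$chapter
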