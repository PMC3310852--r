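MATCH_KINDS <- c("broader", "equivalent", "partial")

#' Read an upper-ontology mapping table
#'
#' Tab-separated with header `source_code`, `target_concept`, `match_kind`,
#' `note` (note optional, `#` comment lines allowed). Match kinds are
#' `broader` (the usual case for mappings from a domain classification into
#' an upper ontology), `equivalent` and `partial`. Duplicate
#' (source, target) pairs are rejected; a source code may map to several
#' distinct targets.
#'
#' @param path File path (or character vector of lines).
#' @return A data.frame of class `sumo_mappings` with columns `source`,
#'   `target`, `match`, `note`.
#' @export
read_mappings <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, encoding = "UTF-8") else path
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl("^source_code\t", lines[1]))
    lines <- lines[-1]
  if (!length(lines)) return(sumo_mappings())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("mapping rows need at least 2 tab-separated fields; offending: ",
         lines[bad][1], call. = FALSE)
  get <- function(i, default = "") vapply(parts, function(p)
    if (length(p) >= i && nzchar(p[i])) p[i] else default, character(1))
  sumo_mappings(source = get(1), target = get(2),
                match = get(3, default = "broader"), note = get(4))
}

#' @rdname read_mappings
#' @param source,target,match,note Column vectors for direct construction;
#'   `match` defaults to `"broader"`.
#' @export
sumo_mappings <- function(source = character(), target = character(),
                          match = rep("broader", length(source)),
                          note = rep("", length(source))) {
  match <- tolower(match)
  if (!all(match %in% MATCH_KINDS))
    stop("vocabulary error: match kind(s) ",
         paste(unique(match[!match %in% MATCH_KINDS]), collapse = ", "),
         "; legal values are: ", paste(MATCH_KINDS, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(target)))
    stop("mapping target must be non-empty", call. = FALSE)
  # source must be a parseable classification code
  if (length(source)) invisible(classify_code(source))
  key <- paste(source, target)
  if (anyDuplicated(key))
    stop("integrity error: duplicate (source, target) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  m <- data.frame(source = source, target = target, match = match,
                  note = note, stringsAsFactors = FALSE)
  class(m) <- c("sumo_mappings", "data.frame")
  m
}

#' Read a level-total table
#'
#' Two tab-separated columns `level` (chapter/block/category/subcategory)
#' and `total`, so coverage denominators for a full classification can be
#' supplied without the classification file itself.
#'
#' @param path File path.
#' @return Named integer vector over the four levels.
#' @export
read_level_totals <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  stopifnot(all(c("level", "total") %in% names(df)))
  if (!all(df$level %in% CONCEPT_KINDS))
    stop("unknown level(s): ",
         paste(setdiff(df$level, CONCEPT_KINDS), collapse = ", "),
         call. = FALSE)
  out <- stats::setNames(rep(0L, length(CONCEPT_KINDS)), CONCEPT_KINDS)
  out[df$level] <- as.integer(df$total)
  out
}

#' Per-level coverage of an upper-ontology mapping
#'
#' A code counts as mapped iff it has at least one mapping entry. Coverage
#' is reported per level (chapter, block, category, subcategory) with the
#' list of unmapped codes when the level's members are known.
#'
#' @param mappings A `sumo_mappings` data.frame.
#' @param levels Either a `classification` (members and totals derived from
#'   its concepts) or a named level-total vector from [read_level_totals()]
#'   (totals only; unmapped lists unavailable). A data.frame with `code`
#'   and `kind` columns (e.g. a chapter list) is also accepted.
#' @param strict Error when a mapping source is absent from the supplied
#'   classification/level members; when `FALSE`, warn instead.
#' @return A data.frame of class `coverage_report` with columns `level`,
#'   `mapped`, `total`, plus an `"unmapped"` attribute (named list of
#'   unmapped code vectors).
#' @export
mapping_coverage <- function(mappings, levels, strict = TRUE) {
  src_kind <- if (nrow(mappings)) classify_code(mappings$source)$kind
              else character()
  members <- NULL
  if (inherits(levels, "classification")) {
    df <- as.data.frame(levels)
    members <- split(df$code, factor(df$kind, CONCEPT_KINDS))
  } else if (is.data.frame(levels)) {
    stopifnot(all(c("code", "kind") %in% names(levels)))
    members <- split(levels$code, factor(levels$kind, CONCEPT_KINDS))
  } else {
    totals <- levels
    stopifnot(is.numeric(totals), !is.null(names(totals)))
    if (!all(names(totals) %in% CONCEPT_KINDS))
      stop("level totals must be named by level", call. = FALSE)
  }
  if (!is.null(members)) {
    totals <- vapply(members, length, integer(1))
    all_codes <- unlist(members, use.names = FALSE)
    missing <- setdiff(mappings$source, all_codes)
    if (length(missing)) {
      msg <- paste("mapping source(s) absent from the classification:",
                   paste(missing, collapse = ", "))
      if (strict) stop("integrity error: ", msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
  }
  lv <- CONCEPT_KINDS
  mapped <- vapply(lv, function(k)
    length(unique(mappings$source[src_kind == k])), integer(1))
  tot <- stats::setNames(rep(NA_integer_, length(lv)), lv)
  tot[names(totals)] <- as.integer(totals)
  if (any(!is.na(tot) & mapped > tot))
    stop("integrity error: more mapped codes than level total", call. = FALSE)
  unmapped <- if (!is.null(members))
    lapply(stats::setNames(lv, lv), function(k)
      setdiff(members[[k]], mappings$source))
  else NULL
  rep <- data.frame(level = lv, mapped = unname(mapped), total = unname(tot),
                    stringsAsFactors = FALSE)
  attr(rep, "unmapped") <- unmapped
  class(rep) <- c("coverage_report", "data.frame")
  rep
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Upper-ontology mapping coverage\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %d/%s\n", x$level[i], x$mapped[i],
                ifelse(is.na(x$total[i]), "?", x$total[i])))
  un <- attr(x, "unmapped")
  if (!is.null(un)) {
    nn <- sum(lengths(un))
    if (nn) cat("  unmapped codes:",
                paste(unlist(un, use.names = FALSE), collapse = " "), "\n")
  }
  invisible(x)
}

match_property <- c(broader = "skos:broadMatch",
                    equivalent = "skos:exactMatch",
                    partial = "skos:relatedMatch")

#' Render mapping entries as an OWL annotation fragment
#'
#' Cross-ontology links are annotations (SKOS match assertions), never
#' logical subclass axioms: the mappings this supports are tentative, often
#' "usually broader" characterizations, and asserting subsumption across
#' ontologies would overstate them. Each entry becomes one match annotation
#' on the source class, pointing at the target concept's IRI in the upper
#' ontology's namespace.
#'
#' @param mappings A `sumo_mappings` data.frame.
#' @param base Ontology IRI for the source classes.
#' @param target_base IRI base of the upper ontology.
#' @return An `ontology_document` fragment (classes + annotations only).
#' @export
export_mapping_annotations <- function(mappings, base = DEFAULT_BASE,
                                       target_base = SUMO_BASE) {
  doc <- ontology_document(base)
  if (!nrow(mappings)) return(doc)
  codes <- sort(unique(mappings$source))
  doc$classes <- data.frame(code = codes, label = codes,
                            stringsAsFactors = FALSE)
  doc$annotations <- data.frame(
    code = mappings$source,
    property = unname(match_property[mappings$match]),
    value = paste0(target_base, "#", mappings$target),
    resource = TRUE, stringsAsFactors = FALSE)
  doc$annotation_properties <-
    sort(unique(doc$annotations$property))
  doc
}
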