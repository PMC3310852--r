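#' The six-way edge relationship vocabulary
#'
#' Parent-child links in an activity classification are conventionally read
#' as subsumption (is-a), but many actually encode something else: a stage of
#' the parent process (`SubProcess`), the number of agents involved
#' (`Agent`), the object acted on (`Patient`), the tool or means used
#' (`Instrument`), or a simple-versus-complex contrast (`Complexity`).
#' The first five come from a standard upper ontology's process predicates;
#' `Complexity` has no upper-ontology counterpart and is flagged as such.
#'
#' @return Character vector of the six relation names, with a logical
#'   `"upper_ontology"` attribute marking which are grounded in the upper
#'   ontology.
#' @export
relationship_types <- function() {
  structure(c("Subsumption", "SubProcess", "Agent", "Patient",
              "Instrument", "Complexity"),
            upper_ontology = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
}

match_relation <- function(name) {
  types <- relationship_types()
  i <- match(tolower(name), tolower(types))
  if (anyNA(i))
    stop("unknown relationship name(s): ",
         paste(unique(name[is.na(i)]), collapse = ", "),
         "; legal values are: ", paste(types, collapse = ", "),
         call. = FALSE)
  types[i]
}

#' Enumerate the logical parent-child edges of a classification
#'
#' Blocks (code-range groupings of consecutive categories) are transparent:
#' a chapter -> block -> category chain yields a single logical
#' chapter -> category edge, and blocks themselves contribute no edge.
#' Residual ("Other specified"/"Unspecified") children are excluded by
#' default, since the analysis this supports leaves them out. An edge is
#' `top`-level iff its (effective) parent is a chapter, `lower` otherwise.
#'
#' @param x A `classification`.
#' @param include_residual Keep edges whose child is a residual class.
#' @return A data.frame with columns `parent`, `child`, `level`.
#' @export
classification_edges <- function(x, include_residual = FALSE) {
  rows <- list()
  for (cd in names(x$concepts)) {
    k <- x$concepts[[cd]]
    if (k$kind == "block") next                 # transparent
    if (is.na(k$parent)) next
    if (k$residual && !include_residual) next
    p <- x$concepts[[k$parent]]
    while (!is.null(p) && p$kind == "block" && !is.na(p$parent))
      p <- x$concepts[[p$parent]]
    if (is.null(p)) next
    rows[[length(rows) + 1L]] <-
      data.frame(parent = p$code, child = cd,
                 level = if (p$kind == "chapter") "top" else "lower",
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(parent = character(), child = character(),
                      level = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

edge_level_from_code <- function(parent_code) {
  kind <- classify_code(parent_code)$kind
  ifelse(kind %in% c("chapter", "block"), "top", "lower")
}

#' Read an edge-annotation table
#'
#' The table is tab-separated with columns `parent_code`, `child_code`,
#' `relation` and an optional `note`; lines starting with `#` are comments
#' and a header row is recognised and skipped. Relation names are matched
#' case-insensitively against the six-way vocabulary. Each parent-child pair
#' may carry exactly one relation.
#'
#' @param path File path (or a character vector of lines).
#' @param classification Optional `classification`; when supplied, every
#'   annotated edge must exist among its logical edges.
#' @return A data.frame of class `edge_annotations` with columns `parent`,
#'   `child`, `relation`, `note`.
#' @export
read_annotations <- function(path, classification = NULL) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, encoding = "UTF-8") else path
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl("^parent_code\t", lines[1]))
    lines <- lines[-1]
  if (!length(lines)) return(edge_annotations())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("annotation rows need at least 3 tab-separated fields; offending: ",
         lines[bad][1], call. = FALSE)
  ann <- data.frame(
    parent = vapply(parts, `[`, character(1), 1L),
    child = vapply(parts, `[`, character(1), 2L),
    relation = match_relation(vapply(parts, `[`, character(1), 3L)),
    note = vapply(parts, function(p) if (length(p) >= 4L) p[4] else "",
                  character(1)),
    stringsAsFactors = FALSE)
  key <- paste(ann$parent, ann$child)
  if (anyDuplicated(key))
    stop("integrity error: duplicate edge annotation(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  if (!is.null(classification)) {
    edges <- classification_edges(classification, include_residual = TRUE)
    known <- paste(edges$parent, edges$child)
    if (!all(key %in% known))
      stop("integrity error: annotation(s) for nonexistent edge(s): ",
           paste(key[!key %in% known], collapse = "; "), call. = FALSE)
  }
  class(ann) <- c("edge_annotations", "data.frame")
  ann
}

#' @rdname read_annotations
#' @param parent,child,relation,note Column vectors for direct construction.
#' @export
edge_annotations <- function(parent = character(), child = character(),
                             relation = character(),
                             note = rep("", length(parent))) {
  ann <- data.frame(parent = parent, child = child,
                    relation = if (length(relation)) match_relation(relation)
                               else character(),
                    note = note, stringsAsFactors = FALSE)
  key <- paste(ann$parent, ann$child)
  if (anyDuplicated(key))
    stop("integrity error: duplicate edge annotation(s)", call. = FALSE)
  class(ann) <- c("edge_annotations", "data.frame")
  ann
}

#' Write an edge-annotation table
#' @param ann An `edge_annotations` data.frame.
#' @param path File path.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("parent_code\tchild_code\trelation\tnote", con)
  if (nrow(ann))
    writeLines(paste(ann$parent, ann$child, ann$relation, ann$note,
                     sep = "\t"), con)
  invisible(path)
}

#' Default lexical-cue lexicon for relationship suggestion
#'
#' Loaded from the editable TSV shipped in `extdata/relation_lexicon.tsv`
#' (columns `relation`, `pattern`, a case-insensitive regular expression
#' matched against the child's preferred title).
#'
#' @param path Optional alternative lexicon file.
#' @return A data.frame with columns `relation`, `pattern`.
#' @export
relation_lexicon <- function(path = system.file("extdata",
                                                "relation_lexicon.tsv",
                                                package = "clamlkit")) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$relation <- match_relation(df$relation)
  df
}

#' Suggest a relationship type for one hierarchy edge
#'
#' Rule-based and advisory only: the child's preferred title is matched
#' against the cue lexicon and the first firing relation is returned, with
#' fixed precedence SubProcess > Agent > Patient > Instrument > Complexity
#' when several cues fire. `NA` means "no cue"; callers conventionally fall
#' back to Subsumption. Curated annotation tables always take precedence
#' over suggestions.
#'
#' @param parent,child `claml_concept` objects (or plain title strings).
#' @param lexicon A lexicon data.frame, see [relation_lexicon()].
#' @return A relation name or `NA_character_`.
#' @export
suggest_relationship <- function(parent, child, lexicon = relation_lexicon()) {
  title <- if (inherits(child, "claml_concept")) concept_title(child)
           else as.character(child)
  hits <- lexicon$relation[vapply(lexicon$pattern, function(p)
    grepl(p, title, ignore.case = TRUE, perl = TRUE), logical(1))]
  if (!length(hits)) return(NA_character_)
  prec <- c("SubProcess", "Agent", "Patient", "Instrument", "Complexity")
  prec[min(match(hits, prec))]
}

#' Suggest annotations for every logical edge of a classification
#'
#' @param x A `classification`.
#' @param lexicon See [relation_lexicon()].
#' @param default Relation recorded when no cue fires (the conventional
#'   hierarchy reading, `"Subsumption"`).
#' @return An `edge_annotations` data.frame; `note` says whether each row
#'   was cue-suggested or defaulted.
#' @export
suggest_annotations <- function(x, lexicon = relation_lexicon(),
                                default = "Subsumption") {
  edges <- classification_edges(x)
  if (!nrow(edges)) return(edge_annotations())
  sugg <- vapply(seq_len(nrow(edges)), function(i)
    suggest_relationship(x$concepts[[edges$parent[i]]],
                         x$concepts[[edges$child[i]]], lexicon), character(1))
  edge_annotations(edges$parent, edges$child,
                   ifelse(is.na(sugg), default, sugg),
                   note = ifelse(is.na(sugg), "default", "suggested"))
}

#' Tabulate edge annotations per chapter, level and relation
#'
#' Produces the per-chapter relationship count table: one row per
#' (chapter, level) with one count column per relation plus a row total.
#' The chapter of an edge comes from its codes, which must agree between
#' parent and child.
#'
#' @param ann An `edge_annotations` data.frame.
#' @param chapters Optional character vector of chapter codes to include as
#'   all-zero rows even when unannotated.
#' @return A `relation_count_table` (data.frame with columns `chapter`,
#'   `level`, the six relations, `total`).
#' @export
tabulate_relationships <- function(ann, chapters = NULL) {
  types <- relationship_types()
  if (nrow(ann)) {
    pch <- chapter_of(ann$parent)
    cch <- chapter_of(ann$child)
    bad <- pch != cch
    if (any(bad))
      stop("integrity error: edge codes disagree on chapter: ",
           paste(ann$parent[bad], ann$child[bad], collapse = "; "),
           call. = FALSE)
    level <- edge_level_from_code(ann$parent)
    chs <- sort(unique(c(pch, chapters)))
  } else {
    pch <- character(); level <- character()
    chs <- sort(unique(chapters))
  }
  grid <- expand.grid(chapter = chs, level = c("top", "lower"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$chapter, grid$level == "lower"), , drop = FALSE]
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(types),
                   dimnames = list(NULL, types))
  if (nrow(ann)) {
    idx <- match(paste(pch, level), paste(grid$chapter, grid$level))
    for (i in seq_along(idx))
      counts[idx[i], ann$relation[i]] <- counts[idx[i], ann$relation[i]] + 1L
  }
  tab <- cbind(grid, as.data.frame(counts))
  tab$total <- as.integer(rowSums(counts))
  rownames(tab) <- NULL
  class(tab) <- c("relation_count_table", "data.frame")
  tab
}

#' Validate a relationship count table
#'
#' Hard invariants: counts are non-negative integers, each row's `total`
#' equals the sum of its six relation counts, and levels are `top`/`lower`.
#'
#' @param tab A `relation_count_table`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_relation_table <- function(tab) {
  types <- relationship_types()
  stopifnot(all(c("chapter", "level", types, "total") %in% names(tab)))
  cnt <- as.matrix(tab[, types, drop = FALSE])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!all(tab$level %in% c("top", "lower")))
    stop("level must be 'top' or 'lower'", call. = FALSE)
  if (any(rowSums(cnt) != tab$total))
    stop("row total differs from sum of relation counts", call. = FALSE)
  invisible(TRUE)
}

#' Column-wise totals of a relationship count table
#'
#' @param tab A `relation_count_table`.
#' @return A data.frame with one `top` and one `lower` row of summed counts
#'   (chapter = `"Total"`).
#' @export
relation_table_totals <- function(tab) {
  types <- relationship_types()
  out <- lapply(c("top", "lower"), function(lv) {
    sub <- tab[tab$level == lv, c(types, "total"), drop = FALSE]
    cbind(data.frame(chapter = "Total", level = lv,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colSums(sub))))
  })
  do.call(rbind, out)
}

#' Read / write the long-form count-table TSV
#'
#' The long form mirrors the published table's content: one row per
#' (chapter, level, relation) with a count; `#` lines are comments. Zero
#' cells may be omitted. Totals are always recomputed, never read.
#'
#' @param path File path.
#' @param tab A `relation_count_table` (for writing).
#' @return `read_count_table` returns a `relation_count_table`.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  stopifnot(all(c("chapter", "level", "relation", "count") %in% names(df)))
  count_long_to_table(df)
}

# pivot a long (chapter, level, relation, count) frame into the wide
# relation_count_table form; totals always recomputed
count_long_to_table <- function(df) {
  df$relation <- match_relation(df$relation)
  if (!all(df$level %in% c("top", "lower")))
    stop("level must be 'top' or 'lower'", call. = FALSE)
  types <- relationship_types()
  chs <- sort(unique(df$chapter))
  grid <- expand.grid(chapter = chs, level = c("top", "lower"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$chapter, grid$level == "lower"), , drop = FALSE]
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(types),
                   dimnames = list(NULL, types))
  idx <- match(paste(df$chapter, df$level), paste(grid$chapter, grid$level))
  for (i in seq_len(nrow(df)))
    counts[idx[i], df$relation[i]] <- counts[idx[i], df$relation[i]] +
      as.integer(df$count[i])
  tab <- cbind(grid, as.data.frame(counts))
  tab$total <- as.integer(rowSums(counts))
  rownames(tab) <- NULL
  class(tab) <- c("relation_count_table", "data.frame")
  validate_relation_table(tab)
  tab
}

#' @rdname read_count_table
#' @export
write_count_table <- function(tab, path) {
  validate_relation_table(tab)
  types <- relationship_types()
  long <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    data.frame(chapter = tab$chapter[i], level = tab$level[i],
               relation = types, count = as.integer(tab[i, types]),
               stringsAsFactors = FALSE)))
  keep <- long$count > 0
  # keep one zero row per chapter that would otherwise vanish
  for (ch in unique(long$chapter))
    if (!any(keep & long$chapter == ch))
      keep[which(long$chapter == ch)[1]] <- TRUE
  long <- long[keep, , drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("chapter\tlevel\trelation\tcount", con)
  if (nrow(long))
    writeLines(paste(long$chapter, long$level, long$relation, long$count,
                     sep = "\t"), con)
  invisible(path)
}
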