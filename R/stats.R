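#' Round half away from zero
#'
#' Integer rounding used for all reported percentages: halves round away
#' from zero (so 89.8 -> 90, 92.86 -> 93, 55.6 -> 56), unlike base R's
#' banker's rounding. This rule reproduces every published percentage the
#' package's fixtures encode.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

pct <- function(num, den) {
  ifelse(den == 0, NA_real_, round_half_away(100 * num / den))
}

#' Summarize relationship usage in a count table
#'
#' Derives the headline statistics of a subsumption audit from a
#' per-chapter, per-level relationship count table:
#' \itemize{
#'   \item `top_subsumption_pct`: percentage of top-level edges
#'     (chapter to category) annotated as plain subsumption;
#'   \item `lower_other_pct`: percentage of lower-level edges carrying a
#'     relation other than subsumption;
#'   \item `per_chapter_lower_other_pct`: the same, per chapter (`NA` -
#'     i.e. undefined, never 0 - for chapters with no lower-level edges);
#'   \item `majority_nonsubsumption_chapters`: chapters whose lower-level
#'     non-subsumption fraction is strictly greater than 1/2;
#'   \item `all_subsumption_chapters`: chapters with at least one edge, all
#'     of whose edges (both levels) are subsumption.
#' }
#' Exact numerator/denominator pairs are reported alongside each rounded
#' percentage.
#'
#' @param tab A `relation_count_table`.
#' @return A list of class `relationship_summary`.
#' @export
summarize_relationships <- function(tab) {
  validate_relation_table(tab)
  if (sum(tab$total) == 0)
    stop("empty report: table has no relationships to summarize",
         call. = FALSE)
  top <- tab[tab$level == "top", , drop = FALSE]
  low <- tab[tab$level == "lower", , drop = FALSE]
  top_n <- sum(top$total); top_subs <- sum(top$Subsumption)
  low_n <- sum(low$total); low_subs <- sum(low$Subsumption)

  chs <- sort(unique(tab$chapter))
  per <- vapply(chs, function(ch) {
    r <- low[low$chapter == ch, , drop = FALSE]
    pct(sum(r$total) - sum(r$Subsumption), sum(r$total))
  }, numeric(1))
  frac_other <- vapply(chs, function(ch) {
    r <- low[low$chapter == ch, , drop = FALSE]
    if (sum(r$total) == 0) NA_real_
    else (sum(r$total) - sum(r$Subsumption)) / sum(r$total)
  }, numeric(1))
  majority <- chs[!is.na(frac_other) & frac_other > 0.5]
  all_subs <- chs[vapply(chs, function(ch) {
    r <- tab[tab$chapter == ch, , drop = FALSE]
    sum(r$total) > 0 && sum(r$Subsumption) == sum(r$total)
  }, logical(1))]

  structure(list(
    top_subsumption_pct = pct(top_subs, top_n),
    top_subsumption_frac = c(numerator = top_subs, denominator = top_n),
    lower_other_pct = pct(low_n - low_subs, low_n),
    lower_other_frac = c(numerator = low_n - low_subs, denominator = low_n),
    per_chapter_lower_other_pct = stats::setNames(per, chs),
    majority_nonsubsumption_chapters = majority,
    all_subsumption_chapters = all_subs
  ), class = "relationship_summary")
}

#' @export
print.relationship_summary <- function(x, ...) {
  cat("Relationship usage summary\n")
  cat(sprintf("  top-level subsumption:        %d%% (%d/%d)\n",
              x$top_subsumption_pct, x$top_subsumption_frac[1],
              x$top_subsumption_frac[2]))
  cat(sprintf("  lower-level non-subsumption:  %d%% (%d/%d)\n",
              x$lower_other_pct, x$lower_other_frac[1],
              x$lower_other_frac[2]))
  per <- x$per_chapter_lower_other_pct
  cat("  per-chapter lower non-subsumption:\n")
  for (ch in names(per))
    cat(sprintf("    %s: %s\n", ch,
                if (is.na(per[ch])) "undefined (no lower-level edges)"
                else paste0(per[ch], "%")))
  cat("  majority non-subsumption chapters:",
      paste(x$majority_nonsubsumption_chapters, collapse = " "), "\n")
  cat("  all-subsumption chapters:",
      paste(x$all_subsumption_chapters, collapse = " "), "\n")
  invisible(x)
}

#' JSON form of a relationship summary
#'
#' Integer percentages and the exact fractions they round from, side by
#' side. `NA` percentages (chapters without lower-level edges) are emitted
#' as the string `"undefined"`.
#'
#' @param x A `relationship_summary`.
#' @return A JSON string.
#' @export
summary_to_json <- function(x) {
  per <- as.list(x$per_chapter_lower_other_pct)
  per <- lapply(per, function(v) if (is.na(v)) "undefined" else as.integer(v))
  jsonlite::toJSON(list(
    top_subsumption_pct = as.integer(x$top_subsumption_pct),
    top_subsumption_frac = as.list(x$top_subsumption_frac),
    lower_other_pct = as.integer(x$lower_other_pct),
    lower_other_frac = as.list(x$lower_other_frac),
    per_chapter_lower_other_pct = per,
    majority_nonsubsumption_chapters =
      as.list(x$majority_nonsubsumption_chapters),
    all_subsumption_chapters = as.list(x$all_subsumption_chapters)
  ), auto_unbox = TRUE, pretty = TRUE)
}

#' Render a count table in the published slash format
#'
#' One row per chapter plus a Total row; each cell is `top/lower`. The TSV
#' form re-parses to the original table via [parse_rendered_table()]; the
#' markdown form is for display.
#'
#' @param tab A `relation_count_table`.
#' @param format `"tsv"` or `"markdown"`.
#' @return A single string.
#' @export
render_table <- function(tab, format = c("tsv", "markdown")) {
  if (!is.character(format) || !all(format %in% c("tsv", "markdown")))
    stop("usage error: unknown format '", format[1],
         "' (use 'tsv' or 'markdown')", call. = FALSE)
  format <- match.arg(format)
  validate_relation_table(tab)
  types <- relationship_types()
  chs <- unique(tab$chapter)
  cell <- function(rows, col) {
    t1 <- rows[rows$level == "top", col]
    t2 <- rows[rows$level == "lower", col]
    paste0(if (length(t1)) t1 else 0L, "/", if (length(t2)) t2 else 0L)
  }
  body <- lapply(chs, function(ch) {
    rows <- tab[tab$chapter == ch, , drop = FALSE]
    c(ch, vapply(c("total", types), function(cl) cell(rows, cl), character(1)))
  })
  tot <- relation_table_totals(tab)
  body <- c(body, list(c("Total",
    vapply(c("total", types), function(cl) cell(tot, cl), character(1)))))
  header <- c("chapter", "total", types)
  if (format == "tsv") {
    paste(c(paste(header, collapse = "\t"),
            vapply(body, paste, character(1), collapse = "\t")),
          collapse = "\n")
  } else {
    md_row <- function(v) paste0("| ", paste(v, collapse = " | "), " |")
    paste(c(md_row(header),
            md_row(rep("---", length(header))),
            vapply(body, md_row, character(1))),
          collapse = "\n")
  }
}

#' Parse the TSV rendering of a count table back
#'
#' @param text Output of `render_table(tab, "tsv")`.
#' @return A `relation_count_table` equal to the table that was rendered.
#' @export
parse_rendered_table <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  types <- relationship_types()
  stopifnot(identical(header, c("chapter", "total", types)))
  rows <- lapply(lines[-1], function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
  rows <- Filter(function(r) r[1] != "Total", rows)
  long <- do.call(rbind, lapply(rows, function(r) {
    ch <- r[1]
    do.call(rbind, lapply(seq_along(types), function(j) {
      tl <- as.integer(strsplit(r[j + 2L], "/", fixed = TRUE)[[1]])
      data.frame(chapter = ch, level = c("top", "lower"),
                 relation = types[j], count = tl, stringsAsFactors = FALSE)
    }))
  }))
  count_long_to_table(long)
}
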