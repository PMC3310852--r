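#' Parameters for the synthetic classification generator
#'
#' Describes the shape of a generated classification: chapter count,
#' categories per chapter, subcategories per category, the fraction of each
#' subcategory sibling group turned into residual ("Other specified"/
#' "Unspecified") classes, an optional number of blocks per chapter, and a
#' relation distribution + seed for annotation generation.
#'
#' @param n_chapters Number of chapters (1-9; codes `d1`..`d9`).
#' @param categories_per_chapter Scalar or length-`n_chapters` vector
#'   (max 90 per chapter).
#' @param subcategories_per_category Scalar or per-chapter vector of the
#'   TOTAL subcategory count for that chapter, spread over its categories
#'   (max 10 per category).
#' @param residual_fraction Fraction of each subcategory sibling group
#'   (rounded down per group) generated as residual classes.
#' @param blocks_per_chapter Number of code-range blocks grouping each
#'   chapter's categories (0 = no blocks).
#' @param relation_distribution Named probability vector over
#'   [relationship_types()] used by [make_synthetic_annotations()].
#' @param seed Integer seed for annotation sampling.
#' @param component Component letter for codes (default `"d"`).
#' @return A list of class `synthesis_params`.
#' @export
synthesis_params <- function(n_chapters = 3,
                             categories_per_chapter = 4,
                             subcategories_per_category = 2,
                             residual_fraction = 0,
                             blocks_per_chapter = 0,
                             relation_distribution =
                               c(Subsumption = 1, SubProcess = 0, Agent = 0,
                                 Patient = 0, Instrument = 0, Complexity = 0),
                             seed = 1L,
                             component = "d") {
  if (n_chapters < 1 || n_chapters > 9)
    stop("parameter error: n_chapters must be in 1..9", call. = FALSE)
  cats <- rep_len(categories_per_chapter, n_chapters)
  if (any(cats < 0) || any(cats > 90))
    stop("parameter error: categories_per_chapter must be in 0..90",
         call. = FALSE)
  # scalar = per category; vector = per-chapter totals
  subs_total <- if (length(subcategories_per_category) == 1L)
    cats * subcategories_per_category else rep_len(subcategories_per_category,
                                                   n_chapters)
  if (any(subs_total < 0))
    stop("parameter error: negative subcategory count", call. = FALSE)
  if (any(subs_total > cats * 10))
    stop("parameter error: more than 10 subcategories per category needed",
         call. = FALSE)
  if (residual_fraction < 0 || residual_fraction > 1)
    stop("parameter error: residual_fraction must be in [0,1]", call. = FALSE)
  if (residual_fraction > 0 && sum(subs_total) == 0)
    stop("parameter error: residual_fraction > 0 needs subcategories",
         call. = FALSE)
  blocks <- rep_len(blocks_per_chapter, n_chapters)
  if (any(blocks < 0) || any(blocks > cats))
    stop("parameter error: blocks_per_chapter must be in 0..categories",
         call. = FALSE)
  types <- relationship_types()
  rd <- relation_distribution[types]
  if (anyNA(rd) || any(rd < 0) || abs(sum(rd) - 1) > 1e-8)
    stop("parameter error: relation_distribution must be a probability ",
         "vector over the six relations", call. = FALSE)
  names(rd) <- types
  structure(list(n_chapters = as.integer(n_chapters),
                 categories = as.integer(cats),
                 subcategories = as.integer(subs_total),
                 residual_fraction = residual_fraction,
                 blocks = as.integer(blocks),
                 relation_distribution = rd,
                 seed = as.integer(seed),
                 component = component),
            class = "synthesis_params")
}

# spread n items over k slots: first (n %% k) slots get one extra
even_split <- function(n, k) {
  if (k == 0L) return(integer())
  base <- n %/% k
  extra <- n %% k
  as.integer(base + (seq_len(k) <= extra))
}

#' Generate a synthetic ClaML classification
#'
#' Deterministic for given parameters (identical parameters give identical
#' output bytes): the structure is fully specified by the shape parameters,
#' residual classes are the trailing floor(fraction * group size) members
#' of each subcategory sibling group, and titles are synthesized from
#' codes. The output always re-parses cleanly with [read_claml()].
#'
#' @param p A [synthesis_params()] object.
#' @param as_text Return ClaML XML text (default); otherwise the parsed
#'   `classification`.
#' @return ClaML XML (single string) or a `classification`.
#' @export
make_synthetic_classification <- function(p, as_text = TRUE) {
  stopifnot(inherits(p, "synthesis_params"))
  concepts <- list()
  add <- function(k) concepts[[length(concepts) + 1L]] <<- k
  for (i in seq_len(p$n_chapters)) {
    chap <- paste0(p$component, i)
    ncat <- p$categories[i]
    cat_codes <- if (ncat) sprintf("%s%d%02d", p$component, i,
                                   9L + seq_len(ncat)) else character()
    nblk <- p$blocks[i]
    blk_sizes <- even_split(ncat, nblk)
    blk_of_cat <- if (nblk) rep(seq_len(nblk), blk_sizes) else integer()
    blk_codes <- if (nblk) vapply(seq_len(nblk), function(b) {
      members <- cat_codes[blk_of_cat == b]
      paste0(members[1], "-", members[length(members)])
    }, character(1)) else character()
    chap_children <- if (nblk) blk_codes else cat_codes
    add(concept(chap, "chapter",
                rubric("preferred", paste("Chapter", i, "activities")),
                children = chap_children))
    for (b in seq_len(nblk))
      add(concept(blk_codes[b], "block",
                  rubric("preferred",
                         paste("Activities group", blk_codes[b])),
                  parent = chap, children = cat_codes[blk_of_cat == b]))
    sub_per_cat <- even_split(p$subcategories[i], ncat)
    for (j in seq_len(ncat)) {
      cc <- cat_codes[j]
      nsub <- sub_per_cat[j]
      sub_codes <- if (nsub) paste0(cc, seq_len(nsub) - 1L) else character()
      add(concept(cc, "category",
                  rubric("preferred", paste("Activity", cc)),
                  parent = if (nblk) blk_codes[blk_of_cat[j]] else chap,
                  children = sub_codes))
      n_res <- floor(p$residual_fraction * nsub)
      for (s in seq_len(nsub)) {
        residual <- s > nsub - n_res
        title <- if (!residual) paste("Activity", sub_codes[s])
          else if (s == nsub && n_res >= 1L) "Unspecified"
          else paste("Other specified activity", cc)
        add(concept(sub_codes[s], "subcategory",
                    rubric("preferred", title), parent = cc))
      }
    }
  }
  cl <- classification(concepts, name = "synthetic classification",
                       version = "0.0")
  if (as_text) write_claml(cl) else cl
}

#' Sample edge annotations from a relation distribution
#'
#' Every non-residual logical edge of the classification gets exactly one
#' relation, drawn independently from `p$relation_distribution` with
#' `p$seed` (runs with the same seed give identical annotation lists; the
#' caller's RNG state is untouched).
#'
#' @param x A `classification`.
#' @param p A [synthesis_params()] object (distribution + seed used).
#' @return An `edge_annotations` data.frame.
#' @export
make_synthetic_annotations <- function(x, p) {
  stopifnot(inherits(x, "classification"), inherits(p, "synthesis_params"))
  edges <- classification_edges(x, include_residual = FALSE)
  if (!nrow(edges)) return(edge_annotations())
  types <- relationship_types()
  rel <- withr::with_seed(p$seed,
    sample(types, nrow(edges), replace = TRUE,
           prob = p$relation_distribution))
  edge_annotations(edges$parent, edges$child, rel,
                   note = rep("synthetic", nrow(edges)))
}

#' Shape parameters mirroring the published ICF Activities and
#' Participation component
#'
#' Nine chapters with 118 categories (partially grouped into 18 blocks) and
#' 266 subcategories. The published per-chapter breakdown is not part of the
#' encoded tables, so categories and subcategories are spread as evenly as
#' possible across chapters (and blocks two per chapter); only the level
#' totals are faithful.
#'
#' @param seed Seed forwarded to the params.
#' @return A [synthesis_params()] object.
#' @export
icf_shape_params <- function(seed = 1L) {
  synthesis_params(
    n_chapters = 9,
    categories_per_chapter = even_split(118L, 9L),
    subcategories_per_category = even_split(266L, 9L),
    blocks_per_chapter = 2,
    seed = seed)
}
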