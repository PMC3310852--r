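# fixtures built in code, shared across test files

ext_file <- function(f) system.file("extdata", f, package = "clamlkit")

# chapter -> category -> subcategory chain, built by hand
chain_classification <- function() {
  classification(list(
    concept("d1", "chapter", rubric("preferred", "Learning"),
            children = "d110"),
    concept("d110", "category", rubric("preferred", "Watching"),
            parent = "d1", children = "d1100"),
    concept("d1100", "subcategory", rubric("preferred", "Watching closely"),
            parent = "d110")
  ), name = "chain", version = "1.0")
}

# chapter with a transparent block and a residual subcategory
block_classification <- function() {
  classification(list(
    concept("d4", "chapter", rubric("preferred", "Mobility"),
            children = "d450-d469"),
    concept("d450-d469", "block",
            rubric("preferred", "Walking and moving"),
            parent = "d4", children = c("d450", "d455")),
    concept("d450", "category",
            list(rubric("preferred", "Walking"),
                 rubric("inclusion", "walking short distances"),
                 rubric("inclusion", "walking long distances"),
                 rubric("exclusion", "moving around (d455)")),
            parent = "d450-d469", children = c("d4500", "d4508")),
    concept("d455", "category", rubric("preferred", "Moving around"),
            parent = "d450-d469"),
    concept("d4500", "subcategory",
            rubric("preferred", "Walking short distances"),
            parent = "d450"),
    concept("d4508", "subcategory",
            rubric("preferred", "Other specified walking"),
            parent = "d450")
  ), name = "mobility extract", version = "1.0")
}

table2_fixture <- function() read_count_table(ext_file("table2_counts.tsv"))

conversation_fixture <- function()
  read_claml(ext_file("conversation_subtree.xml"))

# random synthesis params under the test grid, deterministic per seed
random_params <- function(seed) {
  withr::with_seed(seed, {
    nch <- sample(1:4, 1)
    cats <- sample(0:5, 1)
    subs <- sample(0:3, 1)
    synthesis_params(
      n_chapters = nch,
      categories_per_chapter = cats,
      subcategories_per_category = subs,
      residual_fraction = if (cats * subs > 0) sample(c(0, 0.3, 0.5), 1)
                          else 0,
      blocks_per_chapter = if (cats > 0) sample(0:min(2, cats), 1) else 0,
      relation_distribution = c(Subsumption = 0.4, SubProcess = 0.15,
                                Agent = 0.1, Patient = 0.15,
                                Instrument = 0.1, Complexity = 0.1),
      seed = seed)
  })
}

# triple-count helpers over the independent re-parse
n_of_type <- function(triples, type)
  sum(triples$p == paste0("http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                          "type") &
      triples$o == paste0("http://www.w3.org/2002/07/owl#", type))

n_named_subclass <- function(triples)
  sum(triples$p == paste0("http://www.w3.org/2000/01/rdf-schema#",
                          "subClassOf") &
      !startsWith(triples$o, "_:"))
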