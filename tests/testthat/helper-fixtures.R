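# Shared fixtures and independent brute-force oracles.  The oracles walk the
# DAG downward from the roots (child links), while the package's own
# implementations recurse upward over parent edges, so the two code paths
# share nothing but the loaded ontology.

diamond <- function() read_obo(text = diamond_obo())

# ids of the diamond fixture
D_R <- "GO:0000001"; D_B <- "GO:0000002"; D_C <- "GO:0000003"
D_D <- "GO:0000004"; D_E <- "GO:0000005"

# Brute-force root-to-target path enumeration: DFS from every root downward.
bf_paths <- function(ont, target) {
  res <- list()
  walk <- function(id, path) {
    path <- c(path, id)
    if (id == target) res[[length(res) + 1L]] <<- path
    for (ch in ont$terms[[id]]$children) walk(ch, path)
  }
  ns <- ont$terms[[target]]$namespace
  for (r in sort(ont$roots[[ns]])) walk(r, character())
  res
}

# Longest root-to-id path length for every non-obsolete term, by downward DFS.
bf_depths <- function(ont) {
  ids <- unlist(ont$domains, use.names = FALSE)
  depth <- stats::setNames(rep(0L, length(ids)), ids)
  walk <- function(id, d) {
    if (d > depth[[id]]) depth[[id]] <<- d
    for (ch in ont$terms[[id]]$children) walk(ch, d + 1L)
  }
  for (ns in names(ont$roots)) for (r in ont$roots[[ns]]) walk(r, 0L)
  depth
}

# Ancestor sets for every term by iterating the parent relation to a fixed
# point (no recursion, no memoized DP).
bf_ancestor_sets <- function(ont) {
  ids <- unlist(ont$domains, use.names = FALSE)
  anc <- lapply(stats::setNames(nm = ids), function(id) ont$terms[[id]]$parents)
  repeat {
    changed <- FALSE
    for (id in ids) {
      grown <- unique(c(anc[[id]],
                        unlist(anc[anc[[id]]], use.names = FALSE)))
      if (length(grown) > length(anc[[id]])) {
        anc[[id]] <- grown
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(anc, sort)
}

# Brute-force NCA: scan all common ancestors, keep the deepest.
bf_nca <- function(ids, anc_sets, depths) {
  cand <- Reduce(intersect, lapply(ids, function(i) c(anc_sets[[i]], i)))
  if (!length(cand)) return(character())
  sort(cand[depths[cand] == max(depths[cand])])
}

# A seeded random DAG ontology restricted to one namespace.
random_dag <- function(n, max_parents, seed) {
  spec <- fixture_spec(n_terms = c(biological_process = n),
                       max_parents = max_parents, seed = seed)
  fx <- make_ontology_fixture(spec)
  list(spec = spec, fx = fx, ont = read_obo(text = fx$obo))
}

# One enrichment record in the attached-record shape.
fake_record <- function(go_id = "GO:0000004", p = 0.001, or = 3.2,
                        expected = 2.5, observed = 10L, size = 40L,
                        term = "junction D", direction = "over") {
  list(go_id = go_id, p_value = p, odds_ratio = or, expected_count = expected,
       observed_count = observed, gene_set_size = size, term_name = term,
       direction = direction, significant = p < 0.05,
       fold = if (expected > 0) observed / expected else NA_real_)
}

# GOstats-style table text (tab-delimited unless sep is given).
gostats_text <- function(rows, sep = "\t", id_col = "GOBPID") {
  header <- paste(c(id_col, "Pvalue", "OddsRatio", "ExpCount", "Count",
                    "Size", "Term"), collapse = sep)
  body <- vapply(rows, paste, character(1), collapse = sep)
  paste(c(header, body), collapse = "\n")
}

# Annotation over the diamond with records only on the given ids.
diamond_annotation <- function(ont, ids, labels = "analysis_1", p = 0.001) {
  tabs <- lapply(labels, function(l) {
    data.frame(
      go_id = ids, p_value = p, odds_ratio = 3,
      expected_count = 2, observed_count = 6L, gene_set_size = 20L,
      term_name = vapply(ids, function(i) ont$terms[[i]]$name, character(1)),
      direction = "over", stringsAsFactors = FALSE
    )
  })
  names(tabs) <- labels
  attach_enrichment(ont, analysis_set(tabs))
}

# Deterministic display rows for golden-file rendering (no RNG anywhere).
golden_rows_single <- function() {
  ont <- diamond()
  recs <- list(
    a1 = fake_record(D_E, p = 0.001, or = 3.2, expected = 2.5, observed = 10L),
    a2 = fake_record(D_E, p = 0.2, or = 1.1, expected = 4, observed = 4L),
    a3 = fake_record(D_E, p = 0.04, or = 0.4, expected = 8, observed = 2L,
                     direction = "under"),
    a4 = NULL
  )
  rows <- lapply(seq_along(c(D_R, D_B, D_D, D_E)), function(i) {
    id <- c(D_R, D_B, D_D, D_E)[i]
    per <- lapply(recs, function(r) {
      if (is.null(r) || id != D_E) {
        list(record = NULL, significant = NA, fold = NA_real_)
      } else {
        list(record = r, significant = r$significant, fold = r$fold)
      }
    })
    list(go_id = id, label = ont$terms[[id]]$name, indent = i - 1L,
         terminal = id == D_E, per_analysis = per)
  })
  rows
}

golden_svg_path <- function(name) testthat::test_path("golden", name)

read_file_text <- function(path) {
  paste0(paste(readLines(path, warn = FALSE), collapse = "\n"), "\n")
}

count_matches <- function(text, pattern) {
  lengths(regmatches(text, gregexpr(pattern, text, fixed = TRUE)))
}
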