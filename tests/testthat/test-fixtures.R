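test_that("a single-term spec yields one root stanza and no edges", {
  fx <- make_ontology_fixture(fixture_spec(n_terms = c(biological_process = 1),
                                           seed = 3))
  expect_equal(nrow(fx$edges), 0)
  ont <- read_obo(text = fx$obo)
  expect_length(ont$terms, 1)
  expect_length(ont$roots$biological_process, 1)
})

test_that("fixture generation is deterministic in its seed", {
  spec <- fixture_spec(n_terms = 5, max_parents = 2, seed = 7)
  expect_identical(make_ontology_fixture(spec)$obo,
                   make_ontology_fixture(spec)$obo)
  spec2 <- fixture_spec(n_terms = 5, max_parents = 2, seed = 8)
  expect_false(identical(make_ontology_fixture(spec)$obo,
                         make_ontology_fixture(spec2)$obo))

  fx <- make_ontology_fixture(spec)
  en1 <- make_enrichment_fixture(spec, fx)
  en2 <- make_enrichment_fixture(spec, fx)
  expect_identical(en1, en2)
})

test_that("parsing a fixture recovers exactly the ground-truth edge and term sets", {
  for (seed in c(1, 17, 99)) {
    fx <- make_ontology_fixture(fixture_spec(n_terms = 10, max_parents = 3,
                                             seed = seed))
    ont <- read_obo(text = fx$obo)
    got <- do.call(rbind, lapply(ont$terms, function(t) {
      if (!length(t$parents)) return(NULL)
      data.frame(child = t$id, parent = t$parents, relation = t$relations,
                 stringsAsFactors = FALSE)
    }))
    key <- function(df) sort(paste(df$child, df$parent, df$relation))
    expect_equal(key(got), key(fx$edges))
    expect_setequal(names(ont$terms),
                    c(unlist(fx$term_ids, use.names = FALSE), fx$obsolete_ids))
    expect_equal(sort(names(ont$alt_index)), sort(names(fx$alt_ids)))
    for (alt in names(fx$alt_ids)) {
      expect_equal(resolve_term(ont, alt)$id, fx$alt_ids[[alt]])
    }
  }
})

test_that("every generated fixture is acyclic and namespace-closed", {
  for (seed in 1:10) {
    fx <- make_ontology_fixture(fixture_spec(n_terms = 15, max_parents = 3,
                                             seed = seed))
    # read_obo runs the cycle check; reaching here means acyclic
    ont <- read_obo(text = fx$obo)
    for (tm in ont$terms) {
      for (p in tm$parents) {
        expect_equal(ont$terms[[p]]$namespace, tm$namespace)
      }
    }
  }
})

test_that("enrichment fixtures emit GOstats columns and respect planted values", {
  spec <- demo_spec(seed = 7)
  fx <- make_ontology_fixture(spec)
  en <- make_enrichment_fixture(spec, fx)
  expect_length(en$analyses, 4)
  expect_named(en$analyses, paste0("analysis_", 1:4))
  tab <- en$analyses[[1]]$over
  expect_named(tab, c("GOBPID", "Pvalue", "OddsRatio", "ExpCount", "Count",
                      "Size", "Term"))
  expect_true(all(tab$Count <= tab$Size))
  expect_true(all(tab$Pvalue >= 0 & tab$Pvalue <= 1))

  for (i in seq_len(nrow(en$truth))) {
    tr <- en$truth[i, ]
    side <- en$analyses[[tr$label]][[tr$direction]]
    row <- side[side$GOBPID == tr$go_id, ]
    expect_equal(nrow(row), 1)
    expect_equal(row$Count, round(tr$fold_target * row$ExpCount))
    expect_lt(row$Pvalue, 0.05)
    if (tr$direction == "over") expect_gt(row$OddsRatio, 1)
    if (tr$direction == "under") expect_lt(row$OddsRatio, 1)
    # signal terms never leak into the opposite direction's table
    other <- en$analyses[[tr$label]][[setdiff(c("over", "under"), tr$direction)]]
    expect_false(tr$go_id %in% other$GOBPID)
  }
})

test_that("the full pipeline on a fixture flags exactly the planted signal terms", {
  spec <- demo_spec(seed = 21)
  fx <- make_ontology_fixture(spec)
  en <- make_enrichment_fixture(spec, fx)
  ont <- read_obo(text = fx$obo)
  tabs <- lapply(en$analyses, function(a) {
    ov <- a$over; un <- a$under
    combine_over_under(
      read_gostats(text = gostats_text(
        lapply(seq_len(nrow(ov)), function(i) unlist(format(ov[i, ], trim = TRUE)))),
        direction = "over"),
      read_gostats(text = gostats_text(
        lapply(seq_len(nrow(un)), function(i) unlist(format(un[i, ], trim = TRUE)))),
        direction = "under"))
  })
  ann <- attach_enrichment(ont, analysis_set(tabs))
  for (label in names(tabs)) {
    planted <- en$truth[en$truth$label == label, ]
    for (id in unlist(fx$term_ids, use.names = FALSE)) {
      rec <- goseries:::annotation_record(ann, id, label)
      if (id %in% planted$go_id) {
        expect_true(rec$significant, info = paste(label, id))
        expect_equal(rec$direction,
                     planted$direction[planted$go_id == id])
      } else if (!is.null(rec)) {
        expect_false(rec$significant, info = paste(label, id))
      }
    }
  }
})

test_that("a signal term citing an id outside the ontology is rejected", {
  spec <- fixture_spec(n_terms = 5, signal_terms = data.frame(
    go_id = "GO:7777777", direction = "over", fold = 4), seed = 1)
  fx <- make_ontology_fixture(fixture_spec(n_terms = 5, seed = 1))
  expect_error(make_enrichment_fixture(spec, fx), class = "gs_argument_error")
})

test_that("the written demo set is self-consistent and seed-stable on disk", {
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture_set(d1, seed = 7)
  write_fixture_set(d2, seed = 7)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  ont <- read_obo(file.path(d1, "ontology.obo"))
  sel <- load_selection(file.path(d1, "selection.txt"), ont)
  expect_gte(length(sel$paths), 3)
})

test_that("fixture OBO output is accepted by an independent third-party OBO parser", {
  python <- Sys.which("python")
  fx <- make_ontology_fixture(fixture_spec(n_terms = 8, max_parents = 2, seed = 5))
  obo_path <- tempfile(fileext = ".obo")
  writeLines(fx$obo, obo_path)
  script <- paste(
    "import sys, obonet",
    "g = obonet.read_obo(sys.argv[1])",
    "print(len(g.nodes()), len(g.edges()))",
    sep = "\n")
  script_path <- tempfile(fileext = ".py")
  writeLines(script, script_path)
  out <- system2(python, c(script_path, obo_path), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  counts <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  n_nonobsolete <- length(unlist(fx$term_ids, use.names = FALSE))
  expect_equal(counts[1], n_nonobsolete)  # obonet skips obsolete stanzas
  expect_equal(counts[2], nrow(fx$edges))
})
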