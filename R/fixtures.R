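# Seeded synthetic fixtures: toy ontologies in OBO text with a known edge
# list, and matched enrichment tables in the GOstats summary layout with
# known ground truth, so the whole pipeline is testable without a GO
# release or any real sequencing project.

# run expr under a fixed RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' A five-term diamond ontology in OBO text
#'
#' The worked toy example used throughout the documentation: root R
#' (GO:0000001), B (GO:0000002) and C (GO:0000003) children of R, D
#' (GO:0000004) child of both B and C, E (GO:0000005) child of D.  E lies
#' on exactly two root-to-term paths.
#'
#' @return OBO text as a single string.
#' @export
diamond_obo <- function() {
  paste(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000002", "name: branch B",
    "namespace: biological_process", "is_a: GO:0000001",
    "",
    "[Term]", "id: GO:0000003", "name: branch C",
    "namespace: biological_process", "is_a: GO:0000001",
    "",
    "[Term]", "id: GO:0000004", "name: junction D",
    "namespace: biological_process", "is_a: GO:0000002", "is_a: GO:0000003",
    "",
    "[Term]", "id: GO:0000005", "name: leaf E",
    "namespace: biological_process", "is_a: GO:0000004",
    ""
  ), collapse = "\n")
}

#' Specification for a synthetic fixture
#'
#' @param n_terms Number of terms per namespace: a single number (applied to
#'   all three namespaces) or a named vector over the namespaces.
#' @param max_parents Maximum DAG fan-in; term i draws 1..`max_parents`
#'   parents uniformly among the earlier terms of its namespace, so the
#'   graph is acyclic by construction.
#' @param n_analyses Number of pairwise analyses to emulate.
#' @param signal_terms Data frame with columns `go_id`, `direction`
#'   (`over`/`under`) and `fold`: terms forced significant in every
#'   analysis with the stated direction and fold change.
#' @param seed Integer seed; fixtures are fully reproducible from it.
#' @return An object of class `go_fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 12, max_parents = 2, n_analyses = 4,
                         signal_terms = NULL, seed = 1) {
  if (length(n_terms) == 1L && is.null(names(n_terms))) {
    n_terms <- stats::setNames(rep(as.integer(n_terms), 3), GO_NAMESPACES)
  } else {
    full <- stats::setNames(rep(0L, 3), GO_NAMESPACES)
    full[names(n_terms)] <- as.integer(n_terms)
    n_terms <- full
  }
  if (any(n_terms < 0) || sum(n_terms) < 1) {
    gs_error("gs_argument_error", "need at least one term in total")
  }
  if (max_parents < 1) {
    gs_error("gs_argument_error", "max_parents must be at least 1")
  }
  if (!is.null(signal_terms)) {
    stopifnot(is.data.frame(signal_terms),
              all(c("go_id", "direction", "fold") %in% names(signal_terms)),
              all(signal_terms$direction %in% c("over", "under")))
  }
  structure(list(n_terms = n_terms, max_parents = as.integer(max_parents),
                 n_analyses = as.integer(n_analyses),
                 signal_terms = signal_terms, seed = as.integer(seed)),
            class = "go_fixture_spec")
}

#' Generate a toy ontology as OBO text with its ground-truth edge list
#'
#' Terms are created namespace by namespace; term i (i > 1) receives
#' 1..`max_parents` parents drawn uniformly among terms 1..i-1 of the same
#' namespace, so the graph is acyclic by construction.  Names are
#' deterministic (`"term 0000003"`).  When a namespace has at least five
#' terms, one alternate id is attached to its fourth term and one extra
#' obsolete term is appended, so id resolution and obsolete handling are
#' exercised by every fixture.  The returned edge list (and term/alt/
#' obsolete inventory) is the independent oracle for parser tests.
#'
#' @param spec A `go_fixture_spec`.
#' @return A list: `obo` (text), `edges` (data frame child/parent/relation),
#'   `term_ids` (namespace -> character vector), `alt_ids` (named vector,
#'   alt -> canonical), `obsolete_ids` (character vector).
#' @export
make_ontology_fixture <- function(spec) {
  stopifnot(inherits(spec, "go_fixture_spec"))
  with_seed(spec$seed, {
    counter <- 0L
    next_id <- function() {
      counter <<- counter + 1L
      sprintf("GO:%07d", counter)
    }
    stanzas <- character()
    edges <- list()
    term_ids <- list()
    alt_ids <- character()
    obsolete_ids <- character()

    for (ns in GO_NAMESPACES) {
      n <- spec$n_terms[[ns]]
      if (n < 1) {
        term_ids[[ns]] <- character()
        next
      }
      ids <- vapply(seq_len(n), function(i) next_id(), character(1))
      term_ids[[ns]] <- ids
      alt_here <- if (n >= 5) sprintf("GO:%07d", 9000000L + counter) else NULL
      for (i in seq_len(n)) {
        id <- ids[i]
        st <- c("[Term]",
                paste0("id: ", id),
                paste0("name: term ", substring(id, 4)),
                paste0("namespace: ", ns))
        if (!is.null(alt_here) && i == 4L) {
          st <- c(st, paste0("alt_id: ", alt_here))
          alt_ids[[alt_here]] <- id
        }
        if (i > 1L) {
          k <- sample.int(spec$max_parents, 1L)
          k <- min(k, i - 1L)
          parents <- sort(ids[sample.int(i - 1L, k)])
          st <- c(st, paste0("is_a: ", parents))
          edges[[length(edges) + 1L]] <- data.frame(
            child = id, parent = parents, relation = "is_a",
            stringsAsFactors = FALSE)
        }
        stanzas <- c(stanzas, st, "")
      }
      if (n >= 5) {
        oid <- next_id()
        obsolete_ids <- c(obsolete_ids, oid)
        stanzas <- c(stanzas,
                     "[Term]",
                     paste0("id: ", oid),
                     paste0("name: obsolete term ", substring(oid, 4)),
                     paste0("namespace: ", ns),
                     "is_obsolete: true",
                     "")
      }
    }
    edges <- if (length(edges)) {
      do.call(rbind, edges)
    } else {
      data.frame(child = character(), parent = character(),
                 relation = character(), stringsAsFactors = FALSE)
    }
    list(
      obo = paste(c("format-version: 1.2", "ontology: go-fixture", "", stanzas),
                  collapse = "\n"),
      edges = edges,
      term_ids = term_ids,
      alt_ids = alt_ids,
      obsolete_ids = obsolete_ids
    )
  })
}

#' Generate matched enrichment tables in the GOstats summary layout
#'
#' For each analysis every signal term receives a P value drawn from
#' U(1e-6, 0.01), an expected count from U(1, 10), an observed count of
#' `round(fold * expected)` and an odds ratio consistent with its direction
#' (above 1 for over, below 1 for under); non-signal terms (a random subset
#' of the remaining biological-process terms) receive P from U(0.1, 1) and
#' a fold near 1.  The two ranges do not straddle 0.05, so at the default
#' threshold the pipeline must flag exactly the planted terms.  Columns and
#' header match the GOstats hyperGTest summary and nothing else.
#'
#' Records are drawn from the biological-process domain (GOstats runs one
#' test per GO domain; one domain is enough to exercise the pipeline).
#'
#' @param spec A `go_fixture_spec` whose `signal_terms` cite ids present in
#'   the fixture ontology.
#' @param fixture The result of [make_ontology_fixture()] on `spec`.
#' @param labels Optional analysis labels (default `"analysis_1"`, ...).
#' @return A list: `analyses` (label -> list(over = data frame, under =
#'   data frame), GOstats columns), `truth` (data frame label/go_id/
#'   direction/fold_target/fold_realized/expected/observed/p_value).
#' @export
make_enrichment_fixture <- function(spec, fixture, labels = NULL) {
  stopifnot(inherits(spec, "go_fixture_spec"))
  bp_ids <- fixture$term_ids$biological_process
  signal <- spec$signal_terms
  if (is.null(signal)) {
    signal <- data.frame(go_id = character(), direction = character(),
                         fold = numeric(), stringsAsFactors = FALSE)
  }
  missing <- setdiff(signal$go_id, unlist(fixture$term_ids, use.names = FALSE))
  if (length(missing)) {
    gs_error("gs_argument_error", paste0(
      "signal term(s) not in the fixture ontology: ",
      paste(missing, collapse = ", ")))
  }
  if (is.null(labels)) labels <- paste0("analysis_", seq_len(spec$n_analyses))
  stopifnot(length(labels) == spec$n_analyses)

  with_seed(spec$seed + 104729L, {  # offset: independent of the DAG draw
    term_label <- function(ids) {
      if (!length(ids)) return(character())
      paste("term", substring(ids, 4))
    }
    noise_pool <- setdiff(bp_ids, signal$go_id)
    analyses <- list()
    truth <- list()
    for (label in labels) {
      rows <- list()
      for (k in seq_len(nrow(signal))) {
        id <- signal$go_id[k]
        dir <- signal$direction[k]
        fold <- signal$fold[k]
        p <- stats::runif(1, 1e-6, 0.01)
        expected <- stats::runif(1, 1, 10)
        observed <- round(fold * expected)
        or <- if (dir == "over") {
          max(1.5, fold) * stats::runif(1, 1.1, 1.6)
        } else {
          min(0.67, max(fold, 0.05)) * stats::runif(1, 0.6, 0.95)
        }
        size <- observed + sample(5:50, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          go_id = id, p = p, or = or, expected = expected,
          observed = observed, size = size, direction = dir,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          label = label, go_id = id, direction = dir, fold_target = fold,
          fold_realized = observed / expected, expected = expected,
          observed = observed, p_value = p, stringsAsFactors = FALSE)
      }
      n_noise <- min(length(noise_pool), max(2L, length(noise_pool) %/% 2L))
      for (id in sort(sample(noise_pool, n_noise))) {
        dir <- sample(c("over", "under"), 1)
        p <- stats::runif(1, 0.1, 1)
        expected <- stats::runif(1, 1, 10)
        observed <- round(expected * stats::runif(1, 0.85, 1.15))
        or <- if (dir == "over") stats::runif(1, 1, 1.5) else stats::runif(1, 0.6, 0.99)
        size <- observed + sample(5:50, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          go_id = id, p = p, or = or, expected = expected,
          observed = observed, size = size, direction = dir,
          stringsAsFactors = FALSE)
      }
      rows <- do.call(rbind, rows)
      as_table <- function(sub) {
        data.frame(
          GOBPID = sub$go_id,
          Pvalue = sub$p,
          OddsRatio = sub$or,
          ExpCount = sub$expected,
          Count = sub$observed,
          Size = sub$size,
          Term = term_label(sub$go_id),
          stringsAsFactors = FALSE
        )
      }
      analyses[[label]] <- list(
        over = as_table(rows[rows$direction == "over", , drop = FALSE]),
        under = as_table(rows[rows$direction == "under", , drop = FALSE])
      )
    }
    truth <- if (length(truth)) {
      do.call(rbind, truth)
    } else {
      data.frame(label = character(), go_id = character(),
                 direction = character(), fold_target = numeric(),
                 fold_realized = numeric(), expected = numeric(),
                 observed = numeric(), p_value = numeric(),
                 stringsAsFactors = FALSE)
    }
    list(analyses = analyses, truth = truth)
  })
}

#' The demo fixture preset
#'
#' A four-analysis layout emulating a two-genotype-by-two-dose design
#' against control: three planted signal terms in the biological-process
#' domain (two over-represented, one under-represented).
#'
#' @param seed Integer seed.
#' @return A `go_fixture_spec`.
#' @export
demo_spec <- function(seed = 7) {
  fixture_spec(
    n_terms = c(biological_process = 15, molecular_function = 6,
                cellular_component = 6),
    max_parents = 2,
    n_analyses = 4,
    signal_terms = data.frame(
      go_id = c("GO:0000006", "GO:0000009", "GO:0000012"),
      direction = c("over", "over", "under"),
      fold = c(4, 2.5, 0.25),
      stringsAsFactors = FALSE
    ),
    seed = seed
  )
}

DEMO_LABELS <- c("wildtype_low_dose", "disease_low_dose",
                 "wildtype_high_dose", "disease_high_dose")

#' Write a complete demo fixture set to a directory
#'
#' Emits `ontology.obo`, one `<label>_over.tsv` / `<label>_under.tsv` pair
#' per analysis, a `selection.txt` path-selection file covering every
#' planted signal term, and `truth.tsv` (the ground truth for checking).
#' Deterministic in `seed`: the same seed always writes identical files.
#'
#' @param dir Target directory (created if needed).
#' @param seed Integer seed.
#' @param spec Optional `go_fixture_spec`; default [demo_spec()].
#' @param labels Analysis labels; default the two-genotype-by-two-dose
#'   demo labels.
#' @return Invisibly, a list with the generated `spec`, `fixture`,
#'   `enrichment` and the written file paths.
#' @export
write_fixture_set <- function(dir, seed = 7, spec = NULL, labels = NULL) {
  if (is.null(spec)) spec <- demo_spec(seed)
  if (is.null(labels)) labels <- DEMO_LABELS[seq_len(spec$n_analyses)]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_ontology_fixture(spec)
  en <- make_enrichment_fixture(spec, fx, labels = labels)

  files <- character()
  obo_path <- file.path(dir, "ontology.obo")
  writeLines(fx$obo, obo_path)
  files <- c(files, obo_path)

  num <- function(x) formatC(x, format = "g", digits = 15)
  for (label in labels) {
    for (dir_name in c("over", "under")) {
      tab <- en$analyses[[label]][[dir_name]]
      tab$Pvalue <- num(tab$Pvalue)
      tab$OddsRatio <- num(tab$OddsRatio)
      tab$ExpCount <- num(tab$ExpCount)
      p <- file.path(dir, paste0(label, "_", dir_name, ".tsv"))
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, p)
    }
  }

  ont <- read_obo(text = fx$obo)
  paths <- list()
  for (id in unique(spec$signal_terms$go_id)) {
    ps <- enumerate_paths(ont, id)
    paths[[length(paths) + 1L]] <- ps[[1]]  # first path, lexicographic order
  }
  sel_path <- file.path(dir, "selection.txt")
  save_selection(selection(paths), sel_path)
  files <- c(files, sel_path)

  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(en$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, truth_path)

  invisible(list(spec = spec, fixture = fx, enrichment = en, files = files))
}
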