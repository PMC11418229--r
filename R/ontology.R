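#' @keywords internal
"_PACKAGE"

GO_NAMESPACES <- c("biological_process", "molecular_function", "cellular_component")
GO_PARENT_RELATIONS <- c("is_a", "part_of")

#' Read an OBO flat file into a three-domain ontology DAG
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 flat file into an in-memory
#' directed acyclic graph split across the three GO domains (biological
#' process, molecular function, cellular component).  `is_a` tags always
#' create parent edges; `relationship: part_of` creates one only when
#' `"part_of"` is included in `relations` (the default admits `is_a` only, so
#' edges can never leave a namespace).  Obsolete terms are kept in the index,
#' so result files citing them still resolve, but carry no edges and are
#' excluded from the domains' displayable sets.  `alt_id` tags populate an
#' alternate-id index used by [resolve_term()].  Cross-namespace or unknown
#' relationship tags (`regulates`, `consider`, ...) are ignored with a note on
#' stderr.  After import the parent graph is checked to be acyclic.
#'
#' @param path Path to an OBO file.  Gzip-compressed files are accepted (R's
#'   file connections decompress transparently).
#' @param text OBO content as a character scalar or vector of lines, as an
#'   alternative to `path`.
#' @param relations Character vector of relationship tags admitted as parent
#'   edges, a subset of `c("is_a", "part_of")`.
#' @return An object of class `go_ontology`: a list with elements `terms`
#'   (named list of term records: `id`, `name`, `namespace`, `parents`,
#'   `relations`, `children`, `alt_ids`, `obsolete`), `domains` (namespace ->
#'   ids), `alt_index` (alt id -> canonical id), `roots` (namespace -> ids
#'   with no parents), and `relations` (the admitted relation set).
#' @examples
#' fx <- diamond_obo()
#' ont <- read_obo(text = fx)
#' length(ont$terms)
#' @export
read_obo <- function(path = NULL, text = NULL, relations = "is_a") {
  if (is.null(path) == is.null(text)) {
    gs_error("gs_argument_error", "supply exactly one of `path` or `text`")
  }
  if (!all(relations %in% GO_PARENT_RELATIONS)) {
    gs_error("gs_argument_error", sprintf(
      "admitted relations must be a subset of {%s}",
      paste(GO_PARENT_RELATIONS, collapse = ", ")
    ))
  }
  lines <- if (!is.null(path)) {
    if (!file.exists(path)) {
      gs_error("gs_io_error", sprintf("OBO file not found: %s", path))
    }
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  parsed <- parse_obo_lines(lines)
  build_ontology(parsed$stanzas, parsed$header, relations)
}

# Split raw lines into the header and a list of raw [Term] stanzas.
# Each stanza keeps its starting line number for error reporting.
parse_obo_lines <- function(lines) {
  lines <- sub("\r$", "", lines)
  stanza_starts <- grep("^\\[", lines)
  header_end <- if (length(stanza_starts)) stanza_starts[1] - 1L else length(lines)
  header <- parse_tag_lines(lines[seq_len(header_end)])
  stanzas <- list()
  for (k in seq_along(stanza_starts)) {
    start <- stanza_starts[k]
    end <- if (k < length(stanza_starts)) stanza_starts[k + 1] - 1L else length(lines)
    kind <- lines[start]
    if (kind != "[Term]") next  # [Typedef] and friends are ignored
    body <- lines[(start + 1L):end]
    body <- body[nzchar(trimws(body))]
    stanzas[[length(stanzas) + 1L]] <- list(
      line = start,
      tags = parse_tag_lines(body)
    )
  }
  list(header = header, stanzas = stanzas)
}

# Parse "tag: value" lines into a list mapping tag -> character vector of
# values (tags may repeat).  Trailing OBO comments (" ! ...") are stripped.
parse_tag_lines <- function(lines) {
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_-]+):\\s*(.*)$", ln))[[1]]
    if (length(m) < 3) next
    tag <- m[2]
    value <- sub("\\s*!.*$", "", m[3])
    value <- trimws(value)
    out[[tag]] <- c(out[[tag]], value)
  }
  out
}

build_ontology <- function(stanzas, header, relations) {
  default_ns <- header[["default-namespace"]]
  default_ns <- if (!is.null(default_ns) && default_ns[1] %in% GO_NAMESPACES) {
    default_ns[1]
  } else {
    NULL
  }

  terms <- list()
  for (st in stanzas) {
    tags <- st$tags
    id <- tags[["id"]]
    if (is.null(id) || !nzchar(id[1])) {
      gs_error("gs_parse_error",
               sprintf("[Term] stanza at line %d has no id", st$line))
    }
    id <- id[1]
    ns <- if (!is.null(tags[["namespace"]])) tags[["namespace"]][1] else default_ns
    if (is.null(ns)) {
      gs_error("gs_parse_error",
               sprintf("term %s (line %d) has no namespace", id, st$line))
    }
    if (!ns %in% GO_NAMESPACES) {
      gs_error("gs_parse_error",
               sprintf("term %s (line %d): unknown namespace '%s'", id, st$line, ns))
    }
    obsolete <- identical(tags[["is_obsolete"]], "true")

    parents <- character()
    rels <- character()
    for (v in tags[["is_a"]]) {
      parents <- c(parents, v)
      rels <- c(rels, "is_a")
    }
    for (v in tags[["relationship"]]) {
      parts <- strsplit(trimws(v), "\\s+")[[1]]
      if (length(parts) < 2) next
      rel <- parts[1]
      tgt <- parts[2]
      if (!rel %in% relations) {
        if (rel %in% GO_PARENT_RELATIONS) {
          gs_note("relationship '", rel, "' not admitted for this load; ",
                  "edge ", id, " -> ", tgt, " ignored")
        } else {
          gs_note("ignoring non-parent relationship '", rel, "' on ", id)
        }
        next
      }
      parents <- c(parents, tgt)
      rels <- c(rels, rel)
    }
    if (obsolete && length(parents)) {
      gs_warning("gs_obsolete_edge_warning", sprintf(
        "obsolete term %s declares %d parent edge(s); dropped", id, length(parents)))
      parents <- character()
      rels <- character()
    }
    keep <- !duplicated(paste(parents, rels))
    parents <- parents[keep]
    rels <- rels[keep]

    if (!is.null(terms[[id]])) {
      gs_warning("gs_duplicate_stanza_warning",
                 sprintf("duplicate stanza for %s (line %d); last wins", id, st$line))
    }
    terms[[id]] <- list(
      id = id,
      name = if (!is.null(tags[["name"]])) tags[["name"]][1] else "",
      namespace = ns,
      parents = parents,
      relations = rels,
      children = character(),
      alt_ids = if (!is.null(tags[["alt_id"]])) unique(tags[["alt_id"]]) else character(),
      obsolete = obsolete
    )
  }

  # Drop edges whose parent is missing or sits in another namespace; the
  # invariant is that every retained parent lives in the same domain.
  for (id in names(terms)) {
    tm <- terms[[id]]
    if (!length(tm$parents)) next
    ok <- logical(length(tm$parents))
    for (j in seq_along(tm$parents)) {
      p <- tm$parents[j]
      pt <- terms[[p]]
      if (is.null(pt)) {
        gs_note("parent ", p, " of ", id, " not in ontology; edge dropped")
      } else if (pt$namespace != tm$namespace) {
        gs_note("cross-namespace edge ", id, " -> ", p, " dropped")
      } else if (pt$obsolete) {
        gs_note("edge ", id, " -> obsolete parent ", p, " dropped")
      } else {
        ok[j] <- TRUE
      }
    }
    terms[[id]]$parents <- tm$parents[ok]
    terms[[id]]$relations <- tm$relations[ok]
  }

  alt_index <- character()
  for (tm in terms) {
    for (alt in tm$alt_ids) {
      if (!is.null(terms[[alt]])) {
        gs_note("alt_id ", alt, " of ", tm$id, " shadows a primary id; ignored")
        next
      }
      alt_index[[alt]] <- tm$id
    }
  }

  domains <- lapply(stats::setNames(nm = GO_NAMESPACES), function(ns) {
    ids <- vapply(terms, function(t) t$namespace == ns && !t$obsolete, logical(1))
    names(terms)[ids]
  })

  ont <- structure(
    list(
      terms = terms,
      domains = domains,
      alt_index = alt_index,
      roots = list(),
      relations = relations
    ),
    class = "go_ontology"
  )
  ont <- link_children(ont)
  ont$roots <- lapply(domains, function(ids) {
    ids[vapply(ont$terms[ids], function(t) length(t$parents) == 0L, logical(1))]
  })
  assert_acyclic(ont)
  ont
}

#' Derive child links from parent edges
#'
#' Recomputes every term's `children` set as the exact inverse of the parent
#' edges.  Pure and idempotent; [read_obo()] calls it automatically, it is
#' exported so rebuilt or hand-assembled ontologies can be relinked.
#'
#' @param ontology A `go_ontology`.
#' @return The ontology with `children` repopulated.
#' @export
link_children <- function(ontology) {
  children <- lapply(ontology$terms, function(t) character())
  for (tm in ontology$terms) {
    for (p in tm$parents) {
      children[[p]] <- c(children[[p]], tm$id)
    }
  }
  for (id in names(ontology$terms)) {
    ontology$terms[[id]]$children <- sort(unique(children[[id]]))
  }
  ontology
}

# Kahn's algorithm over parent edges; on failure, walks one cycle and
# reports it.
assert_acyclic <- function(ontology) {
  ids <- names(ontology$terms)
  indeg <- vapply(ontology$terms, function(t) length(t$parents), integer(1))
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in ontology$terms[[id]]$children) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    remaining <- ids[indeg > 0L]
    cycle <- find_cycle(ontology, remaining)
    gs_error("gs_structure_error",
             sprintf("parent graph contains a cycle: %s",
                     paste(cycle, collapse = " -> ")),
             data = list(cycle = cycle))
  }
  invisible(ontology)
}

find_cycle <- function(ontology, candidates) {
  start <- candidates[1]
  path <- character()
  cur <- start
  repeat {
    if (cur %in% path) {
      i <- match(cur, path)
      return(c(path[i:length(path)], cur))
    }
    path <- c(path, cur)
    ps <- ontology$terms[[cur]]$parents
    ps <- ps[ps %in% candidates]
    cur <- ps[1]
  }
}

#' Resolve a primary or alternate GO id to its term
#'
#' Lookup is namespace-agnostic: the id is first tried as a primary id, then
#' through the alternate-id index (merged ids cited by older result files).
#'
#' @param ontology A `go_ontology`.
#' @param id A GO identifier string.
#' @return The term record (a list; see [read_obo()]).
#' @export
resolve_term <- function(ontology, id) {
  tm <- ontology$terms[[id]]
  if (!is.null(tm)) return(tm)
  canon <- unname(ontology$alt_index[id])
  if (length(canon) == 1L && !is.na(canon)) return(ontology$terms[[canon]])
  gs_error("gs_lookup_error", sprintf("unknown GO id: %s", id),
           data = list(id = id))
}

# resolve to canonical id, or NA (no error) -- used by attach()
resolve_id_or_na <- function(ontology, id) {
  if (!is.null(ontology$terms[[id]])) return(id)
  canon <- unname(ontology$alt_index[id])
  if (length(canon) == 1L && !is.na(canon)) return(canon)
  NA_character_
}

#' Serialize an ontology back to OBO text
#'
#' Emits a minimal OBO 1.2 document (header plus one `[Term]` stanza per
#' term, sorted by id) whose re-parse yields an identical term and edge set.
#' Intended for round-trip testing and for persisting fixture ontologies.
#'
#' @param ontology A `go_ontology`.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The OBO text as a single string (invisibly when written to `path`).
#' @export
write_obo <- function(ontology, path = NULL) {
  out <- c("format-version: 1.2", "ontology: go", "")
  for (id in sort(names(ontology$terms))) {
    tm <- ontology$terms[[id]]
    st <- c("[Term]",
            paste0("id: ", tm$id),
            paste0("name: ", tm$name),
            paste0("namespace: ", tm$namespace))
    for (alt in sort(tm$alt_ids)) st <- c(st, paste0("alt_id: ", alt))
    if (tm$obsolete) st <- c(st, "is_obsolete: true")
    if (length(tm$parents)) {
      ord <- order(tm$parents)
      for (j in ord) {
        if (tm$relations[j] == "is_a") {
          st <- c(st, paste0("is_a: ", tm$parents[j]))
        } else {
          st <- c(st, paste0("relationship: ", tm$relations[j], " ", tm$parents[j]))
        }
      }
    }
    out <- c(out, st, "")
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' @export
print.go_ontology <- function(x, ...) {
  n_edges <- sum(vapply(x$terms, function(t) length(t$parents), integer(1)))
  cat("go_ontology:", length(x$terms), "terms,", n_edges, "parent edges\n")
  for (ns in GO_NAMESPACES) {
    cat(sprintf("  %-20s %5d terms, %d root(s)\n", ns,
                length(x$domains[[ns]]), length(x$roots[[ns]])))
  }
  if (length(x$alt_index)) cat("  alt ids:", length(x$alt_index), "\n")
  invisible(x)
}

# Total number of parent edges (used by summaries and the CLI).
ontology_edge_count <- function(ontology) {
  sum(vapply(ontology$terms, function(t) length(t$parents), integer(1)))
}

# namespace of a (resolvable) id
term_namespace <- function(ontology, id) {
  resolve_term(ontology, id)$namespace
}
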