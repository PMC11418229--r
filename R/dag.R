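# Graph computations over the parent DAG: path enumeration and counting,
# ancestors/descendants, depth, nearest common ancestor, term search.
# Paths run root -> term along parent->child edges; a term with several
# parents lies on several paths, so enumeration is capped and counting uses
# the memoized recurrence N(t) = 1 for roots, else sum over parents of N(p).

#' Enumerate all root-to-term paths
#'
#' Returns every distinct path from a root of the term's namespace down to
#' `target`, each as a character vector of GO ids ordered root first.  Output
#' order is lexicographic over the id sequences, so repeated calls (and
#' golden files built from them) are stable.  Because a term's path count can
#' grow combinatorially with fan-in, enumeration refuses to materialize more
#' than `max_paths` paths; [count_paths_to()] is O(V+E) and should be used to
#' size a query first.
#'
#' @param ontology A `go_ontology`.
#' @param target A GO id (primary or alternate).
#' @param max_paths Hard cap on the number of materialized paths.
#' @return A list of character vectors, each a root-to-target id sequence.
#' @examples
#' ont <- read_obo(text = diamond_obo())
#' enumerate_paths(ont, "GO:0000005")
#' @export
enumerate_paths <- function(ontology, target, max_paths = 10000) {
  tm <- resolve_term(ontology, target)
  if (tm$obsolete) {
    gs_error("gs_argument_error",
             sprintf("term %s is obsolete and lies on no path", tm$id))
  }
  n <- count_paths_to(ontology, tm$id)
  if (n > max_paths) {
    gs_error("gs_cap_error", sprintf(
      "term %s lies on %.0f paths, above the cap of %d; raise `max_paths`",
      tm$id, n, max_paths), data = list(count = n, cap = max_paths))
  }
  paths <- enumerate_paths_rec(ontology, tm$id)
  keys <- vapply(paths, paste, character(1), collapse = ">")
  paths[order(keys, method = "radix")]
}

enumerate_paths_rec <- function(ontology, id) {
  parents <- ontology$terms[[id]]$parents
  if (!length(parents)) return(list(id))
  out <- list()
  for (p in sort(parents)) {
    for (pp in enumerate_paths_rec(ontology, p)) {
      out[[length(out) + 1L]] <- c(pp, id)
    }
  }
  out
}

#' Count root-to-term paths without enumerating them
#'
#' Evaluates the recurrence N(t) = 1 if t is a root, else the sum of N over
#' t's parents, memoized so each term is visited once.  Agrees exactly with
#' `length(enumerate_paths(ontology, target))` wherever the enumeration is
#' materializable.
#'
#' @inheritParams enumerate_paths
#' @return A nonnegative number (double: counts can exceed integer range on
#'   a full GO release).
#' @export
count_paths_to <- function(ontology, target) {
  tm <- resolve_term(ontology, target)
  memo <- new.env(parent = emptyenv())
  count_paths_rec(ontology, tm$id, memo)
}

count_paths_rec <- function(ontology, id, memo) {
  got <- memo[[id]]
  if (!is.null(got)) return(got)
  parents <- ontology$terms[[id]]$parents
  n <- if (!length(parents)) {
    1
  } else {
    sum(vapply(parents, function(p) count_paths_rec(ontology, p, memo),
               numeric(1)))
  }
  memo[[id]] <- n
  n
}

#' Count all unique root-to-leaf paths in one domain
#'
#' Sums [count_paths_to()] over every childless, non-obsolete term of the
#' namespace.  On a full GO release this is the "unique paths across the
#' DAG" figure; on toy fixtures it is exactly the number of distinct
#' root-to-leaf traversals.
#'
#' @param ontology A `go_ontology`.
#' @param namespace One of `"biological_process"`, `"molecular_function"`,
#'   `"cellular_component"`.
#' @return A nonnegative number.
#' @export
count_leaf_paths <- function(ontology, namespace) {
  namespace <- match.arg(namespace, GO_NAMESPACES)
  ids <- ontology$domains[[namespace]]
  memo <- new.env(parent = emptyenv())
  leaves <- ids[vapply(ontology$terms[ids],
                       function(t) length(t$children) == 0L, logical(1))]
  sum(vapply(leaves, function(id) count_paths_rec(ontology, id, memo),
             numeric(1)))
}

#' Ancestors, descendants and depth of a term
#'
#' `term_ancestors()` returns the transitive closure of the parent edges
#' (excluding the term itself); `term_descendants()` the closure of the child
#' links; `term_depth()` the length in edges of the LONGEST root-to-term
#' path, matching the GO community's "term level" usage.
#'
#' @inheritParams enumerate_paths
#' @param id A GO id (primary or alternate).
#' @return A character vector of ids (sorted), or a nonnegative integer for
#'   `term_depth()`.
#' @export
term_ancestors <- function(ontology, id) {
  tm <- resolve_term(ontology, id)
  seen <- character()
  frontier <- tm$parents
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(ontology$terms[new], `[[`, "parents"),
                              use.names = FALSE))
  }
  sort(seen)
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(ontology, id) {
  tm <- resolve_term(ontology, id)
  seen <- character()
  frontier <- tm$children
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(ontology$terms[new], `[[`, "children"),
                              use.names = FALSE))
  }
  sort(seen)
}

#' @rdname term_ancestors
#' @export
term_depth <- function(ontology, id) {
  tm <- resolve_term(ontology, id)
  memo <- new.env(parent = emptyenv())
  depth_rec(ontology, tm$id, memo)
}

depth_rec <- function(ontology, id, memo) {
  got <- memo[[id]]
  if (!is.null(got)) return(got)
  parents <- ontology$terms[[id]]$parents
  d <- if (!length(parents)) {
    0L
  } else {
    1L + max(vapply(parents, function(p) depth_rec(ontology, p, memo),
                    integer(1)))
  }
  memo[[id]] <- d
  d
}

#' Nearest common ancestor(s) of a set of terms
#'
#' The candidates are the intersection over the query ids of each id's
#' ancestors plus the id itself; all candidates of maximal depth are
#' returned, sorted by id (a DAG can have several equally deep common
#' ancestors).  A singleton query returns that id.
#'
#' @param ontology A `go_ontology`.
#' @param ids Character vector of GO ids, all in one namespace.
#' @return Character vector of the deepest common ancestor id(s).
#' @examples
#' ont <- read_obo(text = diamond_obo())
#' nearest_common_ancestor(ont, c("GO:0000002", "GO:0000003"))
#' @export
nearest_common_ancestor <- function(ontology, ids) {
  if (!length(ids)) {
    gs_error("gs_argument_error", "need at least one id for an NCA query")
  }
  canon <- vapply(ids, function(i) resolve_term(ontology, i)$id, character(1))
  canon <- unique(unname(canon))
  ns <- vapply(canon, function(i) ontology$terms[[i]]$namespace, character(1))
  if (length(unique(ns)) > 1L) {
    gs_error("gs_domain_error", sprintf(
      "NCA query spans namespaces: %s", paste(unique(ns), collapse = ", ")))
  }
  if (length(canon) == 1L) return(canon)
  cand <- Reduce(intersect, lapply(canon, function(i) {
    c(term_ancestors(ontology, i), i)
  }))
  if (!length(cand)) return(character())
  memo <- new.env(parent = emptyenv())
  depths <- vapply(cand, function(i) depth_rec(ontology, i, memo), integer(1))
  sort(cand[depths == max(depths)])
}

#' Search terms by id or name
#'
#' An exact id match (primary or alternate) is returned on its own;
#' otherwise a case-insensitive substring match over term names is run and
#' hits are sorted by (name length, id), so the most specific-name-first
#' convention of short exact-ish hits leading applies.  Obsolete terms are
#' not searched.  An empty result is valid.
#'
#' @param ontology A `go_ontology`.
#' @param query Search text: a GO id or a name fragment.
#' @return Character vector of GO ids (possibly empty).
#' @export
search_terms <- function(ontology, query) {
  hit <- tryCatch(resolve_term(ontology, query)$id, gs_lookup_error = function(e) NULL)
  if (!is.null(hit)) return(hit)
  ids <- unlist(ontology$domains, use.names = FALSE)
  names <- vapply(ontology$terms[ids], `[[`, character(1), "name")
  keep <- grepl(tolower(query), tolower(names), fixed = TRUE)
  ids <- ids[keep]
  names <- names[keep]
  ids[order(nchar(names), ids, method = "radix")]
}
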