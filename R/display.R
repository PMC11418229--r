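# Display model: tree node states, the ordered/indented row structure of the
# comparison figure, and the versioned path-selection file format.

SELECTION_HEADER <- "#gotermpaths v1"

#' Classify terms by enrichment-data availability
#'
#' Mirrors the three tree-node icons of the viewer: a term with its own
#' record in at least one analysis is `HAS_DATA` (green disc); a term with
#' no record of its own but at least one annotated descendant is
#' `DESCENDANT_HAS_DATA` (green circle); everything else is `NO_DATA`
#' (pink disc, hidden by default in the tree).  Computed in one
#' reverse-topological sweep; `HAS_DATA` dominates.
#'
#' @param ontology A `go_ontology`.
#' @param annotation A `go_annotation` from [attach_enrichment()].
#' @return Named character vector over all non-obsolete terms with values
#'   in `c("HAS_DATA", "DESCENDANT_HAS_DATA", "NO_DATA")`.
#' @export
node_states <- function(ontology, annotation) {
  ids <- unlist(ontology$domains, use.names = FALSE)
  has_own <- ids %in% annotated_ids(annotation)
  names(has_own) <- ids
  state <- stats::setNames(rep("NO_DATA", length(ids)), ids)

  order <- topological_order(ontology, ids)
  for (id in rev(order)) {  # children visited before parents
    if (has_own[[id]]) {
      state[[id]] <- "HAS_DATA"
      next
    }
    kids <- ontology$terms[[id]]$children
    if (length(kids) && any(state[kids] != "NO_DATA")) {
      state[[id]] <- "DESCENDANT_HAS_DATA"
    }
  }
  state
}

# parents-before-children order over the given ids (Kahn)
topological_order <- function(ontology, ids) {
  indeg <- vapply(ontology$terms[ids], function(t) length(t$parents), integer(1))
  names(indeg) <- ids
  queue <- ids[indeg == 0L]
  out <- character(length(ids))
  k <- 0L
  while (length(queue)) {
    id <- queue[[1]]
    queue <- queue[-1]
    k <- k + 1L
    out[k] <- id
    for (ch in ontology$terms[[id]]$children) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out[seq_len(k)]
}

#' Build a path selection
#'
#' A selection is the user's ordered list of root-to-term paths plus the
#' flag controlling whether non-terminal (parent) rows show their
#' enrichment glyphs.
#'
#' @param paths List of character vectors of GO ids (each a root-to-term
#'   path) or strings of ids joined by `">"`.
#' @param show_parent_data Render glyphs for non-terminal rows (default on).
#'   When off, parent rows keep their labels (the indentation structure must
#'   stay readable) but carry no glyphs.
#' @return An object of class `go_selection`.
#' @export
selection <- function(paths = list(), show_parent_data = TRUE) {
  paths <- lapply(paths, function(p) {
    if (is.character(p) && length(p) == 1L && grepl(">", p, fixed = TRUE)) {
      strsplit(p, ">", fixed = TRUE)[[1]]
    } else {
      as.character(p)
    }
  })
  structure(list(paths = paths, show_parent_data = isTRUE(show_parent_data)),
            class = "go_selection")
}

# Validate each path against the ontology; returns list(valid = selection of
# valid paths, failures = character vector of human-readable failures).
validate_selection <- function(sel, ontology) {
  failures <- character()
  valid <- list()
  for (p in sel$paths) {
    bad <- NULL
    for (i in seq_along(p)) {
      known <- tryCatch({resolve_term(ontology, p[i]); TRUE},
                        gs_lookup_error = function(e) FALSE)
      if (!known) {
        bad <- sprintf("unknown term %s", p[i])
        break
      }
    }
    if (is.null(bad)) {
      canon <- vapply(p, function(i) resolve_term(ontology, i)$id, character(1))
      canon <- unname(canon)
      if (length(ontology$terms[[canon[1]]]$parents)) {
        bad <- sprintf("%s is not a root", canon[1])
      } else if (length(canon) > 1L) {
        for (i in 2:length(canon)) {
          if (!canon[i - 1] %in% ontology$terms[[canon[i]]]$parents) {
            bad <- sprintf("edge %s>%s not in ontology", canon[i - 1], canon[i])
            break
          }
        }
      }
      if (is.null(bad)) {
        valid[[length(valid) + 1L]] <- canon
        next
      }
    }
    failures <- c(failures, bad)
  }
  list(valid = selection(valid, sel$show_parent_data), failures = failures)
}

#' Expand a selection into the figure's ordered display rows
#'
#' Paths are processed in selection order; within a path the indent grows by
#' one per step.  A leading prefix shared with the immediately preceding
#' path is emitted only once, so sibling paths read as one indented block; a
#' term reached along several selected paths still yields one row per path
#' (the DAG means a term can legitimately appear several times).  When the
#' selection's `show_parent_data` is off, non-terminal rows keep their label
#' but carry empty per-analysis entries.
#'
#' @param sel A `go_selection`.
#' @param ontology A `go_ontology`.
#' @param annotation A `go_annotation`.
#' @return A list of display rows, each a list with `go_id`, `label`,
#'   `indent`, `terminal`, and `per_analysis` (one entry per analysis label,
#'   each `list(record, significant, fold)` with `NULL`/`NA` when absent).
#' @export
assemble_rows <- function(sel, ontology, annotation) {
  stopifnot(inherits(sel, "go_selection"))
  chk <- validate_selection(sel, ontology)
  if (length(chk$failures)) {
    gs_error("gs_stale_selection_error",
             paste0("selection no longer valid: ",
                    paste(chk$failures, collapse = "; ")),
             data = list(failures = chk$failures))
  }
  rows <- list()
  prev <- character()
  for (p in chk$valid$paths) {
    common <- common_prefix_length(prev, p)
    if (common == length(p)) common <- length(p) - 1L  # re-emit the terminal
    for (i in (common + 1L):length(p)) {
      id <- p[i]
      terminal <- i == length(p)
      with_data <- sel$show_parent_data || terminal
      per <- lapply(annotation$labels, function(label) {
        rec <- if (with_data) annotation_record(annotation, id, label) else NULL
        if (is.null(rec)) {
          list(record = NULL, significant = NA, fold = NA_real_)
        } else {
          list(record = rec, significant = rec$significant, fold = rec$fold)
        }
      })
      names(per) <- annotation$labels
      rows[[length(rows) + 1L]] <- list(
        go_id = id,
        label = ontology$terms[[id]]$name,
        indent = i - 1L,
        terminal = terminal,
        per_analysis = per
      )
    }
    prev <- p
  }
  rows
}

common_prefix_length <- function(a, b) {
  n <- min(length(a), length(b))
  if (!n) return(0L)
  same <- a[seq_len(n)] == b[seq_len(n)]
  if (all(same)) n else which.min(same) - 1L
}

#' Save / load a path selection file
#'
#' The format is versioned plain text: a `#gotermpaths v1` header line, an
#' optional `#show_parent_data: true|false` line, then one path per line as
#' GO ids joined by `">"`.  The file is ontology-release-agnostic; every
#' edge is validated against the CURRENT ontology at load, and a selection
#' citing edges that no longer exist raises a stale-selection error that
#' lists every failure while carrying the still-valid remainder (so callers
#' can continue with a partial figure).
#'
#' @param sel A `go_selection`.
#' @param path File path.
#' @return `save_selection()`: `path` invisibly.  `load_selection()`: a
#'   validated `go_selection`.
#' @export
save_selection <- function(sel, path) {
  stopifnot(inherits(sel, "go_selection"))
  lines <- c(
    SELECTION_HEADER,
    paste0("#show_parent_data: ", if (sel$show_parent_data) "true" else "false"),
    vapply(sel$paths, paste, character(1), collapse = ">")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_selection
#' @param ontology A `go_ontology` to validate against.
#' @export
load_selection <- function(path, ontology) {
  if (!file.exists(path)) {
    gs_error("gs_io_error", sprintf("selection file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (!length(lines) || trimws(lines[1]) != SELECTION_HEADER) {
    gs_error("gs_version_error", sprintf(
      "unrecognized selection file version (expected header '%s')",
      SELECTION_HEADER))
  }
  body <- lines[-1]
  show_parent <- TRUE
  meta <- grep("^#", body)
  for (i in meta) {
    m <- regmatches(body[i], regexec("^#show_parent_data:\\s*(true|false)\\s*$", body[i]))[[1]]
    if (length(m) == 2L) show_parent <- identical(m[2], "true")
  }
  body <- body[setdiff(seq_along(body), meta)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  sel <- selection(as.list(body), show_parent_data = show_parent)
  chk <- validate_selection(sel, ontology)
  if (length(chk$failures)) {
    gs_error("gs_stale_selection_error",
             paste0("selection file cites paths absent from this ontology: ",
                    paste(chk$failures, collapse = "; ")),
             data = list(failures = chk$failures, valid = chk$valid))
  }
  chk$valid
}

#' @export
print.go_selection <- function(x, ...) {
  cat("go_selection:", length(x$paths), "path(s), show_parent_data =",
      x$show_parent_data, "\n")
  for (p in x$paths) cat(" ", paste(p, collapse = ">"), "\n")
  invisible(x)
}
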