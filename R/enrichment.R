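# Ingestion of GOstats hyperGTest summary tables, combination of the over-
# and under-representation directions into one record set per analysis, fold
# change, significance and attachment of records to ontology terms.

GOSTATS_COLUMNS <- c("Pvalue", "OddsRatio", "ExpCount", "Count", "Size", "Term")

#' Read a GOstats hyperGTest summary table
#'
#' Accepts the delimited layout produced by `summary()` on a GOstats
#' hyperGTest result: an id column named like `GOBPID`/`GOMFID`/`GOCCID` (or
#' plain `GOID`), plus `Pvalue`, `OddsRatio`, `ExpCount`, `Count`, `Size` and
#' `Term`, matched case-insensitively.  The delimiter is auto-detected
#' between tab and comma.  `Inf` odds ratios (GOstats emits them when the
#' 2x2 table has a zero cell) are accepted.  An optional `Direction` column
#' (values `over`/`under`) overrides the `direction` argument row-wise, so
#' combined single-file-per-analysis tables written by
#' [write_combined()] read back losslessly.
#'
#' @param path Path to a delimited text file (alternative to `text`).
#' @param text Table content as a character scalar (alternative to `path`).
#' @param direction Direction of the enrichment test this table came from:
#'   `"over"`, `"under"`, or `"infer"` for a combined table lacking a
#'   `Direction` column (a row is then `under` exactly when its odds ratio
#'   is below 1).  Ignored for rows with a `Direction` column.
#' @return A data frame of enrichment records with columns `go_id`,
#'   `p_value`, `odds_ratio`, `expected_count`, `observed_count`,
#'   `gene_set_size`, `term_name`, `direction`.
#' @export
read_gostats <- function(path = NULL, text = NULL,
                         direction = c("over", "under", "infer")) {
  direction <- match.arg(direction)
  if (is.null(path) == is.null(text)) {
    gs_error("gs_argument_error", "supply exactly one of `path` or `text`")
  }
  lines <- if (!is.null(path)) {
    if (!file.exists(path)) {
      gs_error("gs_io_error", sprintf("enrichment table not found: %s", path))
    }
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    gs_error("gs_format_error", "enrichment table is empty (no header row)")
  }
  sep <- detect_delimiter(lines[1])
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  names(df) <- trimws(names(df))

  id_col <- grep("^GO[A-Z]*ID$", names(df), value = TRUE)
  if (!length(id_col)) {
    gs_error("gs_format_error",
             "no GO id column (expected a header matching GO[A-Z]*ID)")
  }
  id_col <- id_col[1]
  col_of <- function(wanted) {
    hit <- which(tolower(names(df)) == tolower(wanted))
    if (!length(hit)) {
      gs_error("gs_format_error", sprintf("missing mandatory column: %s", wanted))
    }
    names(df)[hit[1]]
  }
  cols <- vapply(GOSTATS_COLUMNS, col_of, character(1))

  n <- nrow(df)
  parse_num <- function(values, what, integer = FALSE) {
    values <- trimws(values)
    out <- suppressWarnings(as.numeric(values))
    out[values %in% c("Inf", "inf", "INF")] <- Inf
    bad <- which(is.na(out) & !is.na(values))
    if (length(bad)) {
      gs_error("gs_format_error", sprintf(
        "unparseable %s value '%s' at data row %d", what, values[bad[1]], bad[1]),
        data = list(rows = bad))
    }
    if (integer) out <- as.integer(round(out))
    out
  }

  rec <- data.frame(
    go_id = trimws(df[[id_col]]),
    p_value = if (n) parse_num(df[[cols[["Pvalue"]]]], "Pvalue") else numeric(),
    odds_ratio = if (n) parse_num(df[[cols[["OddsRatio"]]]], "OddsRatio") else numeric(),
    expected_count = if (n) parse_num(df[[cols[["ExpCount"]]]], "ExpCount") else numeric(),
    observed_count = if (n) parse_num(df[[cols[["Count"]]]], "Count", integer = TRUE) else integer(),
    gene_set_size = if (n) parse_num(df[[cols[["Size"]]]], "Size", integer = TRUE) else integer(),
    term_name = if (n) as.character(df[[cols[["Term"]]]]) else character(),
    stringsAsFactors = FALSE
  )
  dir_col <- which(tolower(names(df)) == "direction")
  rec$direction <- if (length(dir_col) && n) {
    tolower(trimws(df[[dir_col[1]]]))
  } else if (direction == "infer") {
    ifelse(rec$odds_ratio < 1, "under", "over")
  } else {
    rep(direction, n)
  }
  bad_dir <- which(!rec$direction %in% c("over", "under"))
  if (length(bad_dir)) {
    gs_error("gs_format_error", sprintf(
      "invalid Direction value '%s' at data row %d", rec$direction[bad_dir[1]], bad_dir[1]))
  }
  bad_p <- which(rec$p_value < 0 | rec$p_value > 1)
  if (length(bad_p)) {
    gs_error("gs_format_error", sprintf(
      "Pvalue out of [0,1] at data row %d", bad_p[1]))
  }
  rec
}

detect_delimiter <- function(header_line) {
  n_tab <- lengths(regmatches(header_line, gregexpr("\t", header_line, fixed = TRUE)))
  n_comma <- lengths(regmatches(header_line, gregexpr(",", header_line, fixed = TRUE)))
  if (n_tab >= n_comma && n_tab > 0) "\t" else if (n_comma > 0) "," else "\t"
}

#' Combine over- and under-representation tables into one record set
#'
#' GOstats reports the two test directions separately; for display they are
#' merged into a single record set per analysis.  The default (`"min_p"`)
#' keeps, for a term present in both directions, the record with the smaller
#' P value (ties go to the over-representation record); `"concat"` keeps
#' both records, distinguished by their `direction` field.
#'
#' @param over,under Data frames from [read_gostats()].
#' @param policy `"min_p"` (default) or `"concat"`.
#' @return A data frame of records; under `"min_p"` one row per GO id.
#' @export
combine_over_under <- function(over, under, policy = c("min_p", "concat")) {
  policy <- match.arg(policy)
  both <- rbind(over, under)
  if (policy == "concat" || !nrow(both)) {
    rownames(both) <- NULL
    return(both)
  }
  # stable order: over rows first, so ties on p keep the over record
  both <- both[order(match(both$go_id, both$go_id)), , drop = FALSE]
  keep <- logical(nrow(both))
  for (id in unique(both$go_id)) {
    rows <- which(both$go_id == id)
    best <- rows[which.min(both$p_value[rows])]  # first minimum: over wins ties
    keep[best] <- TRUE
  }
  out <- both[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold change of observed over expected gene counts
#'
#' Because the number of differentially expressed genes differs between
#' analyses, raw observed/expected counts are not comparable across panels;
#' their ratio is.  Over-represented terms typically give a value above 1,
#' under-represented terms below 1 (the ratio is kept as-is rather than
#' reciprocated, so one monotone axis serves both directions); 0 is valid
#' (a fully depleted term).
#'
#' @param observed_count Nonnegative observed count(s).
#' @param expected_count Positive expected count(s).
#' @return `observed_count / expected_count`, vectorized.
#' @export
fold_change <- function(observed_count, expected_count) {
  if (any(expected_count == 0)) {
    gs_error("gs_undefined_fold_error",
             "fold change undefined where the expected count is 0")
  }
  observed_count / expected_count
}

#' Multiple-testing adjustment for one analysis
#'
#' `adjusted_p()` applies the chosen correction over all records of one
#' analysis (both directions pooled, as combined by [combine_over_under()]);
#' `"benjamini_hochberg"` is the standard step-up FDR procedure.
#'
#' @param p Numeric vector of raw P values.
#' @param mode `"none"` or `"benjamini_hochberg"`.
#' @return Numeric vector of adjusted P values, same order as `p`.
#' @export
adjusted_p <- function(p, mode = c("none", "benjamini_hochberg")) {
  mode <- match.arg(mode)
  switch(mode,
         none = p,
         benjamini_hochberg = stats::p.adjust(p, method = "BH"))
}

#' Significance of enrichment records
#'
#' A record is significant when its (raw or adjusted, per `adjust`) P value
#' is strictly below `alpha`; a record at exactly `alpha` is not significant.
#'
#' @param records Data frame of records for ONE analysis (the adjustment
#'   pools all of its rows).
#' @param alpha Significance threshold in (0, 1).
#' @param adjust `"none"` (default; GOstats reports raw hypergeometric P
#'   values) or `"benjamini_hochberg"`.
#' @return Logical vector along the rows of `records`.
#' @export
is_significant <- function(records, alpha = 0.05, adjust = c("none", "benjamini_hochberg")) {
  adjust <- match.arg(adjust)
  if (!(alpha > 0 && alpha < 1)) {
    gs_error("gs_argument_error", "alpha must lie strictly between 0 and 1")
  }
  adjusted_p(records$p_value, adjust) < alpha
}

#' Bundle analyses into an ordered analysis set
#'
#' The order of `analyses` is preserved end to end: it defines the column
#' order of the rendered figure's panels.
#'
#' @param analyses Named list (label -> record data frame from
#'   [read_gostats()] / [combine_over_under()]).  Labels must be unique.
#' @param alpha Significance threshold, default 0.05.
#' @param adjust Multiple-testing mode, `"none"` or `"benjamini_hochberg"`.
#' @return An object of class `go_analysis_set`.
#' @export
analysis_set <- function(analyses, alpha = 0.05, adjust = c("none", "benjamini_hochberg")) {
  adjust <- match.arg(adjust)
  if (!length(analyses)) {
    gs_error("gs_argument_error", "need at least one analysis")
  }
  labels <- names(analyses)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    gs_error("gs_argument_error", "analyses must carry unique non-empty labels")
  }
  if (!(alpha > 0 && alpha < 1)) {
    gs_error("gs_argument_error", "alpha must lie strictly between 0 and 1")
  }
  structure(list(analyses = analyses, alpha = alpha, adjust = adjust),
            class = "go_analysis_set")
}

#' Attach enrichment records to ontology terms
#'
#' Record ids are resolved through the ontology's primary and alternate id
#' indexes and filed under their canonical id; significance and fold change
#' are precomputed per record.  Ids that resolve nowhere are collected into
#' an unmatched report (never dropped silently).  Records whose expected
#' count is 0 keep an `NA` fold change (rendered as an absent bar).
#'
#' @param ontology A `go_ontology`.
#' @param aset A `go_analysis_set`.
#' @return An object of class `go_annotation`: list with `labels`, `alpha`,
#'   `adjust`, `index` (canonical id -> label -> record row as a list) and
#'   `unmatched` (data frame label/go_id).
#' @export
attach_enrichment <- function(ontology, aset) {
  stopifnot(inherits(aset, "go_analysis_set"))
  index <- new.env(parent = emptyenv())
  unmatched <- list()
  for (label in names(aset$analyses)) {
    records <- aset$analyses[[label]]
    if (!nrow(records)) next
    sig <- is_significant(records, aset$alpha, aset$adjust)
    folds <- ifelse(records$expected_count > 0,
                    records$observed_count / records$expected_count, NA_real_)
    if (any(records$expected_count == 0)) {
      gs_note("analysis '", label, "': ",
              sum(records$expected_count == 0),
              " record(s) with ExpCount 0; fold change undefined there")
    }
    for (i in seq_len(nrow(records))) {
      canon <- resolve_id_or_na(ontology, records$go_id[i])
      if (is.na(canon)) {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(label = label, go_id = records$go_id[i],
                     stringsAsFactors = FALSE)
        next
      }
      slot <- index[[canon]]
      if (is.null(slot)) slot <- list()
      rec <- as.list(records[i, , drop = FALSE])
      rec$go_id <- canon
      rec$significant <- sig[i]
      rec$fold <- folds[i]
      slot[[label]] <- rec
      index[[canon]] <- slot
    }
  }
  unmatched <- if (length(unmatched)) {
    do.call(rbind, unmatched)
  } else {
    data.frame(label = character(), go_id = character(), stringsAsFactors = FALSE)
  }
  structure(list(
    labels = names(aset$analyses),
    alpha = aset$alpha,
    adjust = aset$adjust,
    index = index,
    unmatched = unmatched
  ), class = "go_annotation")
}

# Record for one (term, analysis), or NULL.
annotation_record <- function(annotation, go_id, label) {
  slot <- annotation$index[[go_id]]
  if (is.null(slot)) return(NULL)
  slot[[label]]
}

# ids carrying at least one record
annotated_ids <- function(annotation) {
  ls(annotation$index)
}

#' Write a combined single-file-per-analysis results table
#'
#' Emits the GOstats summary columns plus a `Direction` column as
#' tab-delimited text; [read_gostats()] reads it back losslessly.
#'
#' @param records Data frame of records (one analysis).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_combined <- function(records, path) {
  out <- data.frame(
    GOID = records$go_id,
    Pvalue = records$p_value,
    OddsRatio = records$odds_ratio,
    ExpCount = records$expected_count,
    Count = records$observed_count,
    Size = records$gene_set_size,
    Term = records$term_name,
    Direction = records$direction,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the unmatched-id report of an annotation
#'
#' @param annotation A `go_annotation`.
#' @param path Output file path (tab-delimited, columns label/go_id).
#' @return `path`, invisibly.
#' @export
write_unmatched <- function(annotation, path) {
  utils::write.table(annotation$unmatched, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("go_annotation:", length(x$labels), "analyses (",
      paste(x$labels, collapse = ", "), ")\n")
  cat("  annotated terms:", length(annotated_ids(x)), "\n")
  cat("  unmatched ids:  ", nrow(x$unmatched), "\n")
  cat("  alpha:", x$alpha, " adjust:", x$adjust, "\n")
  invisible(x)
}
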