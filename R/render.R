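# Deterministic SVG rendering of display rows: one label column on the
# left, one glyph panel per analysis on the right.  The odds ratio of a
# record is drawn as a triangle (up = over-represented, down =
# under-represented; green = significant, pink = not), the fold change as a
# vertical bar (red = significant, grey = not).  All coordinates are
# emitted with fixed two-decimal formatting and no timestamps or generated
# ids, so identical inputs give byte-identical SVG.

#' Axis configuration for the glyph panels
#'
#' One linear axis is shared by the triangle (odds ratio) and bar (fold
#' change) of every panel; `mode` picks which quantity the axis is scaled
#' and labelled for.  The odds-ratio axis defaults to the 0-25 range; the
#' fold-change axis auto-fits to the smallest integer at or above the
#' largest displayed fold change.  Values outside the range are clamped to
#' the axis end (with a small overflow notch) when `clamp` is on -- GOstats
#' emits infinite odds ratios for zero cells, which land on the axis
#' maximum.
#'
#' @param mode `"fold_change"` or `"odds_ratio"`.
#' @param minimum Axis minimum (default 0).
#' @param maximum Axis maximum; `NULL` means 25 for `odds_ratio` and
#'   auto-fit for `fold_change`.
#' @param clamp Clamp out-of-range values to the axis ends (default on).
#' @return An object of class `go_axis`.
#' @export
axis_config <- function(mode = c("fold_change", "odds_ratio"),
                        minimum = 0, maximum = NULL, clamp = TRUE) {
  mode <- match.arg(mode)
  if (is.null(maximum) && mode == "odds_ratio") maximum <- 25
  if (!is.null(maximum) && minimum >= maximum) {
    gs_error("gs_argument_error", "axis minimum must lie below its maximum")
  }
  structure(list(mode = mode, minimum = minimum, maximum = maximum,
                 clamp = isTRUE(clamp)),
            class = "go_axis")
}

# Fill in an auto-fit maximum from the rows about to be drawn.
resolve_axis <- function(axis, rows) {
  if (!is.null(axis$maximum)) return(axis)
  vals <- unlist(lapply(rows, function(r) {
    vapply(r$per_analysis, function(pa) {
      if (is.null(pa$record)) NA_real_ else {
        if (axis$mode == "fold_change") pa$fold else pa$record$odds_ratio
      }
    }, numeric(1))
  }), use.names = FALSE)
  vals <- vals[is.finite(vals)]
  axis$maximum <- if (length(vals)) max(1, ceiling(max(vals))) else 1
  axis
}

#' Default style options for the rendered figure
#'
#' All geometry and colours live in one structure so golden files stay
#' stable and every aspect is overridable (e.g. from the CLI's YAML
#' config).  Colours are artifact defaults for the named glyph colours:
#' significant enrichment green `#2ca02c` / red bar `#d62728`,
#' non-significant pink `#f7b6d2` / grey bar `#9e9e9e`.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of style settings.
#' @export
style_options <- function(...) {
  defaults <- list(
    row_height = 22,
    label_width = 300,
    indent_px = 14,
    panel_width = 160,
    panel_gap = 14,
    margin = 10,
    header_height = 26,
    axis_height = 30,
    font_family = "Helvetica, Arial, sans-serif",
    font_size = 12,
    title_font_size = 12,
    tick_font_size = 9,
    triangle_half_width = 5,
    triangle_height = 9,
    bar_width = 3,
    bar_height = 14,
    colour_significant = "#2ca02c",
    colour_nonsignificant = "#f7b6d2",
    colour_bar_significant = "#d62728",
    colour_bar_nonsignificant = "#9e9e9e",
    colour_axis = "#444444",
    colour_text = "#000000",
    colour_rowline = "#eeeeee"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) {
      gs_error("gs_argument_error",
               paste0("unknown style option(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(over)] <- over
  }
  defaults
}

#' Glyph geometry and colours for one record
#'
#' Applies the full glyph semantics: the triangle sits at the (clamped)
#' odds ratio, points up for over-representation and down for
#' under-representation, and is green when significant, pink when not; the
#' bar sits at the (clamped) fold change and is red when significant, grey
#' when not.  An absent fold change (undefined: expected count 0) gives an
#' absent bar.
#'
#' @param record A record list (see [attach_enrichment()]).
#' @param significant Logical significance flag.
#' @param fold Fold change, or `NA` for absent.
#' @param axis A resolved `go_axis` (maximum filled in).
#' @return A list: `triangle_x`, `triangle_orientation` (`"up"`/`"down"`),
#'   `triangle_colour`, `triangle_clamped`, `bar_x` (or `NA`),
#'   `bar_colour`, `bar_clamped`.
#' @export
build_glyph <- function(record, significant, fold, axis) {
  clamp1 <- function(v) {
    if (!axis$clamp) return(list(x = v, clamped = FALSE))
    if (v > axis$maximum) return(list(x = axis$maximum, clamped = TRUE))
    if (v < axis$minimum) return(list(x = axis$minimum, clamped = TRUE))
    list(x = v, clamped = FALSE)
  }
  tri <- clamp1(record$odds_ratio)
  bar <- if (is.na(fold)) list(x = NA_real_, clamped = FALSE) else clamp1(fold)
  list(
    triangle_x = tri$x,
    triangle_orientation = if (identical(record$direction, "under")) "down" else "up",
    triangle_colour = if (isTRUE(significant)) "green" else "pink",
    triangle_clamped = tri$clamped,
    bar_x = bar$x,
    bar_colour = if (isTRUE(significant)) "red" else "grey",
    bar_clamped = bar$clamped
  )
}

fmt <- function(x) sprintf("%.2f", x)
esc_xml <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render display rows as a deterministic SVG figure
#'
#' Produces the two-area comparison figure: term labels on the left,
#' indented by DAG depth within their selected path, and one equal-width
#' glyph panel per analysis on the right, in analysis label order, each
#' with its own axis line and tick labels.  The output is a pure function
#' of its arguments -- fixed float formatting, no timestamps, no random
#' ids -- so repeated renders are byte-identical.
#'
#' @param rows Display rows from [assemble_rows()].
#' @param labels Character vector of analysis labels (panel order).
#' @param axis A `go_axis` (default: auto-fit fold-change axis).
#' @param style Style options from [style_options()].
#' @return The SVG document as a single string.
#' @export
render_figure <- function(rows, labels, axis = axis_config(), style = style_options()) {
  if (!length(rows)) {
    gs_error("gs_empty_figure_error", "no rows to render (empty selection)")
  }
  if (!length(labels)) {
    gs_error("gs_argument_error", "need at least one analysis label")
  }
  axis <- resolve_axis(axis, rows)
  s <- style
  n_rows <- length(rows)
  n_panels <- length(labels)
  width <- s$margin * 2 + s$label_width +
    n_panels * s$panel_width + (n_panels - 1) * s$panel_gap
  height <- s$margin * 2 + s$header_height + n_rows * s$row_height + s$axis_height
  panel_x <- function(j) {
    s$margin + s$label_width + (j - 1) * (s$panel_width + s$panel_gap)
  }
  row_top <- function(i) s$margin + s$header_height + (i - 1) * s$row_height
  axis_y <- s$margin + s$header_height + n_rows * s$row_height + 8
  value_x <- function(j, v) {
    panel_x(j) + (v - axis$minimum) / (axis$maximum - axis$minimum) * s$panel_width
  }

  out <- character()
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="',
       fmt(width), '" height="', fmt(height), '" viewBox="0 0 ',
       fmt(width), ' ', fmt(height), '">')
  push('<rect x="0" y="0" width="', fmt(width), '" height="', fmt(height),
       '" fill="#ffffff"/>')

  # panel titles
  for (j in seq_len(n_panels)) {
    push('<text x="', fmt(panel_x(j) + s$panel_width / 2), '" y="',
         fmt(s$margin + s$title_font_size),
         '" text-anchor="middle" font-family="', s$font_family,
         '" font-size="', fmt(s$title_font_size), '" fill="', s$colour_text,
         '">', esc_xml(labels[j]), '</text>')
  }

  # row separators + labels
  for (i in seq_len(n_rows)) {
    r <- rows[[i]]
    y <- row_top(i)
    ymid <- y + s$row_height / 2
    push('<line x1="', fmt(s$margin), '" y1="', fmt(y + s$row_height),
         '" x2="', fmt(width - s$margin), '" y2="', fmt(y + s$row_height),
         '" stroke="', s$colour_rowline, '" stroke-width="1"/>')
    push('<text x="', fmt(s$margin + r$indent * s$indent_px), '" y="',
         fmt(ymid + s$font_size / 2 - 1.5),
         '" font-family="', s$font_family, '" font-size="', fmt(s$font_size),
         '" fill="', s$colour_text, '">', esc_xml(r$label), '</text>')
  }

  # panels: axis, ticks, glyphs
  ticks <- axis_ticks(axis)
  colour_of <- function(key) switch(key,
    green = s$colour_significant,
    pink = s$colour_nonsignificant,
    red = s$colour_bar_significant,
    grey = s$colour_bar_nonsignificant)
  for (j in seq_len(n_panels)) {
    x0 <- panel_x(j)
    push('<line x1="', fmt(x0), '" y1="', fmt(axis_y), '" x2="',
         fmt(x0 + s$panel_width), '" y2="', fmt(axis_y), '" stroke="',
         s$colour_axis, '" stroke-width="1"/>')
    for (tv in ticks) {
      tx <- value_x(j, tv)
      push('<line x1="', fmt(tx), '" y1="', fmt(axis_y), '" x2="', fmt(tx),
           '" y2="', fmt(axis_y + 4), '" stroke="', s$colour_axis,
           '" stroke-width="1"/>')
      push('<text x="', fmt(tx), '" y="', fmt(axis_y + 5 + s$tick_font_size),
           '" text-anchor="middle" font-family="', s$font_family,
           '" font-size="', fmt(s$tick_font_size), '" fill="', s$colour_axis,
           '">', format_tick(tv), '</text>')
    }
    axis_label <- if (axis$mode == "fold_change") "fold change" else "odds ratio"
    push('<text x="', fmt(x0 + s$panel_width / 2),
         '" y="', fmt(axis_y + 8 + 2 * s$tick_font_size),
         '" text-anchor="middle" font-family="', s$font_family,
         '" font-size="', fmt(s$tick_font_size), '" fill="', s$colour_axis,
         '">', axis_label, '</text>')

    for (i in seq_len(n_rows)) {
      pa <- rows[[i]]$per_analysis[[j]]
      if (is.null(pa$record)) next
      g <- build_glyph(pa$record, pa$significant, pa$fold, axis)
      ymid <- row_top(i) + s$row_height / 2
      # fold-change bar first so the triangle overdraws it on collision
      if (!is.na(g$bar_x)) {
        bx <- value_x(j, g$bar_x)
        push('<rect x="', fmt(bx - s$bar_width / 2), '" y="',
             fmt(ymid - s$bar_height / 2), '" width="', fmt(s$bar_width),
             '" height="', fmt(s$bar_height), '" fill="',
             colour_of(g$bar_colour), '"/>')
      }
      tx <- value_x(j, g$triangle_x)
      hw <- s$triangle_half_width
      th <- s$triangle_height
      pts <- if (g$triangle_orientation == "up") {
        paste0(fmt(tx), ",", fmt(ymid - th / 2), " ",
               fmt(tx - hw), ",", fmt(ymid + th / 2), " ",
               fmt(tx + hw), ",", fmt(ymid + th / 2))
      } else {
        paste0(fmt(tx), ",", fmt(ymid + th / 2), " ",
               fmt(tx - hw), ",", fmt(ymid - th / 2), " ",
               fmt(tx + hw), ",", fmt(ymid - th / 2))
      }
      push('<polygon points="', pts, '" fill="', colour_of(g$triangle_colour), '"/>')
      if (g$triangle_clamped || g$bar_clamped) {
        ox <- x0 + s$panel_width + 2
        push('<path d="M ', fmt(ox), ' ', fmt(ymid - 3), ' L ', fmt(ox + 4),
             ' ', fmt(ymid), ' L ', fmt(ox), ' ', fmt(ymid + 3),
             '" stroke="', s$colour_axis, '" stroke-width="1" fill="none"/>')
      }
    }
  }
  push('</svg>')
  paste0(paste(out, collapse = "\n"), "\n")
}

# ticks at min, midpoint, max (deterministic; midpoint dropped when it
# coincides with an end after rounding)
axis_ticks <- function(axis) {
  mid <- (axis$minimum + axis$maximum) / 2
  unique(c(axis$minimum, mid, axis$maximum))
}

format_tick <- function(v) {
  if (v == round(v)) sprintf("%d", as.integer(round(v))) else sprintf("%.1f", v)
}

#' Rasterize a rendered SVG to PNG
#'
#' Requires the optional `rsvg` package; without a rasterizer installed a
#' capability error is raised advising SVG output (the SVG is the primary,
#' bit-stable artifact).
#'
#' @param svg SVG document text from [render_figure()].
#' @param scale Scale factor (> 0); the raster is `scale` times the SVG's
#'   unit size.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_png <- function(svg, path, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    gs_error("gs_argument_error", "scale must be a single positive number")
  }
  if (!requireNamespace("rsvg", quietly = TRUE)) {
    gs_error("gs_capability_error",
             "no SVG rasterizer available (package 'rsvg' not installed); use the SVG output")
  }
  dims <- svg_dimensions(svg)
  rsvg::rsvg_png(charToRaw(svg), path,
                 width = round(dims[1] * scale),
                 height = round(dims[2] * scale))
  invisible(path)
}

# width/height declared in the SVG root element
svg_dimensions <- function(svg) {
  w <- regmatches(svg, regexec('<svg[^>]* width="([0-9.]+)"', svg))[[1]][2]
  h <- regmatches(svg, regexec('<svg[^>]* height="([0-9.]+)"', svg))[[1]][2]
  c(as.numeric(w), as.numeric(h))
}
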