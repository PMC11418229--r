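---
title: "Methods and design of goseries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of goseries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goseries)
```

## What the package computes

`goseries` compares GO term enrichment across an ordered series of pairwise
differential-expression analyses.  Its inputs are (a) a GO release in OBO
flat-file format and (b) one enrichment table per analysis and direction in
the layout of GOstats' `hyperGTest` summary.  It does **not** perform the
hypergeometric test, call differentially expressed genes, or parse gene
annotation (GAF) files: it consumes the statistics GOstats already computed
and is responsible for organizing and drawing them faithfully.

The pipeline is: parse the ontology into a three-domain DAG; merge each
analysis' over/under tables into one record set; attach records to terms
(through the alternate-id index, so tables produced against an older GO
release still resolve); expand the user's selected root-to-term paths into
an ordered, indented row list; and render one glyph panel per analysis
beside the labels.

## The ontology graph

Each GO domain is stored as a flat collection of terms carrying explicit
parent and (derived) child links.  Paths are never precomputed: a full GO
release holds on the order of tens of thousands of terms, roughly twice as
many parent–child edges, and a root-to-leaf path count in the hundreds of
thousands, so materializing the path set would dominate memory for a
quantity that is only needed per selected term.

* **Admitted parent relations.**  `is_a` only by default; `part_of` is
  opt-in (`relations = c("is_a", "part_of")`).  `is_a` is the one relation
  guaranteed never to cross namespaces, which keeps each domain
  self-contained; regulatory and other relationship tags are ignored with a
  logged note.  Whether `part_of` should count as a parent is a genuine
  modelling choice in GO tooling; both are supported and the default is
  documented rather than asserted as canonical.
* **Obsolete terms** stay in the id index — enrichment tables citing a
  since-obsoleted id should resolve, not vanish — but carry no edges and are
  excluded from the displayable domain sets and from root sets.
* **Duplicate stanzas** for one id keep the last occurrence, with a
  warning (mirrors how most OBO consumers behave on malformed files).
* **Acyclicity** is checked at load (Kahn's algorithm); on failure one
  witness cycle is reported.  Every downstream recurrence assumes it.

### Graph queries

* **Path counting** uses `N(t) = 1` for roots, else the sum of `N` over
  parents, memoized in topological order — O(V+E), exact in doubles (counts
  can exceed 2^31 on a full release).
* **Path enumeration** materializes at most `max_paths` (default 10 000)
  paths and refuses otherwise, since fan-in makes deep terms combinatorial.
  The count is consulted first, so refusal costs O(V+E), not an aborted
  enumeration.  Output order is lexicographic over the id sequences, making
  golden files and piped output stable.
* **Depth** is the *longest* root-to-term path, matching the GO community's
  "term level" usage (the shortest-path alternative is noted in the code
  but not offered as an option until someone needs it).
* **NCA** returns *all* deepest common ancestors, sorted by id.  A DAG can
  hold several equally deep common ancestors, and silently picking one
  would discard exactly the ambiguity the user asked about.

## Enrichment records

* The id column is recognized by the header pattern `GO[A-Z]*ID`
  (`GOBPID`, `GOMFID`, `GOCCID`, `GOID`); the remaining mandatory columns
  (`Pvalue`, `OddsRatio`, `ExpCount`, `Count`, `Size`, `Term`) are matched
  case-insensitively; tab and comma delimiters are auto-detected from the
  header.  `Inf` odds ratios are accepted as infinite — GOstats emits them
  whenever the 2×2 table has a zero cell — and clamped only at render time,
  never in storage.
* **Combining directions.**  The default policy keeps, for a term tested in
  both directions, the record with the smaller *P* value (ties go to the
  over table, a documented arbitrary tie-break); a concatenation policy
  that keeps both records is available.  Min-p matches the intuition that
  one term gets one row per analysis in the figure.
* **Significance** is strict `p < alpha`, default `alpha = 0.05` on raw
  *P* values: GOstats reports raw hypergeometric *P* values and no
  particular correction is canonical for this display, so correction
  (Benjamini–Hochberg step-up via `stats::p.adjust`, pooled over both
  directions of one analysis) is opt-in rather than silently applied.
* **Fold change** is `Count / ExpCount`, kept below 1 for depleted terms
  rather than reciprocated, so a single monotone axis serves both
  directions.  `ExpCount = 0` leaves the fold undefined; the record is kept
  (the odds-ratio triangle still renders) and the bar is absent.
* Ids that resolve neither as primary nor alternate are accumulated into an
  unmatched report written next to the figure — dropped silently they would
  masquerade as biology.

## Display model

Selected paths expand to one row per step, indent equal to the position in
the path.  Consecutive paths sharing a leading prefix emit the shared rows
once — sibling selections read as one indented block — but a term reached
along different selected paths is drawn once *per path*: in a DAG that
repetition is information (which lineage the user chose), not duplication.
A path that is a pure prefix of its predecessor re-emits its terminal row,
keeping the invariant that the sequence of terminal rows equals the
sequence of selected targets.

Node states (`HAS_DATA` / `DESCENDANT_HAS_DATA` / `NO_DATA`) are computed
in one reverse-topological sweep and mirror the three tree icons of the
interactive viewer this design descends from; the CLI's `validate` command
prints their counts.

Turning parent data off suppresses glyphs on non-terminal rows but keeps
the labels: collapsing rows as well would destroy the indentation structure
that encodes the term relationships.  Selection files are versioned plain
text (`#gotermpaths v1`), ids only, validated against the current ontology
at load; a stale selection reports *all* failures and carries the valid
remainder so a partial figure can still be produced (CLI exit code 3).

## Rendering

SVG is generated directly as text with fixed two-decimal coordinate
formatting, no timestamps and no generated ids, making renders
byte-identical for identical inputs — the property the golden-file tests
pin.  Glyph abscissae are affine in the displayed value; the test suite
recovers coordinates from the SVG and checks the map to 0.01 px.  One axis
is shared by triangle and bar; `odds_ratio` mode fixes the range 0–25 (the
conventional display range for these odds ratios; GOstats' infinities make
any finite cap a choice, and values beyond it clamp to the end with an
overflow notch), `fold_change` mode auto-fits to the smallest integer
covering the data.  Colours (`#2ca02c` green, `#f7b6d2` pink, `#d62728`
red, `#9e9e9e` grey) and all geometry live in `style_options()` and are
overridable; the defaults are artifact choices, since only the colour
*names* are fixed by the display convention.  PNG export delegates to the
optional `rsvg` rasterizer and raises a capability error advising SVG when
it is absent; raster bytes are rasterizer-dependent and only dimensions are
tested.

## The synthetic data generator

The generator emulates the *inputs* of the real pipeline, not the biology:

* **Ontology**: term *i* draws 1..`max_parents` parents uniformly among
  earlier terms of its namespace — acyclic by construction, with realistic
  fan-in.  One alternate id and one obsolete term are injected per
  namespace (as extra stanzas beyond the requested size) so id resolution
  and obsolete handling are always exercised.  The returned edge list is
  the oracle parser tests compare against, and the emitted OBO is
  cross-checked against an independent third-party OBO parser.
* **Enrichment**: planted signal terms get `p ~ U(1e-6, 0.01)`,
  `ExpCount ~ U(1, 10)`, `Count = round(fold × ExpCount)` and a
  direction-consistent odds ratio; background terms get `p ~ U(0.1, 1)` and
  fold near 1.  The two *P* ranges deliberately do not straddle 0.05, so
  ground-truth recovery is exact by construction.  *P* values are assigned,
  not computed from a hypergeometric model: the package visualizes GOstats
  output, it does not re-derive it, so the fixture needs format and range
  fidelity only.  Note `round()` means the *realized* fold is
  `Count/ExpCount`, which the ground truth records.
* The demo preset is four analyses in a two-genotype × two-dose-vs-control
  layout — the shape of series this display is for — with three planted
  signals (folds 4 and 2.5 over-represented, 0.25 under-represented),
  values typical of GOstats output on mid-sized DEG lists.

What the fixtures do **not** emulate: correlated enrichment between related
terms (real parent terms inherit their children's genes), realistic *P*
distributions, batch effects, or GO-release idiosyncrasies (cross-domain
relationships, `consider` chains).  Passing tests therefore demonstrate
correctness of parsing, graph algebra, combination rules and rendering —
not robustness to every malformed real-world file.

## Problem sizes and numerical choices

The test suite runs the graph oracles on 200 seeded random DAGs of 5–40
terms (brute-force enumeration stays trivially cheap at this size while
still producing multi-parent topologies), 50 NCA queries per DAG, and a
1200-term fan-in-3 fixture as a scale smoke test — the smallest round size
whose leaf-path count exceeds 10^5, i.e. the same order of magnitude a real
GO release exhibits.  Fold-change identities are asserted to 1e-12;
rendered coordinates to 0.01 px; everything else is exact.  All generators
take explicit integer seeds and restore the caller's RNG state.

## Known limitations

* OBO only — no OWL, no GAF, no network retrieval of releases.
* No semantic-similarity scores or term clustering; this is by design the
  un-aggregated display.
* The interactive tree browser of the original viewer design is replaced
  by `paths` / `nca` / `search` commands that compose selection files; no
  GUI is provided.
* Figure text width is estimated, not measured: very long term names can
  overrun the label column (widen `label_width` in `style_options()`).
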