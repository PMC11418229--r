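Package: goseries
Title: Side-by-Side Visualization of GO Term Enrichment Across Multiple
    Differential Expression Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Loads a Gene Ontology release from its OBO flat file into an
    in-memory directed acyclic graph split across the three GO domains,
    attaches hypergeometric over- and under-enrichment results (in the
    tabular layout produced by GOstats' hyperGTest summary) from one or
    more pairwise differential-expression analyses, and renders a
    deterministic side-by-side comparison figure: indented term labels on
    the left, one glyph panel per analysis on the right, with odds-ratio
    triangles and fold-change bars.  Includes DAG queries (root-to-term
    path enumeration and counting, ancestors, depth, nearest common
    ancestor, term search), a versioned path-selection file format, a
    seeded synthetic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    png,
    rsvg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
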