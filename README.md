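# goseries

Side-by-side visualization of Gene Ontology (GO) term enrichment across a
series of pairwise differential-expression analyses.

## The problem

RNA profiling experiments increasingly contain several related pairwise
comparisons — a time course, a dose series, two genotypes under two
treatments.  Each comparison yields a list of differentially expressed genes
(DEG), and each DEG list yields a table of over- and under-represented GO
terms (here: the hypergeometric-test summaries produced by GOstats'
`hyperGTest`).  Most enrichment-visualization tools display one analysis at
a time, often after aggregating terms by semantic similarity, which makes
the *progression* of a physiological response across the series hard to
read.  `goseries` takes the opposite approach: no aggregation, no
similarity scores — the user selects specific root-to-term paths through the
GO graph, and the tool draws the selected terms as an indented list with one
small glyph panel per analysis beside them, so change across the series is
read off a single figure.

## The model

The GO vocabulary is a directed acyclic graph (DAG) split into three
domains (biological process, molecular function, cellular component).  A
term may have several parents, so it lies on several root-to-term paths;
`goseries` stores each domain as a flat term collection and constructs
paths on the fly:

- the number of root-to-term paths satisfies `N(t) = 1` if `t` is a root,
  else `N(t) = Σ_{p ∈ parents(t)} N(p)`, evaluated memoized in topological
  order (a full GO release has hundreds of thousands of root-to-leaf
  paths, so paths are counted before they are materialized);
- the nearest common ancestor (NCA) of a term set is every deepest member
  of `⋂_i (ancestors(t_i) ∪ {t_i})`, where depth is the longest root path;
- per analysis and term, GOstats reports an odds ratio, a hypergeometric
  *P* value, and the observed (`Count`) versus expected (`ExpCount`)
  number of DEG; the displayed fold change is `Count / ExpCount`, which is
  comparable across analyses with different DEG-list sizes when the raw
  counts are not.

In the figure each record becomes a triangle at the odds-ratio position
(pointing up for over-representation, down for under-representation; green
when significant, pink when not) plus a vertical bar at the fold-change
position (red when significant, grey when not).  Significance defaults to
raw `P < 0.05` (strict), with Benjamini–Hochberg adjustment opt-in.  One
linear axis (default 0 to an auto-fitted fold-change maximum; 0–25 in
odds-ratio mode) is shared by all panels; out-of-range values — including
the infinite odds ratios GOstats emits for zero cells — are clamped to the
axis end and flagged with a small overflow notch.

## Worked example

Generate the seeded demo data set (a toy ontology plus four analyses
emulating a two-genotype × two-dose design against control, with three
planted signal terms), then explore and render it:

```sh
Rscript -e 'goseries::goseries_cli(commandArgs(TRUE))' fixtures --out-dir demo --seed 7
Rscript -e 'goseries::goseries_cli(commandArgs(TRUE))' paths --obo demo/ontology.obo GO:0000012
```

```
GO:0000001>GO:0000002>GO:0000003>GO:0000006>GO:0000011>GO:0000012
GO:0000001>GO:0000002>GO:0000003>GO:0000006>GO:0000012
GO:0000001>GO:0000002>GO:0000004>GO:0000006>GO:0000011>GO:0000012
GO:0000001>GO:0000002>GO:0000004>GO:0000006>GO:0000012
GO:0000001>GO:0000002>GO:0000005>GO:0000011>GO:0000012
```

Term `GO:0000012` sits on five distinct paths — pick the informative one,
paste it into a selection file (the lines above are already in the saved
selection-file syntax), and render:

```sh
Rscript -e 'goseries::goseries_cli(commandArgs(TRUE))' validate --obo demo/ontology.obo \
  --analysis wildtype_low_dose=demo/wildtype_low_dose_over.tsv,demo/wildtype_low_dose_under.tsv \
  --analysis disease_low_dose=demo/disease_low_dose_over.tsv,demo/disease_low_dose_under.tsv
```

```
terms: 30
edges: 36
biological_process : 15 terms, 1 root(s)
molecular_function : 6 terms, 1 root(s)
cellular_component : 6 terms, 1 root(s)
analyses: 2
   wildtype_low_dose : 9 records
   disease_low_dose : 9 records
unmatched ids: 0
node states: HAS_DATA: 12  DESCENDANT_HAS_DATA: 2  NO_DATA: 13
```

`terms`/`edges` summarize the parsed DAG; each analysis contributed 9
combined records (over- and under-direction tables merged, smaller *P*
wins per term); no record cited an id missing from the ontology; 12 terms
carry their own data, 2 are unannotated ancestors of annotated terms, and
13 (including the other two domains) carry none.

```sh
Rscript -e 'goseries::goseries_cli(commandArgs(TRUE))' render --obo demo/ontology.obo \
  --analysis wildtype_low_dose=demo/wildtype_low_dose_over.tsv,demo/wildtype_low_dose_under.tsv \
  --analysis disease_low_dose=demo/disease_low_dose_over.tsv,demo/disease_low_dose_under.tsv \
  --analysis wildtype_high_dose=demo/wildtype_high_dose_over.tsv,demo/wildtype_high_dose_under.tsv \
  --analysis disease_high_dose=demo/disease_high_dose_over.tsv,demo/disease_high_dose_under.tsv \
  --selection demo/selection.txt --out figure.svg
```

writes a deterministic `figure.svg` (identical bytes on every run) plus
`figure.svg.unmatched.tsv`, and exits 0.  Exit codes follow shell
conventions throughout: 0 success, 1 data error, 2 usage error, 3 partial
success (a stale selection: paths whose edges vanished from a newer GO
release are reported and skipped, the rest are still drawn).

The same pipeline is available as plain functions (`read_obo()`,
`read_gostats()`, `combine_over_under()`, `attach_enrichment()`,
`load_selection()`, `assemble_rows()`, `render_figure()`), with the CLI a
thin wrapper; `inst/cli/goseries` is an installable Rscript front end.

## Selection files

```
#gotermpaths v1
#show_parent_data: true
GO:0000001>GO:0000002>GO:0000003>GO:0000006
```

One root-to-term path per line, ids joined by `>`.  Files are
ontology-release-agnostic; every edge is re-validated at load time.

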