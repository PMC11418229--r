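test_that("a GOstats row maps onto the record fields, for both delimiters", {
  row <- c("GO:0000004", "0.001", "3.2", "2.5", "10", "40", "junction D")
  for (sep in c("\t", ",")) {
    rec <- read_gostats(text = gostats_text(list(row), sep = sep),
                        direction = "over")
    expect_equal(nrow(rec), 1)
    expect_equal(rec$go_id, "GO:0000004")
    expect_equal(rec$p_value, 0.001)
    expect_equal(rec$odds_ratio, 3.2)
    expect_equal(rec$expected_count, 2.5)
    expect_equal(rec$observed_count, 10L)
    expect_equal(rec$gene_set_size, 40L)
    expect_equal(rec$term_name, "junction D")
    expect_equal(rec$direction, "over")
  }
})

test_that("a header-only table yields an empty record set", {
  rec <- read_gostats(text = gostats_text(list()), direction = "under")
  expect_equal(nrow(rec), 0)
  expect_named(rec, c("go_id", "p_value", "odds_ratio", "expected_count",
                      "observed_count", "gene_set_size", "term_name",
                      "direction"))
})

test_that("an Inf odds ratio is accepted as infinite, without error", {
  rec <- read_gostats(text = gostats_text(list(
    c("GO:0000002", "0.01", "Inf", "1.5", "8", "20", "branch B"))),
    direction = "over")
  expect_true(is.infinite(rec$odds_ratio))
})

test_that("id-column detection accepts the per-domain GOstats headers", {
  for (id_col in c("GOBPID", "GOMFID", "GOCCID", "GOID")) {
    rec <- read_gostats(text = gostats_text(list(
      c("GO:0000001", "0.5", "1.0", "2", "2", "10", "x")), id_col = id_col),
      direction = "over")
    expect_equal(rec$go_id, "GO:0000001")
  }
})

test_that("format errors name the missing column or the offending row", {
  no_id <- "Foo\tPvalue\tOddsRatio\tExpCount\tCount\tSize\tTerm\nx\t1\t1\t1\t1\t1\tt"
  expect_error(read_gostats(text = no_id), class = "gs_format_error")

  no_size <- "GOBPID\tPvalue\tOddsRatio\tExpCount\tCount\tTerm\nGO:1\t1\t1\t1\t1\tt"
  err <- expect_error(read_gostats(text = no_size), class = "gs_format_error")
  expect_match(conditionMessage(err), "Size")

  bad_num <- gostats_text(list(
    c("GO:0000001", "0.5", "1.0", "2", "2", "10", "ok"),
    c("GO:0000002", "oops", "1.0", "2", "2", "10", "bad")))
  err <- expect_error(read_gostats(text = bad_num), class = "gs_format_error")
  expect_match(conditionMessage(err), "row 2")
})

test_that("combining keeps the smaller-p record per id, ties to the over table", {
  over <- read_gostats(text = gostats_text(list(
    c("GO:0000001", "0.001", "3", "2", "6", "20", "a"),
    c("GO:0000002", "0.5", "1.2", "2", "2", "20", "b"),
    c("GO:0000004", "0.03", "2", "2", "4", "20", "d"))), direction = "over")
  under <- read_gostats(text = gostats_text(list(
    c("GO:0000001", "0.9", "0.5", "4", "2", "20", "a"),
    c("GO:0000002", "0.5", "0.6", "4", "2", "20", "b"),
    c("GO:0000003", "0.2", "0.7", "4", "3", "20", "c"))), direction = "under")
  comb <- combine_over_under(over, under)
  expect_setequal(comb$go_id, c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))
  expect_equal(nrow(comb), length(union(over$go_id, under$go_id)))
  by_id <- function(id) comb[comb$go_id == id, ]
  expect_equal(by_id("GO:0000001")$direction, "over")   # 0.001 < 0.9
  expect_equal(by_id("GO:0000002")$direction, "over")   # tie -> over
  expect_equal(by_id("GO:0000003")$direction, "under")  # only under
  expect_equal(by_id("GO:0000004")$direction, "over")   # only over

  concat <- combine_over_under(over, under, policy = "concat")
  expect_equal(nrow(concat), nrow(over) + nrow(under))
})

test_that("fold change is observed/expected, zero is valid, zero expected is not", {
  expect_equal(fold_change(10, 2.5), 4)
  expect_equal(fold_change(1, 4), 0.25)
  expect_equal(fold_change(0, 2), 0)
  expect_error(fold_change(1, 0), class = "gs_undefined_fold_error")
})

test_that("fold change times the expected count reproduces the observed count", {
  set.seed(99)
  expected <- runif(50, 0.1, 20)
  observed <- rpois(50, 5)
  expect_true(all(abs(fold_change(observed, expected) * expected - observed) < 1e-12))
})

test_that("significance is strict at alpha and supports BH over pooled records", {
  recs <- data.frame(p_value = c(0.001, 0.05, 0.04999))
  flags <- is_significant(recs, alpha = 0.05)
  expect_equal(flags, c(TRUE, FALSE, TRUE))  # 0.05 exactly is NOT significant

  bh <- data.frame(p_value = c(0.01, 0.02, 0.04))
  expect_equal(adjusted_p(bh$p_value, "benjamini_hochberg"), c(0.03, 0.03, 0.04))
  expect_equal(is_significant(bh, alpha = 0.05, adjust = "benjamini_hochberg"),
               rep(TRUE, 3))
})

test_that("BH adjusted p-values are monotone in raw-p rank and bounded by 1", {
  set.seed(11)
  for (k in 1:5) {
    p <- runif(40)
    adj <- adjusted_p(p, "benjamini_hochberg")
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(adj >= p))
  }
})

test_that("attachment resolves alt ids, keeps label order, and reports unmatched ids", {
  text <- sub("id: GO:0000004", "id: GO:0000004\nalt_id: GO:0000044",
              diamond_obo(), fixed = TRUE)
  ont <- read_obo(text = text)
  mk <- function(id) data.frame(
    go_id = id, p_value = 0.01, odds_ratio = 2, expected_count = 2,
    observed_count = 4L, gene_set_size = 10L, term_name = "t",
    direction = "over", stringsAsFactors = FALSE)
  labels <- paste0("analysis_", 1:4)
  tabs <- list(mk(D_D), mk(D_D), mk("GO:0000044"), mk(c(D_D, "GO:8888888")))
  names(tabs) <- labels
  ann <- attach_enrichment(ont, analysis_set(tabs))
  expect_equal(ann$labels, labels)
  slot <- ann$index[[D_D]]
  expect_equal(names(slot), labels)  # alt id filed under canonical, in order
  expect_equal(slot$analysis_3$go_id, D_D)
  expect_equal(nrow(ann$unmatched), 1)
  expect_equal(ann$unmatched$go_id, "GO:8888888")
  expect_equal(ann$unmatched$label, "analysis_4")
})

test_that("a combined table round-trips through write_combined, keeping directions", {
  over <- read_gostats(text = gostats_text(list(
    c("GO:0000001", "0.001", "3", "2", "6", "20", "a"))), direction = "over")
  under <- read_gostats(text = gostats_text(list(
    c("GO:0000003", "0.2", "0.7", "4", "3", "20", "c"))), direction = "under")
  comb <- combine_over_under(over, under)
  path <- tempfile(fileext = ".tsv")
  write_combined(comb, path)
  back <- read_gostats(path, direction = "over")  # Direction column wins
  expect_equal(back[order(back$go_id), ]$direction, c("over", "under"))
})

test_that("direction is inferred from the odds ratio for direction-free combined tables", {
  rec <- read_gostats(text = gostats_text(list(
    c("GO:0000001", "0.01", "2.5", "2", "5", "20", "a"),
    c("GO:0000002", "0.01", "0.4", "5", "2", "20", "b"))),
    direction = "infer")
  expect_equal(rec$direction, c("over", "under"))
})

test_that("analysis sets demand unique labels and a sane alpha", {
  tab <- data.frame(p_value = 0.5)
  expect_error(analysis_set(list(tab)), class = "gs_argument_error")
  expect_error(analysis_set(stats::setNames(list(tab, tab), c("a", "a"))),
               class = "gs_argument_error")
  expect_error(analysis_set(list(a = tab), alpha = 1), class = "gs_argument_error")
})
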