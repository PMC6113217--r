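gaf_line <- function(gene, term, qualifier = "involved_in", aspect = "P") {
  paste(c("DB", gene, gene, qualifier, term, "REF:1", "IEA", "", aspect,
          "", "", "protein", "taxon:9606", "20240101", "DB", "", ""),
        collapse = "\t")
}

test_that("GAF reader keeps the aspect, drops NOT rows and collapses duplicates", {
  f <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    gaf_line("g1", "GO:0000001"),
    gaf_line("g2", "GO:0000001", qualifier = "NOT|involved_in"),
    gaf_line("g3", "GO:0000002"),
    gaf_line("g3", "GO:0000002"),              # duplicate row
    gaf_line("g4", "GO:0000003", aspect = "F") # wrong aspect
  ), f)
  ann <- load_gaf(f)
  expect_setequal(names(ann), c("GO:0000001", "GO:0000002"))
  expect_equal(ann[["GO:0000001"]], "g1")
  expect_equal(ann[["GO:0000002"]], "g3")
})

test_that("GAF reader errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2", gaf_line("g1", "GO:1"), "short\trow"), f)
  expect_error(load_gaf(f), "line 3")
  writeLines("!gaf-version: 2.2", f)
  expect_error(load_gaf(f), "no annotation rows")
})

test_that("log-odds score matches direct evaluation of the formula", {
  # disease-specific term: all 5 annotated genes are seeds, genome-wide
  # seed frequency 306/13987
  expect_equal(term_log_odds(5, 5, 306, 13987),
               log((6 / 6) / (306 / 13987)))
  expect_equal(term_log_odds(5, 5, 306, 13987), 3.8223, tolerance = 1e-4)

  # score is exactly 0 when the corrected term frequency equals m0/n0
  expect_equal(term_log_odds(0, 5, 1, 6), 0)

  # grid agreement with a high-precision independent evaluation
  grid <- expand.grid(m = 0:6, n = c(6, 10, 40), m0 = c(10, 300),
                      n0 = c(1000, 14000), a = c(0.5, 1, 2))
  got <- with(grid, term_log_odds(m, n, m0, n0, a))
  want <- with(grid, log(m + a) - log(n + a) - (log(m0) - log(n0)))
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(term_log_odds(1, 5, 0, 100), "positive")
  expect_error(term_log_odds(1, 5, 10, 100, a = 0), "positive")
  expect_error(term_log_odds(6, 5, 10, 100), "n >= m")
})

test_that("log-odds is strictly increasing in m, and in a it approaches ln(n0/m0) at m = 0", {
  for (n in c(5, 20, 100)) {
    s <- term_log_odds(0:n, n, 306, 13987)
    expect_true(all(diff(s) > 0))
  }
  # numeric sweep: at m = 0 the score rises monotonically with a toward
  # its limit ln(n0/m0), with shrinking gap
  a_grid <- c(0.5, 1, 2, 5, 20, 100)
  s0 <- term_log_odds(0, 10, 306, 13987, a = a_grid)
  lim <- log(13987 / 306)
  expect_true(all(diff(s0) > 0))
  expect_true(all(diff(abs(s0 - lim)) < 0))
  expect_lt(abs(s0[length(s0)] - lim), abs(s0[1] - lim))
})

test_that("term screening filters exactly the undersized terms and counts within the universe", {
  universe <- sprintf("u%02d", 1:40)
  pos <- universe[1:8]
  ann <- structure(list(
    "GO:A" = universe[1:10],          # n = 10, m = 8
    "GO:B" = universe[5:8],           # n = 4 -> excluded at min_n = 5
    "GO:C" = c(universe[30:36], "external_gene"),  # n = 7 in universe
    "GO:D" = sprintf("x%02d", 1:20)   # entirely outside -> n = 0
  ), class = "annotation_set")
  ts <- score_all_terms(ann, pos, universe, min_n = 5)
  expect_setequal(ts$term, c("GO:A", "GO:C"))
  expect_equal(ts$m[ts$term == "GO:A"], 8L)
  expect_equal(ts$n[ts$term == "GO:C"], 7L)
  expect_equal(ts$score[ts$term == "GO:A"],
               term_log_odds(8, 10, 8, 40))
  # exhaustive recount of the exclusion rule at several cutoffs
  for (mn in c(1, 5, 8)) {
    kept <- score_all_terms(ann, pos, universe, min_n = mn)$term
    sizes <- vapply(unclass(ann),
                    function(g) length(intersect(g, universe)), integer(1))
    expect_setequal(kept, names(sizes)[sizes >= mn])
  }
  expect_error(score_all_terms(ann, pos, character(0)), "empty")
  expect_error(score_all_terms(ann, "nobody", universe), "no positive")
})

test_that("labels = universe collapses every term score to the identity value 0", {
  # with every gene a seed, m = n and m0 = n0, so the corrected odds
  # ratio is exactly 1 for every term
  universe <- sprintf("u%03d", 1:500)
  ann <- structure(list("GO:S" = universe[1:10], "GO:L" = universe),
                   class = "annotation_set")
  ts <- score_all_terms(ann, universe, universe)
  expect_true(all(ts$score <= 0))
  expect_equal(ts$score, c(0, 0))
})

test_that("per-gene GO scores sum qualifying terms, defaulting to 0", {
  universe <- c("g1", "g2", "g3")
  ts <- data.frame(term = c("GO:A", "GO:B"), m = c(1L, 1L), n = c(2L, 2L),
                   score = c(1.5, -0.5))
  ann <- structure(list("GO:A" = c("g1", "g2"), "GO:B" = c("g1", "g3"),
                        "GO:X" = "g3"),  # GO:X did not qualify
                   class = "annotation_set")
  gs <- gene_go_scores(ann, ts, universe)
  expect_equal(gs$go_score[gs$gene == "g1"], 1.0)
  expect_equal(gs$go_score[gs$gene == "g2"], 1.5)
  expect_equal(gs$go_score[gs$gene == "g3"], -0.5)

  gs2 <- gene_go_scores(ann, ts[0, ], universe)
  expect_equal(gs2$go_score, c(0, 0, 0))
})

test_that("splitting a term into two identically scored halves doubles nothing, sums consistently", {
  universe <- sprintf("g%02d", 1:30)
  ts1 <- data.frame(term = "GO:A", m = 3L, n = 10L, score = 2.0)
  ann1 <- structure(list("GO:A" = universe[1:10]),
                    class = "annotation_set")
  ts2 <- data.frame(term = c("GO:A1", "GO:A2"), m = c(3L, 3L),
                    n = c(10L, 10L), score = c(2.0, 2.0))
  ann2 <- structure(list("GO:A1" = universe[1:10],
                         "GO:A2" = universe[1:10]),
                    class = "annotation_set")
  g1 <- gene_go_scores(ann1, ts1, universe)
  g2 <- gene_go_scores(ann2, ts2, universe)
  expect_equal(g2$go_score, 2 * g1$go_score)
})

test_that("synthetic GAF round-trips through the reader with term sizes preserved", {
  out <- withr::local_tempdir()
  sim2 <- generate_synthetic(
    synthetic_spec(n_genes = 120, n_positives = 15, intra_edge_boost = 10,
                   n_terms = 12, genes_per_term = c(5, 20),
                   enriched_terms = 3, seed = 31),
    out_dir = out)
  ann <- load_gaf(file.path(out, "annotations.gaf"))
  sizes_file <- vapply(ann, length, integer(1))
  sizes_mem <- vapply(unclass(sim2$annotations), length, integer(1))
  expect_equal(sizes_file[sort(names(sizes_file))],
               sizes_mem[sort(names(sizes_file))])
})
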