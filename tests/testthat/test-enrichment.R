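test_that("initial weights decay per inherited level and floor at the minimum", {
  fx <- worked_fixture()
  w <- initial_weights(fx$annotations)
  expect_equal(w[["W:06"]][["g01"]], 1.0)  # direct
  expect_equal(w[["W:04"]][["g01"]], 0.8)  # inherited 2 levels up
  expect_equal(w[["W:01"]][["g01"]], 0.6)
  # distance 9 with the defaults floors at 0.5
  d <- stats::setNames(c(0, 2, 9), c("a", "b", "c"))
  ann <- structure(list(expanded = list(X = d), expanded_done = TRUE),
                   class = "annotation_table")
  expect_equal(unname(initial_weights(ann)[["X"]]), c(1.0, 0.8, 0.5))
})

test_that("dynamic weight is the natural-log ratio of child to parent scores", {
  expect_equal(dynamic_weight(1e-6, 1e-3), 2.0)
  expect_equal(dynamic_weight(1e-3, 1e-3), 1.0)
  expect_equal(dynamic_weight(1e-3, 1e-6), 0.5)
  expect_error(dynamic_weight(0, 0.5), "\\(0, 1\\]")
  # a score of exactly 1 is nudged below 1, not rejected
  expect_gt(dynamic_weight(0.5, 1), 0)
})

test_that("penalty follows the xmin formula and clamps at one", {
  # both scores 1e-2: 0.1 * log(xmin) / (2 * log(1e-2))
  expect_equal(penalty(1e-2, 1e-2),
               0.1 * log(2.2250738585072014e-308) / (2 * log(1e-2)),
               tolerance = 1e-12)
  expect_equal(penalty(1e-2, 1e-2), 7.6913163892, tolerance = 1e-8)
  # extreme scores drive the ratio below 1: clamped
  expect_equal(penalty(1e-80, 1e-80), 1)
  expect_equal(penalty(1e-300, 1e-300), 1)
  expect_error(penalty(-0.1, 0.5), "\\(0, 1\\]")
})

test_that("with weighting disabled every node reduces to plain ORA", {
  check_reduction <- function(graph, ann, interest) {
    res <- run_enrichment(graph, ann, interest, weight_step = 0,
                          min_init_weight = 1, decorrelate = FALSE)
    N <- attr(res, "N")
    n <- attr(res, "n_interest_total")
    manual <- hyper_test(N, res$n_term, n, res$n_interest)
    expect_equal(res$p, manual, tolerance = 1e-12)
    # and the classic method is the same thing
    cls <- run_ora(graph, ann, interest)
    expect_equal(cls$p, res$p, tolerance = 1e-12)
  }
  fx <- worked_fixture()
  check_reduction(fx$graph, fx$annotations, fx$interest)
  for (seed in 1:20) {
    rf <- random_fixture(seed, n_terms = 40, n_genes = 120)
    interest <- with(rf, implant_interest(
      graph, annotations, select_known_terms(annotations, 3, seed),
      seed = seed
    ))
    check_reduction(rf$graph, rf$annotations, interest)
  }
})

test_that("the worked fixture decorrelates the implanted term's ancestors", {
  fx <- worked_fixture()
  res <- run_enrichment(fx$graph, fx$annotations, fx$interest)
  ora <- run_ora(fx$graph, fx$annotations, fx$interest)

  # the implanted specific term (all 5 interesting genes direct) is first
  expect_equal(res$term_id[1], "W:06")
  # all 5 of 5 drawn from the 5 annotated genes: C(5,5)/C(20,5)
  expect_equal(res$p[res$term_id == "W:06"], 1 / choose(20, 5),
               tolerance = 1e-12)

  # each ancestor's weighted p is no smaller than its plain-ORA p
  anc <- c("W:05", "W:04", "W:02", "W:03", "W:01")
  for (a in anc) {
    expect_gte(res$p[res$term_id == a], ora$p[ora$term_id == a])
  }
  # the direct parent, significant under ORA, is pushed past the cutoff
  expect_lt(ora$p[ora$term_id == "W:05"], 0.01)
  expect_gt(res$p[res$term_id == "W:05"], 0.01)
})

test_that("a parent enriched only by inheritance is worsened against plain ORA", {
  # chain R -> M -> C; the interesting genes are all direct at C, M holds
  # them only by inheritance plus two genes of its own
  terms <- tibble::tibble(
    term_id = c("R", "M", "C"), name = c("root", "mid", "child"),
    synonyms = replicate(3, character(0), simplify = FALSE),
    parents = list(character(0), "R", "M"), obsolete = FALSE
  )
  g <- build_graph(terms, "R")
  direct <- tibble::tibble(
    gene = c(paste0("s", 1:6), "t1", "t2", paste0("b", 1:12)),
    term_id = c(rep("C", 6), rep("M", 2), rep("R", 12))
  )
  ann <- propagate_true_path(annotation_table(direct), g)
  res <- run_enrichment(g, ann, paste0("s", 1:6))
  ora <- run_ora(g, ann, paste0("s", 1:6))
  # the specific child keeps its plain score and outranks the parent
  expect_equal(res$term_id[1], "C")
  expect_equal(res$p[res$term_id == "C"], ora$p[ora$term_id == "C"],
               tolerance = 1e-12)
  expect_lt(res$p[res$term_id == "C"], res$p[res$term_id == "M"])
  # the parent, significant under ORA only through inheritance, is demoted
  expect_lt(ora$p[ora$term_id == "M"], 0.01)
  expect_gt(res$p[res$term_id == "M"], ora$p[ora$term_id == "M"])
})

test_that("degenerate single-node and saturated runs behave", {
  terms <- tibble::tibble(
    term_id = "R", name = "root", synonyms = list(character(0)),
    parents = list(character(0)), obsolete = FALSE
  )
  g <- build_graph(terms, "R")
  ann <- propagate_true_path(
    annotation_table(tibble::tibble(gene = paste0("g", 1:4), term_id = "R")), g
  )
  res <- run_enrichment(g, ann, paste0("g", 1:4))
  expect_equal(nrow(res), 1L)
  expect_equal(res$p, 1)

  fx <- worked_fixture()
  expect_error(run_enrichment(fx$graph, fx$annotations, c("nope1", "nope2")),
               "no interesting genes")
})

test_that("gene-count bounds skip terms entirely", {
  fx <- worked_fixture()
  res <- run_enrichment(fx$graph, fx$annotations, fx$interest,
                        min_genes = 2, max_genes = 15)
  expect_false(any(res$n_term < 2))
  expect_false(any(res$n_term > 15))
  expect_lt(nrow(res), 12L)
})

test_that("identical inputs give bit-identical results", {
  rf <- random_fixture(5)
  interest <- implant_interest(rf$graph, rf$annotations,
                               select_known_terms(rf$annotations, 3, 5),
                               background_rate = 0.05, seed = 5)
  a <- run_enrichment(rf$graph, rf$annotations, interest)
  b <- run_enrichment(rf$graph, rf$annotations, interest)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("result table is sorted, consistent and serializable", {
  fx <- worked_fixture()
  res <- run_enrichment(fx$graph, fx$annotations, fx$interest)
  expect_true(!is.unsorted(res$p))
  expect_true(all(res$p_adjust >= res$p))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_equal(res$gene_ratio,
               paste0(res$n_interest, "/", attr(res, "n_interest_total")))
  expect_equal(res$bg_ratio, paste0(res$n_term, "/", attr(res, "N")))
  g <- glance(res)
  expect_equal(g$N, 20L)
  expect_equal(g$n_interest, 5L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, out)
  back <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(names(back),
               c("DOID", "DOTerm", "level", "p", "p_adjust", "geneRatio",
                 "bgRatio", "genes"))
  expect_equal(back$DOID, res$term_id)
  expect_equal(back$p, res$p, tolerance = 1e-12)
})
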