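test_that("parse_obo reads stanzas, synonyms, is_a targets and obsolete flags", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: disease", "",
    "[Term]", "id: T:2", "name: childA",
    "synonym: \"AD\" EXACT []", "is_a: T:1 ! disease", "",
    "[Term]", "id: T:3", "name: childB", "is_a: T:1", "",
    "[Term]", "id: T:4", "name: gone", "is_obsolete: true", "is_a: T:1", "",
    "[Typedef]", "id: part_of"
  ), obo)
  terms <- parse_obo(obo)
  expect_equal(nrow(terms), 4L)
  expect_equal(terms$parents[[2]], "T:1")
  expect_equal(terms$parents[[3]], "T:1")
  expect_equal(terms$synonyms[[2]], "AD")
  expect_equal(terms$obsolete, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("parse_obo errors on missing files and id-less stanzas", {
  expect_error(parse_obo(tempfile()), "cannot read")
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T:1", "", "[Term]", "name: anonymous"), obo)
  expect_error(parse_obo(obo), "stanza 2")
})

test_that("build_graph keeps reachable non-obsolete terms and handles diamonds", {
  terms <- tibble::tibble(
    term_id = c("R", "A", "B", "C"),
    name = c("root", "a", "b", "c"),
    synonyms = list(character(0), character(0), character(0), character(0)),
    parents = list(character(0), "R", "R", c("A", "B")),
    obsolete = FALSE
  )
  g <- build_graph(terms, "R")
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(nrow(g$edges), 4L)
  expect_equal(g$parents[["C"]], c("A", "B"))

  # an obsolete node and its incident edges are dropped; its orphaned
  # child becomes unreachable and is dropped with a warning
  terms2 <- terms
  terms2$obsolete[2] <- TRUE # A obsolete
  terms2$parents[[4]] <- "A" # C only under A
  expect_warning(g2 <- build_graph(terms2, "R"), "not reachable")
  expect_equal(sort(g2$nodes$term_id), c("B", "R"))

  # self-loops and longer cycles are reported as cycles
  terms3 <- terms
  terms3$parents[[2]] <- c("R", "A")
  expect_error(build_graph(terms3, "R"), "cycle")
  expect_error(build_graph(terms, "missing"), "absent or obsolete")
})

test_that("levels equal 1 + longest path from the root", {
  # chain root -> A -> B
  chain <- tibble::tibble(
    term_id = c("R", "A", "B"), name = c("r", "a", "b"),
    synonyms = list(character(0), character(0), character(0)),
    parents = list(character(0), "R", "A"), obsolete = FALSE
  )
  g <- build_graph(chain, "R")
  expect_equal(assign_levels(g)[c("R", "A", "B")], c(R = 1L, A = 2L, B = 3L))

  # diamond where C is reachable by paths of lengths 2 and 3: longest wins
  dia <- tibble::tibble(
    term_id = c("R", "A", "B", "C"), name = c("r", "a", "b", "c"),
    synonyms = list(character(0), character(0), character(0), character(0)),
    parents = list(character(0), "R", "A", c("R", "B")), obsolete = FALSE
  )
  gd <- build_graph(dia, "R")
  expect_equal(assign_levels(gd)[["C"]], 4L)

  # 13-level chain reaches depth 13
  n <- 13
  deep <- tibble::tibble(
    term_id = sprintf("T%02d", 1:n), name = as.character(1:n),
    synonyms = replicate(n, character(0), simplify = FALSE),
    parents = c(list(character(0)), as.list(sprintf("T%02d", 1:(n - 1)))),
    obsolete = FALSE
  )
  expect_equal(max(build_graph(deep, "T01")$nodes$level), 13L)
})

test_that("levels match brute-force path enumeration on random DAGs", {
  for (seed in 1:5) {
    fx <- random_fixture(seed)
    expect_equal(assign_levels(fx$graph), oracle_levels(fx$graph))
    # no edge connects two nodes of the same level
    lev <- stats::setNames(fx$graph$nodes$level, fx$graph$nodes$term_id)
    expect_true(all(lev[fx$graph$edges$child] > lev[fx$graph$edges$parent]))
  }
})

test_that("pruning removes exactly the unannotated leaf cascades and is idempotent", {
  fx <- worked_fixture()
  # full fixture is fully annotated: pruning is a fixed point
  pruned <- prune_unannotated(fx$graph, fx$annotations)
  expect_equal(pruned$nodes, fx$graph$nodes)

  # remove all annotations under W:05's subtree leaves a chain of empty
  # leaves (W:12 -> W:06, and W:11) that must all disappear; W:05 keeps
  # its own direct gene
  direct <- fx$annotations$direct
  direct <- direct[!direct$term_id %in% c("W:06", "W:12", "W:11"), ]
  ann <- propagate_true_path(annotation_table(direct), fx$graph)
  pr <- prune_unannotated(fx$graph, ann)
  expect_false(any(c("W:06", "W:11", "W:12") %in% pr$nodes$term_id))
  expect_true("W:05" %in% pr$nodes$term_id)
  # every surviving node has at least one expanded gene
  expect_true(all(lengths(ann$expanded[pr$nodes$term_id]) >= 1))
  expect_equal(prune_unannotated(pr, ann)$nodes, pr$nodes)

  # empty annotations would prune the root
  empty <- propagate_true_path(
    annotation_table(tibble::tibble(gene = character(0),
                                    term_id = character(0))),
    fx$graph
  )
  expect_error(prune_unannotated(fx$graph, empty), "empty annotation set")
})

test_that("graph_summary reports levels, degrees and gene counts", {
  fx <- worked_fixture()
  s <- graph_summary(fx$graph, fx$annotations)
  expect_equal(nrow(s), 12L)
  expect_equal(s$n_genes[s$term_id == "W:01"], 20L)
  expect_equal(s$n_parents[s$term_id == "W:04"], 2L)
  expect_equal(s$level[s$term_id == "W:12"], 6L)
})
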