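# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: levels by exhaustive path enumeration,
# the hypergeometric tail by subset enumeration / explicit binomial sums,
# BH by the literal step-up definition.

# longest-path levels by enumerating every root-to-node path (DFS over the
# child adjacency); feasible for fixtures up to ~100 nodes
oracle_levels <- function(graph) {
  lev <- stats::setNames(rep(NA_integer_, nrow(graph$nodes)),
                         graph$nodes$term_id)
  walk <- function(node, depth) {
    lev[node] <<- max(lev[node], depth, na.rm = TRUE)
    for (ch in graph$children[[node]]) walk(ch, depth + 1L)
  }
  walk(graph$root, 1L)
  lev
}

# P(overlap >= r) by enumerating every n-subset of an N-gene universe in
# which genes 1..m are annotated
oracle_hyper_enum <- function(N, m, n, r) {
  if (r == 0) return(1)
  if (n == 0) return(0)
  hits <- 0
  sets <- utils::combn(N, n)
  for (j in seq_len(ncol(sets))) {
    if (sum(sets[, j] <= m) >= r) hits <- hits + 1
  }
  hits / ncol(sets)
}

# same tail as an explicit sum of choose() ratios (no log-space shortcuts)
oracle_hyper_sum <- function(N, m, n, r) {
  if (r == 0) return(1)
  k <- seq(r, min(m, n))
  if (length(k) == 0) return(0)
  sum(choose(m, k) * choose(N - m, n - k)) / choose(N, n)
}

# literal step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  M <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(M)
  for (i in seq_len(M)) {
    adj[i] <- min(sorted[i:M] * M / (i:M), 1)
  }
  out <- numeric(M)
  out[o] <- adj
  out
}

# hand-written 12-node worked fixture (diamond + chain, 20 genes)
worked_fixture <- function() {
  dir <- system.file("extdata", "worked", package = "enrichdag")
  terms <- parse_obo(file.path(dir, "ontology.obo"))
  graph <- build_graph(terms, "W:01")
  ann <- load_annotations(file.path(dir, "annotations.tsv"), graph)
  ann <- propagate_true_path(ann, graph)
  interest <- readLines(file.path(dir, "interest.txt"))
  list(terms = terms, graph = graph, annotations = ann, interest = interest)
}

# small random enrichment fixture used across integration tests
random_fixture <- function(seed, n_terms = 60, n_levels = 6, n_genes = 200) {
  ont <- generate_ontology(n_terms, n_levels, seed = seed)
  graph <- build_graph(ont$terms, ont$root_id)
  ann <- generate_annotations(graph, n_genes, seed = seed + 1L)
  ann <- propagate_true_path(ann, graph)
  list(ont = ont, graph = graph, annotations = ann)
}
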