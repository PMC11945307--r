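#' Generate a seeded synthetic ontology
#'
#' Builds a rooted DAG with the structural features a leveled disease
#' ontology exhibits: a backbone chain guarantees the target depth; every
#' other term draws a target level from a mid-peaked law (few terms just
#' under the root, a bulge at intermediate levels, thinning again toward
#' the deepest levels — the census shape of real disease ontologies) and
#' attaches to a parent one level up; a second, strictly shallower parent
#' is added with probability `multi_parent_prob`, producing the diamonds
#' of multiple inheritance. Term ids sort lexicographically in creation
#' order.
#'
#' @param n_terms Total number of terms (including the root).
#' @param n_levels Target depth; the generated DAG reaches at least
#'   `0.8 * n_levels` levels (the backbone guarantees `n_levels` exactly).
#' @param multi_parent_prob Probability that a non-root term gets a second
#'   parent.
#' @param seed Integer seed; identical seeds give identical ontologies.
#' @return A list with `terms` (a term table in the [parse_obo()] layout)
#'   and `root_id`.
#' @export
generate_ontology <- function(n_terms = 100, n_levels = 8,
                              multi_parent_prob = 0.3, seed = 1) {
  stopifnot(n_levels >= 2, n_terms >= n_levels)
  ids <- sprintf("SYN:%06d", seq_len(n_terms))
  with_seed(seed, {
    parents <- rep(list(character(0)), n_terms)
    level <- integer(n_terms)
    level[1] <- 1L
    # backbone chain pins the depth
    for (i in seq(2, n_levels)) {
      parents[[i]] <- ids[i - 1L]
      level[i] <- i
    }
    # mid-peaked target-level law over 2..n_levels
    lv <- seq(2L, n_levels)
    p_lv <- stats::dbeta((lv - 1) / n_levels, 4, 3)
    if (n_terms > n_levels) {
      for (i in seq(n_levels + 1L, n_terms)) {
        tl <- lv[sample.int(length(lv), 1L, prob = p_lv)]
        pool <- which(level[seq_len(i - 1L)] == tl - 1L)
        if (length(pool) == 0L) pool <- which(level[seq_len(i - 1L)] < tl)
        p1 <- pool[sample.int(length(pool), 1L)]
        level[i] <- level[p1] + 1L
        ps <- ids[p1]
        if (stats::runif(1) < multi_parent_prob) {
          shallower <- setdiff(which(level[seq_len(i - 1L)] < level[i]), p1)
          if (length(shallower) > 0L) {
            ps <- c(ps, ids[shallower[sample.int(length(shallower), 1L)]])
          }
        }
        parents[[i]] <- sort(ps)
      }
    }
    terms <- tibble::tibble(
      term_id = ids,
      name = c("disease", paste("synthetic disease", seq_len(n_terms - 1L))),
      synonyms = c(list(character(0)),
                   lapply(seq_len(n_terms - 1L),
                          function(i) paste("syndrome", i))),
      parents = parents,
      obsolete = FALSE
    )
    list(terms = terms, root_id = ids[1L])
  })
}

#' Serialize a term table as an OBO flat file
#'
#' Writes one `[Term]` stanza per row with `id`, `name`, `synonym`,
#' `is_a` and (when set) `is_obsolete` lines, so that
#' [parse_obo()] round-trips the table losslessly.
#'
#' @param terms A term table ([parse_obo()] layout).
#' @param path Output path.
#' @export
write_obo <- function(terms, path) {
  stanza <- function(i) {
    syn <- terms$synonyms[[i]]
    c("[Term]",
      paste0("id: ", terms$term_id[i]),
      paste0("name: ", terms$name[i]),
      if (length(syn)) paste0("synonym: \"", syn, "\" EXACT []"),
      if (length(terms$parents[[i]])) paste0("is_a: ", terms$parents[[i]]),
      if (terms$obsolete[i]) "is_obsolete: true",
      "")
  }
  header <- c("format-version: 1.2", "")
  writeLines(c(header, unlist(lapply(seq_len(nrow(terms)), stanza))), path)
  invisible(path)
}

# discrete truncated power law P(X = k) proportional to k^-alpha, k in 1..kmax
rpowerlaw <- function(n, alpha, kmax) {
  pk <- seq_len(kmax)^(-alpha)
  sample.int(kmax, n, replace = TRUE, prob = pk)
}

#' Generate a heavy-tailed synthetic annotation table
#'
#' Draws each term's direct gene count from a truncated discrete power law
#' (`P(count = k)` proportional to `k^-tail_exponent`), emulating the
#' right-skewed genes-per-term distribution of real ontology annotation
#' sets, where most terms carry a handful of genes and a few carry
#' thousands. Every term receives at least one direct gene, so leaf
#' pruning is a no-op on a fresh fixture.
#'
#' The defaults (`tail_exponent = 1.3`, truncation at 300) put about 68%
#' of terms below 10 direct genes while letting a few terms reach
#' hundreds, the shape observed for genome-scale disease annotation sets.
#'
#' @param graph An `ontology_graph`.
#' @param n_genes Size of the gene universe (ids `g00001`, ...).
#' @param tail_exponent Power-law exponent; smaller values give heavier
#'   tails (default 1.3).
#' @param max_genes_per_term Truncation point of the count law (default
#'   `min(n_genes, 300)`).
#' @param seed Integer seed.
#' @return An [annotation_table] of direct annotations (not yet expanded).
#' @export
generate_annotations <- function(graph, n_genes = 500, tail_exponent = 1.3,
                                 max_genes_per_term = min(n_genes, 300),
                                 seed = 1) {
  stopifnot(inherits(graph, "ontology_graph"), n_genes >= 1)
  genes <- sprintf("g%05d", seq_len(n_genes))
  ids <- graph$nodes$term_id
  with_seed(seed, {
    counts <- rpowerlaw(length(ids), tail_exponent, max_genes_per_term)
    direct <- tibble::tibble(
      gene = unlist(lapply(counts, function(k) sample(genes, k)),
                    use.names = FALSE),
      term_id = rep(ids, counts)
    )
    annotation_table(direct)
  })
}

#' Implant an interest set with known enriched terms
#'
#' Constructs a gene list carrying planted signal: each signal term
#' contributes its directly annotated genes independently with probability
#' `1 - 1/strength` (so strengths just above 1 contribute almost nothing
#' and the noiseless limit of infinite strength contributes every direct
#' gene), and every other background gene joins with probability
#' `background_rate`.
#'
#' @param graph An `ontology_graph` (signal terms must be nodes).
#' @param annotations An expanded [annotation_table].
#' @param signal_terms Character vector of implanted term ids, or a named
#'   numeric vector mapping term ids to strengths (> 1).
#' @param strength Common strength used when `signal_terms` is unnamed
#'   (default 1e9, i.e. effectively certain inclusion).
#' @param background_rate Probability that a non-signal background gene
#'   joins the list (default 0).
#' @param seed Integer seed.
#' @return Sorted character vector of genes, with the implanted term ids
#'   attached as attribute `signal_terms`.
#' @export
implant_interest <- function(graph, annotations, signal_terms,
                             strength = 1e9, background_rate = 0,
                             seed = 1) {
  stopifnot(inherits(graph, "ontology_graph"),
            inherits(annotations, "annotation_table"),
            background_rate >= 0, background_rate <= 1)
  if (is.numeric(signal_terms)) {
    strengths <- signal_terms
  } else {
    strengths <- stats::setNames(rep(strength, length(signal_terms)),
                                 signal_terms)
  }
  stopifnot(all(strengths > 1))
  missing <- setdiff(names(strengths), graph$nodes$term_id)
  if (length(missing) > 0L) {
    stop("signal term(s) absent from the graph: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    picked <- unlist(lapply(names(strengths), function(t) {
      g <- annotations$direct$gene[annotations$direct$term_id == t]
      g[stats::runif(length(g)) < 1 - 1 / strengths[[t]]]
    }), use.names = FALSE)
    if (background_rate > 0) {
      pool <- setdiff(annotations$universe, picked)
      picked <- c(picked, pool[stats::runif(length(pool)) < background_rate])
    }
    structure(sort(unique(picked)), signal_terms = sort(names(strengths)))
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Generates an ontology, annotations and an implanted interest list under
#' one of three presets and writes them as `ontology.obo`,
#' `annotations.tsv` and `interest.txt` in `dir`.
#'
#' Presets: `"small"` (60 terms / 6 levels / 200 genes), `"deep"`
#' (200 terms / 13 levels / 400 genes, mirroring a deep ontology), and
#' `"skewed"` (150 terms / 8 levels / 500 genes with a heavier annotation
#' tail).
#'
#' @param preset One of `"small"`, `"deep"`, `"skewed"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths (invisibly) plus the
#'   implanted term ids as attribute `signal_terms`.
#' @export
make_fixture <- function(preset = c("small", "deep", "skewed"), seed = 1,
                         dir = tempfile("fixture")) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    small = list(n_terms = 60, n_levels = 6, n_genes = 200, tail = 1.8),
    deep = list(n_terms = 200, n_levels = 13, n_genes = 400, tail = 1.8),
    skewed = list(n_terms = 150, n_levels = 8, n_genes = 500, tail = 1.3)
  )
  ont <- generate_ontology(cfg$n_terms, cfg$n_levels, seed = seed)
  graph <- build_graph(ont$terms, ont$root_id)
  ann <- generate_annotations(graph, cfg$n_genes, tail_exponent = cfg$tail,
                              seed = seed + 1L)
  ann <- propagate_true_path(ann, graph)
  known <- select_known_terms(ann, k = 5, seed = seed + 2L)
  interest <- implant_interest(graph, ann, known, seed = seed + 3L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    interest = file.path(dir, "interest.txt")
  )
  write_obo(ont$terms, paths$obo)
  write_annotations(ann, paths$annotations)
  writeLines(interest, paths$interest)
  invisible(structure(paths, signal_terms = attr(interest, "signal_terms")))
}
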