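#' Parse an OBO flat file into a term table
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 flat file and returns one row
#' per term. Only the fields the enrichment model consumes are parsed: `id`,
#' `name`, `synonym` (the quoted surface string), `is_a` (trailing `!`
#' comments stripped) and `is_obsolete`. Other stanza types (`[Typedef]`,
#' `[Instance]`) and other relationship lines (`part_of`, ...) are ignored:
#' the ontology DAG is built from `is_a` alone.
#'
#' @param path Path to an OBO flat file.
#' @return A tibble with one row per `[Term]` stanza and columns `term_id`,
#'   `name`, `synonyms` (list of character), `parents` (list of character,
#'   `is_a` targets) and `obsolete` (logical).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "[Term]", "id: T:1", "name: disease", "",
#'   "[Term]", "id: T:2", "name: tauopathy",
#'   "synonym: \"tau disease\" EXACT []", "is_a: T:1 ! disease"
#' ), obo)
#' parse_obo(obo)
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read OBO file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  # stanza boundaries: a [Term] header opens a term stanza, any other
  # [Header] closes it
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) {
    stop("no [Term] stanza found in ", path, call. = FALSE)
  }
  headers <- which(grepl("^\\[.+\\]$", lines))
  ends <- vapply(starts, function(s) {
    nxt <- headers[headers > s]
    if (length(nxt) == 0L) length(lines) else nxt[1L] - 1L
  }, integer(1))

  parse_stanza <- function(i) {
    body <- lines[seq(starts[i] + 1L, ends[i])]
    body <- body[nzchar(body) & !grepl("^!", body)]
    key <- sub("^([A-Za-z_]+):.*$", "\\1", body)
    val <- stringr::str_trim(sub("^[A-Za-z_]+:", "", body))
    id <- val[key == "id"]
    if (length(id) == 0L || !nzchar(id[1L])) {
      stop("OBO stanza ", i, " has no id line", call. = FALSE)
    }
    syn_raw <- val[key == "synonym"]
    synonyms <- stringr::str_match(syn_raw, "^\"(.*)\"")[, 2L]
    synonyms <- synonyms[!is.na(synonyms)]
    isa <- val[key == "is_a"]
    isa <- stringr::str_trim(sub("!.*$", "", isa))
    isa <- isa[nzchar(isa)]
    name <- val[key == "name"]
    list(
      term_id = id[1L],
      name = if (length(name)) name[1L] else NA_character_,
      synonyms = synonyms,
      parents = unique(isa),
      obsolete = any(tolower(val[key == "is_obsolete"]) == "true")
    )
  }

  stanzas <- lapply(seq_along(starts), parse_stanza)
  tibble::tibble(
    term_id = vapply(stanzas, `[[`, character(1), "term_id"),
    name = vapply(stanzas, `[[`, character(1), "name"),
    synonyms = lapply(stanzas, `[[`, "synonyms"),
    parents = lapply(stanzas, `[[`, "parents"),
    obsolete = vapply(stanzas, `[[`, logical(1), "obsolete")
  )
}

#' Build a rooted is_a DAG from a term table
#'
#' Keeps the non-obsolete terms reachable from `root_id` by descending is_a
#' edges, verifies acyclicity, and assigns each node its level: 1 for the
#' root, and 1 + the length of the longest root-to-node path otherwise.
#' Nodes on one level never share an edge, so a level-by-level sweep can
#' treat them independently.
#'
#' @param terms A term table as returned by [parse_obo()].
#' @param root_id Term id of the root (e.g. `"DOID:4"` for the Disease
#'   Ontology). Must be present and non-obsolete.
#' @return An `ontology_graph` object: a list with a `nodes` tibble
#'   (`term_id`, `name`, `level`), an `edges` tibble (`child`, `parent`),
#'   parent/child adjacency lists and the root id.
#' @export
build_graph <- function(terms, root_id) {
  stopifnot(is.data.frame(terms), nrow(terms) > 0)
  keep <- !terms$obsolete
  terms <- terms[keep, , drop = FALSE]
  if (!root_id %in% terms$term_id) {
    stop("root term ", root_id, " is absent or obsolete", call. = FALSE)
  }
  ids <- terms$term_id
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  # child -> parent edges restricted to retained (non-obsolete) terms
  edges <- tibble::tibble(
    child = rep(ids, lengths(terms$parents)),
    parent = unlist(terms$parents, use.names = FALSE)
  )
  edges <- dplyr::filter(edges, .data$parent %in% ids)

  cyc <- find_cycle(ids, edges)
  if (!is.null(cyc)) {
    stop("is_a cycle detected: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }

  children <- split(edges$child, factor(edges$parent, levels = ids))
  reachable <- descendants_of(root_id, children)
  dropped <- setdiff(ids, reachable)
  if (length(dropped) > 0L) {
    warning(length(dropped), " term(s) not reachable from ", root_id,
            " were dropped", call. = FALSE)
  }
  keep_ids <- sort(reachable)
  edges <- dplyr::filter(edges, .data$child %in% keep_ids,
                         .data$parent %in% keep_ids)
  terms <- terms[match(keep_ids, terms$term_id), , drop = FALSE]

  g <- new_ontology_graph(terms, edges, root_id)
  g$nodes$level <- unname(assign_levels(g)[g$nodes$term_id])
  g
}

new_ontology_graph <- function(terms, edges, root_id) {
  ids <- terms$term_id
  fac <- function(x) factor(x, levels = ids)
  structure(
    list(
      nodes = tibble::tibble(term_id = ids, name = terms$name,
                             level = NA_integer_),
      edges = edges,
      root = root_id,
      parents = lapply(split(edges$parent, fac(edges$child)), sort),
      children = lapply(split(edges$child, fac(edges$parent)), sort),
      terms = terms
    ),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$nodes), " terms, ", nrow(x$edges),
      " is_a edges, root ", x$root,
      ", depth ", max(x$nodes$level), "\n", sep = "")
  invisible(x)
}

# depth-first search for one directed cycle; returns the cycle path or NULL
find_cycle <- function(ids, edges) {
  adj <- split(edges$parent, factor(edges$child, levels = ids))
  state <- stats::setNames(integer(length(ids)), ids) # 0 new, 1 open, 2 done
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (u in adj[[v]]) {
      if (state[[u]] == 1L) {
        found <<- c(path[seq(match(u, path), length(path))], u)
        return()
      }
      if (state[[u]] == 0L) visit(u)
      if (!is.null(found)) return()
    }
    state[[v]] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in ids) if (state[[v]] == 0L) visit(v)
  found
}

descendants_of <- function(root_id, children) {
  seen <- character(0)
  frontier <- root_id
  while (length(frontier) > 0L) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  unique(seen)
}

#' Longest-path levels of a rooted DAG
#'
#' Level of the root is 1; every other node's level is 1 plus the maximum
#' level among its parents, i.e. 1 + the number of edges on the longest path
#' from the root. Computed by dynamic programming over a topological order.
#'
#' @param graph An `ontology_graph`.
#' @return Named integer vector of levels, one entry per node.
#' @export
assign_levels <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  ids <- graph$nodes$term_id
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = ids)
  )
  # topological order along child -> parent edges puts parents last;
  # reverse it so every parent precedes its children
  topo <- rev(names(igraph::topo_sort(ig, mode = "out")))
  lev <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  lev[graph$root] <- 1L
  for (v in topo) {
    if (v == graph$root) next
    pl <- lev[graph$parents[[v]]]
    if (length(pl) == 0L || anyNA(pl)) {
      stop("node ", v, " is not reachable from the root", call. = FALSE)
    }
    lev[v] <- 1L + max(pl)
  }
  lev
}

#' Iteratively prune annotation-free leaves
#'
#' Repeatedly removes leaf terms (no retained children) whose true-path
#' expanded gene set is empty, until every remaining term carries at least
#' one annotated gene, then recomputes levels on the pruned graph (pruning
#' can remove longest paths).
#'
#' @param graph An `ontology_graph`.
#' @param annotations An expanded [annotation_table] (see
#'   [propagate_true_path()]).
#' @return The pruned, re-leveled `ontology_graph`.
#' @export
prune_unannotated <- function(graph, annotations) {
  stopifnot(inherits(graph, "ontology_graph"),
            inherits(annotations, "annotation_table"))
  if (!annotations$expanded_done) {
    stop("annotations must be true-path expanded before pruning",
         call. = FALSE)
  }
  n_genes <- vapply(annotations$expanded[graph$nodes$term_id], length,
                    integer(1))
  n_genes[is.na(n_genes)] <- 0L
  names(n_genes) <- graph$nodes$term_id

  keep <- graph$nodes$term_id
  edges <- graph$edges
  repeat {
    n_child <- table(factor(edges$parent, levels = keep))
    leaves <- keep[n_child[keep] == 0L]
    drop <- leaves[n_genes[leaves] == 0L]
    if (length(drop) == 0L) break
    if (graph$root %in% drop) stop("empty annotation set", call. = FALSE)
    keep <- setdiff(keep, drop)
    edges <- dplyr::filter(edges, !.data$child %in% drop,
                           !.data$parent %in% drop)
  }
  terms <- graph$terms[match(sort(keep), graph$terms$term_id), , drop = FALSE]
  g <- new_ontology_graph(terms, edges, graph$root)
  g$nodes$level <- unname(assign_levels(g)[g$nodes$term_id])
  g
}

#' All ancestors of every node
#'
#' @param graph An `ontology_graph`.
#' @return Named list mapping each term id to the sorted character vector of
#'   its ancestors (excluding itself; empty for the root).
#' @export
ontology_ancestors <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  lev <- stats::setNames(graph$nodes$level, graph$nodes$term_id)
  anc <- vector("list", nrow(graph$nodes))
  names(anc) <- graph$nodes$term_id
  for (v in graph$nodes$term_id[order(lev, graph$nodes$term_id)]) {
    ps <- graph$parents[[v]]
    anc[[v]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  anc
}

#' Per-term structural summary
#'
#' One row per node with its level, parent/child counts and (optionally)
#' the size of its expanded gene set — the per-level census view of a
#' leveled, annotated ontology.
#'
#' @param graph An `ontology_graph`.
#' @param annotations Optional expanded [annotation_table].
#' @return A tibble with columns `term_id`, `name`, `level`, `n_parents`,
#'   `n_children` and, when annotations are given, `n_genes`.
#' @export
graph_summary <- function(graph, annotations = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  out <- dplyr::mutate(
    graph$nodes,
    n_parents = unname(lengths(graph$parents[.data$term_id])),
    n_children = unname(lengths(graph$children[.data$term_id]))
  )
  if (!is.null(annotations)) {
    out$n_genes <- unname(vapply(annotations$expanded[out$term_id], length,
                                 integer(1)))
  }
  dplyr::arrange(out, .data$level, .data$term_id)
}
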