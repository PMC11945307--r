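#' Gene-to-term annotation tables
#'
#' An `annotation_table` holds the direct gene-term pairs plus, after
#' [propagate_true_path()], the expanded annotation: for every term, the
#' genes annotated to it or to any of its descendants, each with an
#' origin distance — the minimum number of levels the annotation was
#' inherited upward to reach the term (0 for a direct annotation).
#'
#' @param direct A tibble with character columns `gene` and `term_id`.
#' @return An `annotation_table` with empty expansion.
#' @export
annotation_table <- function(direct) {
  stopifnot(is.data.frame(direct), all(c("gene", "term_id") %in% names(direct)))
  direct <- dplyr::distinct(
    dplyr::arrange(tibble::as_tibble(direct[, c("gene", "term_id")]),
                   .data$gene, .data$term_id)
  )
  structure(
    list(direct = direct, expanded = list(), expanded_done = FALSE,
         universe = character(0)),
    class = "annotation_table"
  )
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("<annotation_table> ", nrow(x$direct), " direct gene-term pairs (",
      length(unique(x$direct$gene)), " genes, ",
      length(unique(x$direct$term_id)), " terms); ",
      if (x$expanded_done) {
        paste0("expanded over ", length(x$expanded), " terms, universe ",
               length(x$universe), " genes")
      } else "not expanded",
      "\n", sep = "")
  invisible(x)
}

#' Load direct annotations from a two-column TSV
#'
#' Reads `gene<TAB>term_id` rows (an optional third column is ignored, an
#' optional header line starting with `gene` is skipped), de-duplicates
#' them, and drops pairs whose term is not in the graph with a single
#' counted warning.
#'
#' @param path Path to the TSV file.
#' @param graph An `ontology_graph`; rows referencing terms outside it are
#'   dropped.
#' @return An `annotation_table` (not yet expanded).
#' @export
load_annotations <- function(path, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty annotation file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop("malformed annotation row at line ", bad[1L],
         " (need gene<TAB>term_id)", call. = FALSE)
  }
  gene <- vapply(fields, `[[`, character(1), 1L)
  term <- vapply(fields, `[[`, character(1), 2L)
  if (tolower(gene[1L]) %in% c("gene", "gene_id", "geneid")) {
    gene <- gene[-1L]
    term <- term[-1L]
  }
  known <- term %in% graph$nodes$term_id
  if (any(!known)) {
    warning(sum(!known), " annotation row(s) referenced terms absent from ",
            "the graph and were dropped", call. = FALSE)
  }
  annotation_table(tibble::tibble(gene = gene[known], term_id = term[known]))
}

#' Expand annotations along the true-path rule
#'
#' A gene annotated to a term is implicitly annotated to all of that term's
#' ancestors. The expansion records, per (term, gene), the origin distance:
#' the difference in levels between the term and the shallowest directly
#' annotated descendant carrying the gene (minimum over all such
#' descendants; 0 when the gene is directly annotated to the term itself).
#' When several annotated descendants contribute the same gene, the minimum
#' distance — hence the strongest eventual weight — is kept.
#'
#' @param table An `annotation_table`.
#' @param graph A leveled `ontology_graph`.
#' @return The `annotation_table` with `expanded` filled in: a list mapping
#'   each annotated term to a named numeric vector of origin distances
#'   (names are gene ids), and `universe` set to all annotated genes.
#' @export
propagate_true_path <- function(table, graph) {
  stopifnot(inherits(table, "annotation_table"),
            inherits(graph, "ontology_graph"))
  lev <- stats::setNames(graph$nodes$level, graph$nodes$term_id)
  direct <- dplyr::filter(table$direct, .data$term_id %in% names(lev))

  # minlev[[t]][g]: the shallowest level at which gene g is directly
  # annotated among t and its descendants; distance = minlev - level(t)
  by_term <- split(direct$gene, factor(direct$term_id, levels = names(lev)))
  minlev <- vector("list", length(lev))
  names(minlev) <- names(lev)
  for (t in names(lev)[order(lev, names(lev), decreasing = c(TRUE, FALSE),
                             method = "radix")]) {
    own <- unique(by_term[[t]])
    acc <- if (length(own)) stats::setNames(rep(lev[[t]], length(own)), own)
           else stats::setNames(numeric(0), character(0))
    for (ch in graph$children[[t]]) {
      cl <- minlev[[ch]]
      if (length(cl) == 0L) next
      new <- setdiff(names(cl), names(acc))
      acc[new] <- Inf
      acc[names(cl)] <- pmin(acc[names(cl)], cl)
    }
    minlev[[t]] <- acc
  }

  expanded <- lapply(names(lev), function(t) {
    d <- minlev[[t]] - lev[[t]]
    d[order(names(d), method = "radix")]
  })
  names(expanded) <- names(lev)
  expanded <- expanded[lengths(expanded) > 0L]

  table$expanded <- expanded
  table$expanded_done <- TRUE
  table$universe <- sort(unique(direct$gene))
  table
}

#' Expanded annotation as a tidy tibble
#'
#' @param x An expanded `annotation_table`.
#' @param ... Unused.
#' @return A tibble with columns `term_id`, `gene`, `distance` (levels the
#'   annotation was inherited upward; 0 = direct).
#' @export
tidy.annotation_table <- function(x, ...) {
  if (!x$expanded_done) {
    return(dplyr::mutate(x$direct, distance = 0)[, c("term_id", "gene",
                                                     "distance")])
  }
  tibble::tibble(
    term_id = rep(names(x$expanded), lengths(x$expanded)),
    gene = unlist(lapply(x$expanded, names), use.names = FALSE),
    distance = unlist(x$expanded, use.names = FALSE)
  )
}

#' Write direct annotations as a two-column TSV
#'
#' @param table An `annotation_table`.
#' @param path Output path.
#' @export
write_annotations <- function(table, path) {
  stopifnot(inherits(table, "annotation_table"))
  readr::write_tsv(table$direct, path, col_names = FALSE)
  invisible(path)
}

#' Build a surface-string dictionary from ontology terms
#'
#' Collects the names and synonyms of non-obsolete terms, case-folds and
#' whitespace-normalizes them, and drops strings shorter than 3 characters.
#' When two terms share a surface string the lexicographically smallest
#' term id wins and a collision warning is raised.
#'
#' @param terms A term table as returned by [parse_obo()].
#' @return A `term_dictionary`: a tibble with columns `surface` and
#'   `term_id`, one row per retained surface string.
#' @export
build_dictionary <- function(terms) {
  stopifnot(is.data.frame(terms))
  terms <- terms[!terms$obsolete, , drop = FALSE]
  entries <- tibble::tibble(
    surface = c(terms$name, unlist(terms$synonyms, use.names = FALSE)),
    term_id = c(terms$term_id, rep(terms$term_id, lengths(terms$synonyms)))
  )
  entries$surface <- stringr::str_squish(tolower(entries$surface))
  entries <- dplyr::filter(entries, !is.na(.data$surface),
                           nchar(.data$surface) >= 3L)
  entries <- dplyr::distinct(entries)
  clash <- entries$surface[duplicated(entries$surface)]
  if (length(clash) > 0L) {
    warning(length(unique(clash)), " surface string(s) mapped to several ",
            "terms; keeping the smallest term id for each", call. = FALSE)
  }
  out <- dplyr::slice_min(dplyr::group_by(entries, .data$surface),
                          .data$term_id, n = 1, with_ties = FALSE)
  out <- dplyr::arrange(dplyr::ungroup(out), .data$surface)
  structure(out, class = c("term_dictionary", class(out)))
}

#' Match dictionary entries in free text
#'
#' Case-insensitive longest-match scan at word boundaries: candidate
#' surfaces are tried longest first, and any shorter match overlapping an
#' already accepted span is suppressed. This is a deliberately simple exact
#' phrase matcher for concept recognition in short functional descriptions
#' (GeneRIF-like text).
#'
#' @param dictionary A `term_dictionary` from [build_dictionary()].
#' @param text A single character string.
#' @return Sorted character vector of the matched term ids (deduplicated);
#'   empty when nothing matches.
#' @export
annotate_text <- function(dictionary, text) {
  stopifnot(inherits(dictionary, "term_dictionary"),
            is.character(text), length(text) == 1L, nzchar(text))
  hay <- stringr::str_squish(tolower(text))
  surfaces <- dictionary$surface[order(-nchar(dictionary$surface),
                                       dictionary$surface)]
  taken <- matrix(numeric(0), ncol = 2) # accepted [start, end] spans
  hits <- character(0)
  for (s in surfaces) {
    pat <- paste0("(?<![[:alnum:]])", escape_regex(s), "(?![[:alnum:]])")
    m <- gregexpr(pat, hay, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (k in seq_along(m)) {
      a <- m[k]
      b <- a + attr(m, "match.length")[k] - 1L
      overlaps <- nrow(taken) > 0 && any(a <= taken[, 2] & b >= taken[, 1])
      if (!overlaps) {
        taken <- rbind(taken, c(a, b))
        hits <- c(hits, dictionary$term_id[dictionary$surface == s])
      }
    }
  }
  sort(unique(hits))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
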