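# run code under a private, restorable RNG state so studies never disturb
# (or depend on) the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# per-rep seeds derived from a master seed; kept below .Machine$integer.max
derive_seed <- function(seed, rep) (as.integer(seed) + 7919L * as.integer(rep)) %% 2147483629L

#' Randomly select "known" terms from the middle of the annotation-size range
#'
#' Terms with very few or very many annotated genes are biased ground
#' truths for a recovery simulation, so candidates are ordered by
#' annotation count (ascending, ties by term id) and the draw is
#' restricted to ranks strictly above the 25th percentile and up to the
#' 75th percentile of that ordering. By default the ordering uses the
#' true-path expanded counts, which is what "genes annotated to a term"
#' means once the expansion is in force; `by = "direct"` orders by direct
#' annotations only.
#'
#' @param annotations An [annotation_table] (expanded when
#'   `by = "expanded"`, the default).
#' @param k Number of terms to implant as ground truth.
#' @param seed Integer seed; identical seeds give identical selections.
#' @param by Count ordering: `"expanded"` (default) or `"direct"`.
#' @return Sorted character vector of `k` term ids.
#' @export
select_known_terms <- function(annotations, k, seed,
                               by = c("expanded", "direct")) {
  by <- match.arg(by)
  stopifnot(inherits(annotations, "annotation_table"), k >= 1)
  if (by == "expanded") {
    if (!annotations$expanded_done) {
      stop("annotations must be expanded for by = \"expanded\"",
           call. = FALSE)
    }
    counts <- tibble::tibble(term_id = names(annotations$expanded),
                             n = lengths(annotations$expanded))
  } else {
    counts <- dplyr::count(annotations$direct, .data$term_id)
  }
  counts <- dplyr::arrange(counts, .data$n, .data$term_id)
  total <- nrow(counts)
  lo <- floor(0.25 * total)
  hi <- floor(0.75 * total)
  eligible <- counts$term_id[seq_len(total) > lo & seq_len(total) <= hi]
  if (k > length(eligible)) {
    stop("only ", length(eligible), " terms in the middle 50%; cannot ",
         "select ", k, call. = FALSE)
  }
  with_seed(seed, sort(sample(eligible, k)))
}

#' Build an interest set from implanted terms
#'
#' Takes the union of the terms' gene sets — directly annotated genes
#' (`mode = "direct"`) or the full true-path expansion
#' (`mode = "expanded"`) — and removes promiscuous genes annotated to
#' `max_terms_per_gene` or more terms, which carry little term-specific
#' signal. The promiscuity count is taken in the same annotation space as
#' the interest set itself: direct annotations per gene in direct mode,
#' expanded (inherited) annotations per gene in expanded mode. An
#' expansion-derived list naturally loses many more genes to the filter,
#' since every direct annotation inherits to the whole ancestor chain.
#'
#' @param terms Character vector of term ids.
#' @param annotations An expanded [annotation_table].
#' @param mode `"direct"` or `"expanded"`.
#' @param max_terms_per_gene Promiscuity cutoff on the per-gene term count
#'   (default 30; `Inf` disables).
#' @return Sorted character vector of genes.
#' @export
build_interest_set <- function(terms, annotations,
                               mode = c("direct", "expanded"),
                               max_terms_per_gene = 30) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotations, "annotation_table"))
  if (mode == "expanded" && !annotations$expanded_done) {
    stop("annotations must be expanded for mode = \"expanded\"",
         call. = FALSE)
  }
  if (mode == "direct") {
    genes <- annotations$direct$gene[annotations$direct$term_id %in% terms]
    per_gene <- table(annotations$direct$gene)
  } else {
    genes <- unlist(
      lapply(annotations$expanded[intersect(terms,
                                            names(annotations$expanded))],
             names),
      use.names = FALSE
    )
    per_gene <- table(unlist(lapply(annotations$expanded, names),
                             use.names = FALSE))
  }
  genes <- sort(unique(genes))
  promiscuous <- names(per_gene)[per_gene >= max_terms_per_gene]
  genes <- setdiff(genes, promiscuous)
  if (length(genes) == 0L) {
    stop("interest set is empty after the promiscuity filter", call. = FALSE)
  }
  genes
}

#' Overlap of a ranked result with known terms at top-k cutoffs
#'
#' Counts, for each cutoff `c`, how many of the top `c` significant terms
#' (raw p within the result's traversal threshold) are among the known
#' term ids. Only terms passing the threshold are ranked.
#'
#' @param result An `enrich_result` sorted by ascending p.
#' @param known Character vector of ground-truth term ids.
#' @param cutoffs Positive ascending integer cutoffs.
#' @return A tibble with columns `cutoff`, `overlap`, `fraction`
#'   (overlap / number of known terms).
#' @export
evaluate_overlap <- function(result, known, cutoffs = c(25, 50, 100)) {
  stopifnot(inherits(result, "enrich_result"),
            all(cutoffs > 0), !is.unsorted(cutoffs))
  thr <- attr(result, "params")$threshold
  ranked <- result$term_id[result$p <= thr]
  ov <- vapply(cutoffs, function(ct) {
    length(intersect(utils::head(ranked, ct), known))
  }, integer(1))
  tibble::tibble(cutoff = as.integer(cutoffs), overlap = ov,
                 fraction = ov / length(known))
}

#' Perturb an interest gene list
#'
#' Either removes a fraction of the list uniformly at random, or adds a
#' fraction of noise genes sampled from the background outside the list.
#' At most one of the two fractions may be nonzero.
#'
#' @param interest Character vector of interesting genes.
#' @param background Character vector of background genes (superset used
#'   for noise sampling).
#' @param remove_frac,noise_frac Fractions in `[0, 0.3]`; the perturbation
#'   size is `round(frac * length(interest))`.
#' @param seed Integer seed.
#' @return The perturbed gene list (sorted).
#' @export
perturb_gene_list <- function(interest, background, remove_frac = 0,
                              noise_frac = 0, seed = 1) {
  stopifnot(remove_frac >= 0, remove_frac <= 0.3,
            noise_frac >= 0, noise_frac <= 0.3)
  if (remove_frac > 0 && noise_frac > 0) {
    stop("set only one of remove_frac and noise_frac", call. = FALSE)
  }
  interest <- sort(unique(interest))
  if (remove_frac > 0) {
    k <- round(remove_frac * length(interest))
    return(with_seed(seed, sort(setdiff(interest,
                                        sample(interest, k)))))
  }
  if (noise_frac > 0) {
    k <- round(noise_frac * length(interest))
    pool <- setdiff(background, interest)
    if (length(pool) < k) {
      stop("background too small: need ", k, " noise genes, have ",
           length(pool), call. = FALSE)
    }
    return(with_seed(seed, sort(c(interest, sample(pool, k)))))
  }
  interest
}

#' Recovery (accuracy) simulation with implanted known terms
#'
#' For each repetition: select `k_known` ground-truth terms from the middle
#' 50% of the direct-annotation-size ordering, build the interest set from
#' their genes, run both the weighted model and classic ORA, and count the
#' overlap between the top-ranked significant terms and the implanted
#' ground truth at each cutoff.
#'
#' @param graph A pruned, leveled `ontology_graph`.
#' @param annotations An expanded [annotation_table].
#' @param k_known Number of implanted terms per repetition.
#' @param mode Interest-set construction, `"direct"` or `"expanded"` (see
#'   [build_interest_set()]).
#' @param n_reps Number of repetitions.
#' @param seed Master seed; per-rep seeds are derived deterministically.
#' @param cutoffs Top-k cutoffs for overlap counting.
#' @param max_terms_per_gene Promiscuity cutoff, see [build_interest_set()].
#' @param ... Further parameters for [run_enrichment()].
#' @return A `recovery_report` tibble with one row per
#'   (rep, method, cutoff): columns `rep`, `method` (`"weighted"` or
#'   `"classic"`), `cutoff`, `overlap`, `fraction`.
#' @export
run_recovery_study <- function(graph, annotations, k_known = 10,
                               mode = c("direct", "expanded"),
                               n_reps = 20, seed = 1,
                               cutoffs = c(25, 50, 100),
                               max_terms_per_gene = 30, ...) {
  mode <- match.arg(mode)
  reps <- lapply(seq_len(n_reps), function(i) {
    s <- derive_seed(seed, i)
    known <- select_known_terms(annotations, k_known, s)
    interest <- build_interest_set(known, annotations, mode,
                                   max_terms_per_gene)
    one <- function(method) {
      res <- run_enrichment(graph, annotations, interest, method = method,
                            ...)
      dplyr::mutate(evaluate_overlap(res, known, cutoffs),
                    rep = i, method = method, .before = 1)
    }
    dplyr::bind_rows(one("weighted"), one("classic"))
  })
  out <- dplyr::bind_rows(reps)
  structure(out, class = c("recovery_report", class(out)),
            k_known = k_known, mode = mode, seed = seed)
}

#' Perturbation robustness study
#'
#' Reruns the enrichment after perturbing the interest list (removal or
#' added noise) at increasing fractions, and measures how much of the
#' unperturbed top-`top_k` significant term set survives.
#'
#' @param graph,annotations,interest As for [run_enrichment()].
#' @param kind `"remove"` or `"noise"`.
#' @param levels Perturbation fractions (default 0 to 0.3 in steps of
#'   0.05).
#' @param n_reps Repetitions per level.
#' @param seed Master seed.
#' @param top_k Size of the reference top set (default 100).
#' @param ... Further parameters for [run_enrichment()].
#' @return A `perturbation_report` tibble with one row per (level, rep):
#'   `level`, `rep`, `overlap` (terms of the unperturbed top set
#'   recovered), `ratio` (overlap / size of the unperturbed top set).
#' @export
run_perturbation_study <- function(graph, annotations, interest,
                                   kind = c("remove", "noise"),
                                   levels = seq(0, 0.30, by = 0.05),
                                   n_reps = 100, seed = 1, top_k = 100,
                                   ...) {
  kind <- match.arg(kind)
  base <- run_enrichment(graph, annotations, interest, ...)
  thr <- attr(base, "params")$threshold
  base_top <- utils::head(base$term_id[base$p <= thr], top_k)
  if (length(base_top) == 0L) {
    stop("the unperturbed run has no significant terms", call. = FALSE)
  }
  grid <- tidyr::expand_grid(level = levels, rep = seq_len(n_reps))
  overlap <- purrr::pmap_int(grid, function(level, rep) {
    if (level == 0) return(length(base_top))
    s <- derive_seed(seed, rep + 1000L * match(level, levels))
    pert <- perturb_gene_list(
      interest, annotations$universe,
      remove_frac = if (kind == "remove") level else 0,
      noise_frac = if (kind == "noise") level else 0,
      seed = s
    )
    res <- run_enrichment(graph, annotations, pert, ...)
    top <- utils::head(res$term_id[res$p <= thr], top_k)
    length(intersect(top, base_top))
  })
  out <- dplyr::mutate(grid, overlap = overlap,
                       ratio = overlap / length(base_top))
  structure(out, class = c("perturbation_report", class(out)),
            kind = kind, top_k = top_k, seed = seed,
            baseline_top = base_top)
}

#' Per-level means of a perturbation report
#'
#' @param report A `perturbation_report`.
#' @return A tibble with `level`, `mean_overlap`, `mean_ratio`.
#' @export
summarise_perturbation <- function(report) {
  stopifnot(inherits(report, "perturbation_report"))
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(report), .data$level),
                   mean_overlap = mean(.data$overlap),
                   mean_ratio = mean(.data$ratio), .groups = "drop")
}
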