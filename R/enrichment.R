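#' Initial per-(term, gene) weights
#'
#' Directly annotated genes start at weight 1; a gene inherited upward
#' along the true-path rule loses `weight_step` per level of inheritance,
#' floored at `min_init_weight`:
#' `w = max(1 - weight_step * distance, min_init_weight)`.
#' With the defaults (step 0.1, floor 0.5) an annotation inherited 2 levels
#' up weighs 0.8 and nothing ever weighs less than 0.5, so indirect
#' evidence is damped but never erased.
#'
#' @param annotations An expanded [annotation_table].
#' @param weight_step Per-level decay of inherited annotations.
#' @param min_init_weight Floor of the initial weights.
#' @return A list mapping each annotated term to a named numeric weight
#'   vector over its expanded gene set.
#' @export
initial_weights <- function(annotations, weight_step = 0.1,
                            min_init_weight = 0.5) {
  stopifnot(inherits(annotations, "annotation_table"),
            annotations$expanded_done,
            weight_step >= 0, weight_step < 1,
            min_init_weight > 0, min_init_weight <= 1)
  lapply(annotations$expanded, function(d) {
    pmax(1 - weight_step * d, min_init_weight)
  })
}

#' Dynamic weight of a parent-child term pair
#'
#' The log-ratio `log(p_child) / log(p_parent)` of the two significance
#' scores (natural log). A value above 1 means the child is more
#' significant than the parent; scores of exactly 1 are nudged just below
#' 1 before taking logs.
#'
#' @param p_child,p_parent Significance scores in `(0, 1]`.
#' @return The dynamic weight (a positive ratio).
#' @examples
#' dynamic_weight(1e-6, 1e-3) # 2: the child is more significant
#' @export
dynamic_weight <- function(p_child, p_parent) {
  if (any(c(p_child, p_parent) <= 0) || any(c(p_child, p_parent) > 1)) {
    stop("significance scores must lie in (0, 1]", call. = FALSE)
  }
  log(clamp_for_log(p_child)) / log(clamp_for_log(p_parent))
}

#' Penalty score of a parent-child term pair
#'
#' A multiplicative weight-reduction factor that kicks in when parent and
#' child are similarly significant but neither is extreme:
#' `max(penalty_scale * log(xmin) / (log(p_parent) + log(p_child)), 1)`
#' with `xmin` the smallest positive normalized double (so `log(xmin)`
#' is about -708.4, natural log). For moderate p-values the ratio is large
#' and the penalty dominates the dynamic weight; for very small p-values
#' it falls below 1 and is clamped, leaving the weights untouched.
#'
#' @param p_parent,p_child Significance scores in `(0, 1]`.
#' @param penalty_scale Scale factor (default 1/10).
#' @return Penalty factor, always `>= 1`.
#' @examples
#' penalty(1e-2, 1e-2) # ~7.69: similar moderate scores, strong penalty
#' penalty(1e-80, 1e-80) # 1: both extreme, no extra penalty
#' @export
penalty <- function(p_parent, p_child, penalty_scale = 0.1) {
  if (any(c(p_child, p_parent) <= 0) || any(c(p_child, p_parent) > 1)) {
    stop("significance scores must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(penalty_scale > 0)
  lp <- log(clamp_for_log(p_parent)) + log(clamp_for_log(p_child))
  pmax(penalty_scale * log(XMIN) / lp, 1)
}

#' Double-weighted DAG-aware enrichment analysis
#'
#' Runs the weighted over-representation model over a leveled ontology:
#' every (term, gene) annotation carries a weight, initialized by
#' [initial_weights()], and the per-term significance score is the
#' hypergeometric upper-tail probability computed on floored weight sums
#' ([weighted_hyper_test()]). Terms are processed bottom-up, from the
#' deepest level to the root, so each term is scored after all of its
#' children; within a level, terms are visited in lexicographic id order.
#'
#' For the current term `t` (score `p(t) <= threshold`), its already-scored
#' children with scores within the threshold are compared to it through the
#' dynamic weight `w_d = log(p(child))/log(p(t))`:
#' \itemize{
#'   \item children with `w_d > 1` are locally more significant; the
#'     weights of their genes at `t` and at every ancestor of `t` are
#'     divided by `w_d` times the penalty factor, and the children leave
#'     the comparison permanently. `p(t)` is then recomputed and the
#'     comparison repeats (up to `max_refine_iters` passes).
#'   \item when no child outranks `t`, `t` is the local optimum: each
#'     remaining child's weights (at the child) are multiplied by
#'     `w_d <= 1` and divided by the penalty, its score is recomputed and
#'     overwritten, and `t`'s final score is recorded.
#' }
#' Weights only ever decrease after initialization. After the traversal a
#' single Benjamini-Hochberg adjustment is applied over all recorded
#' scores.
#'
#' @param graph A leveled (ideally pruned) `ontology_graph`.
#' @param annotations An expanded [annotation_table] on the same graph.
#' @param interest Character vector of interesting genes. Genes absent from
#'   the annotated background are dropped with a message.
#' @param threshold Raw-p significance cutoff steering the traversal
#'   (default 0.01). Adjustment happens once at the end and does not feed
#'   back into the traversal.
#' @param weight_step,min_init_weight Initial-weight decay and floor, see
#'   [initial_weights()].
#' @param penalty_scale Scale factor of the penalty formula.
#' @param min_genes,max_genes Optional bounds on a term's annotated gene
#'   count; terms outside the bounds are skipped entirely (no score, never
#'   compared as children). 0 disables a bound (the default); 10 and 2000
#'   are sensible for genome-scale annotation sets.
#' @param max_refine_iters Safety cap on the per-term refinement loop;
#'   hitting it keeps the last computed score and records a warning.
#' @param method `"weighted"` (the full model) or `"classic"`: plain
#'   term-for-term hypergeometric ORA (all weights 1, no cross-term
#'   updates).
#' @param decorrelate Debug switch: `FALSE` skips the dynamic-weight and
#'   penalty machinery while keeping the initial weights, so each term is
#'   scored independently.
#' @return An `enrich_result`: a tibble sorted by ascending p (ties broken
#'   by term id) with columns `term_id`, `name`, `level`, `p`, `p_adjust`,
#'   `n_interest` (r), `n_term` (m), `gene_ratio` ("r/n"), `bg_ratio`
#'   ("m/N") and `genes` (list column of the interesting genes annotated to
#'   the term). Attributes carry `N`, `n_interest_total`, the parameters
#'   and any refinement warnings.
#' @export
run_enrichment <- function(graph, annotations, interest,
                           threshold = 0.01,
                           weight_step = 0.1,
                           min_init_weight = 0.5,
                           penalty_scale = 0.1,
                           min_genes = 0,
                           max_genes = 0,
                           max_refine_iters = 50,
                           method = c("weighted", "classic"),
                           decorrelate = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(graph, "ontology_graph"),
            inherits(annotations, "annotation_table"),
            annotations$expanded_done,
            threshold > 0, threshold < 1,
            max_refine_iters >= 1)
  if (method == "classic") {
    weight_step <- 0
    min_init_weight <- 1
    decorrelate <- FALSE
  }

  ids <- graph$nodes$term_id
  lev <- stats::setNames(graph$nodes$level, ids)
  N <- length(annotations$universe)
  interest <- sort(unique(as.character(interest)))
  dropped <- setdiff(interest, annotations$universe)
  if (length(dropped) > 0L) {
    rlang::inform(paste0(length(dropped), " interesting gene(s) absent from",
                         " the annotated background were dropped"))
  }
  interest <- setdiff(interest, dropped)
  n <- length(interest)
  if (n == 0L) {
    stop("no interesting genes overlap the annotated background",
         call. = FALSE)
  }

  # per-term static structures (membership never changes during a run)
  genes <- lapply(ids, function(t) names(annotations$expanded[[t]]))
  names(genes) <- ids
  sel <- lapply(genes, function(g) g %in% interest)
  m_count <- vapply(genes, length, integer(1))
  r_count <- vapply(sel, sum, integer(1))

  w <- initial_weights(annotations, weight_step, min_init_weight)[ids]
  names(w) <- ids
  w[vapply(w, is.null, logical(1))] <- list(numeric(0))

  wscore <- function(t) {
    wt <- w[[t]]
    weighted_hyper_test(N, n, floor(sum(wt)), floor(sum(wt[sel[[t]]])))
  }

  anc <- ontology_ancestors(graph)
  score <- stats::setNames(rep(NA_real_, length(ids)), ids)
  refine_hit <- character(0)
  bounded <- min_genes > 0 || max_genes > 0
  order_bottom_up <- ids[order(-lev, ids, method = "radix")]

  for (t in order_bottom_up) {
    if (bounded &&
        ((min_genes > 0 && m_count[[t]] < min_genes) ||
         (max_genes > 0 && m_count[[t]] > max_genes))) {
      next # skipped terms get no score and never act as scored children
    }
    p_t <- wscore(t)
    if (!decorrelate) {
      score[t] <- p_t
      next
    }

    kids <- graph$children[[t]]
    kids <- kids[!is.na(score[kids]) & score[kids] <= threshold]
    iter <- 0L
    do_step5 <- FALSE
    while (p_t <= threshold && length(kids) > 0L) {
      w_d <- stats::setNames(
        vapply(kids, function(k) dynamic_weight(score[[k]], p_t),
               numeric(1)),
        kids
      )
      sig <- kids[w_d > 1] # ties (w_d == 1) stay with the parent
      if (length(sig) == 0L) {
        do_step5 <- TRUE
        break
      }
      iter <- iter + 1L
      if (iter > max_refine_iters) {
        refine_hit <- c(refine_hit, t)
        break
      }
      targets <- c(t, anc[[t]])
      for (k in sig) {
        f <- w_d[[k]] * penalty(p_t, score[[k]], penalty_scale)
        stopifnot(f >= 1) # weights may only shrink
        gk <- genes[[k]]
        for (a in targets) {
          idx <- match(gk, genes[[a]])
          idx <- idx[!is.na(idx)]
          if (length(idx)) w[[a]][idx] <- w[[a]][idx] / f
        }
      }
      kids <- setdiff(kids, sig)
      p_t <- wscore(t)
    }

    if (do_step5) {
      for (k in kids) {
        f <- dynamic_weight(score[[k]], p_t) /
          penalty(p_t, score[[k]], penalty_scale)
        stopifnot(f <= 1 + 1e-12) # remaining children never gain weight
        w[[k]] <- w[[k]] * pmin(f, 1)
        score[k] <- wscore(k) # final child score overwrites the earlier one
      }
      p_t <- wscore(t)
    }
    score[t] <- p_t
  }

  if (length(refine_hit) > 0L) {
    warning("refinement cap (", max_refine_iters, ") reached at ",
            length(refine_hit), " term(s); last computed scores kept",
            call. = FALSE)
  }

  recorded <- ids[!is.na(score)]
  p <- unname(score[recorded])
  res <- tibble::tibble(
    term_id = recorded,
    name = graph$nodes$name[match(recorded, ids)],
    level = unname(lev[recorded]),
    p = p,
    p_adjust = bh_adjust(p),
    n_interest = unname(r_count[recorded]),
    n_term = unname(m_count[recorded]),
    gene_ratio = paste0(r_count[recorded], "/", n),
    bg_ratio = paste0(m_count[recorded], "/", N),
    genes = lapply(recorded, function(t) sort(genes[[t]][sel[[t]]]))
  )
  res <- dplyr::arrange(res, .data$p, .data$term_id)
  structure(
    res,
    class = c("enrich_result", class(res)),
    N = N,
    n_interest_total = n,
    interest = interest,
    params = list(threshold = threshold, weight_step = weight_step,
                  min_init_weight = min_init_weight,
                  penalty_scale = penalty_scale, min_genes = min_genes,
                  max_genes = max_genes, max_refine_iters = max_refine_iters,
                  method = method, decorrelate = decorrelate),
    refine_warnings = refine_hit
  )
}

#' Classic term-for-term over-representation analysis
#'
#' Plain hypergeometric ORA on the same expanded annotations: every weight
#' is 1 and terms are scored independently. Provided for comparison with
#' the weighted model.
#'
#' @inheritParams run_enrichment
#' @param ... Passed on to [run_enrichment()] (e.g. `min_genes`).
#' @return An `enrich_result`, see [run_enrichment()].
#' @export
run_ora <- function(graph, annotations, interest, threshold = 0.01, ...) {
  run_enrichment(graph, annotations, interest, threshold = threshold,
                 method = "classic", ...)
}

#' Write an enrichment result as TSV
#'
#' Columns: term id, term name, level, p, adjusted p, gene ratio (`r/n`),
#' background ratio (`m/N`), and the interesting genes collapsed with
#' `/` — the layout of a standard enrichment result table.
#'
#' @param result An `enrich_result`.
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(result, path) {
  stopifnot(inherits(result, "enrich_result"))
  out <- tibble::tibble(
    DOID = result$term_id,
    DOTerm = result$name,
    level = result$level,
    p = result$p,
    p_adjust = result$p_adjust,
    geneRatio = result$gene_ratio,
    bgRatio = result$bg_ratio,
    genes = vapply(result$genes, paste, character(1), collapse = "/")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
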