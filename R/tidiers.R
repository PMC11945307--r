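#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment result
#'
#' @param x An `enrich_result`.
#' @param ... Unused.
#' @return A plain tibble of per-term statistics (the gene list column is
#'   dropped): `term_id`, `name`, `level`, `p`, `p_adjust`, `n_interest`,
#'   `n_term`, `gene_ratio`, `bg_ratio`.
#' @export
tidy.enrich_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("term_id", "name", "level", "p", "p_adjust",
                           "n_interest", "n_term", "gene_ratio", "bg_ratio")]
}

#' One-row summary of an enrichment result
#'
#' @param x An `enrich_result`.
#' @param ... Unused.
#' @return A one-row tibble: background size `N`, interest size `n`,
#'   number of scored terms, number significant at the traversal threshold
#'   (raw p) and after adjustment, and the method used.
#' @export
glance.enrich_result <- function(x, ...) {
  par <- attr(x, "params")
  tibble::tibble(
    N = attr(x, "N"),
    n_interest = attr(x, "n_interest_total"),
    n_terms = nrow(x),
    n_significant = sum(x$p <= par$threshold),
    n_significant_adjusted = sum(x$p_adjust <= par$threshold),
    threshold = par$threshold,
    method = par$method
  )
}

#' Bar plot of the top enriched terms
#'
#' @param object An `enrich_result`.
#' @param top_n Number of terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot: terms on the y axis ordered by significance,
#'   -log10(adjusted p) as bar length, filled by the interesting-gene
#'   count.
#' @export
autoplot.enrich_result <- function(object, top_n = 15, ...) {
  df <- utils::head(tidy(object), top_n)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adjust),
                                   y = .data$name,
                                   fill = .data$n_interest)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  fill = "genes") +
    ggplot2::theme_minimal()
}

#' Mean recovery per method and cutoff
#'
#' @param x A `recovery_report` from [run_recovery_study()].
#' @param ... Unused.
#' @return A tibble with `method`, `cutoff`, `mean_overlap`,
#'   `mean_fraction` averaged over repetitions.
#' @export
tidy.recovery_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$method, .data$cutoff),
    mean_overlap = mean(.data$overlap),
    mean_fraction = mean(.data$fraction),
    .groups = "drop"
  )
}

#' Recovery curves by method
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot of mean recovered fraction against the top-k cutoff,
#'   one line per method.
#' @export
autoplot.recovery_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff,
                                   y = .data$mean_fraction,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "top-k cutoff", y = "mean recovered fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Perturbation robustness curve
#'
#' @param object A `perturbation_report`.
#' @param ... Unused.
#' @return A ggplot of the mean overlap with the unperturbed top set
#'   against the perturbation level.
#' @export
autoplot.perturbation_report <- function(object, ...) {
  df <- summarise_perturbation(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level,
                                   y = .data$mean_overlap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("fraction ", attr(object, "kind"), "d"),
                  y = paste0("mean overlap with unperturbed top ",
                             attr(object, "top_k"))) +
    ggplot2::theme_minimal()
}
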