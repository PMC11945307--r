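# smallest positive normalized double; keeps log(p) finite after clamping
XMIN <- 2.2250738585072014e-308

clamp_p <- function(p) pmin(pmax(p, XMIN), 1)

# scores of exactly 1 are nudged below 1 only inside the weight formulas,
# where log(1) = 0 would divide by zero; reported p-values are never
# clamped at the top
clamp_for_log <- function(p) pmin(pmax(p, XMIN), 1 - 1e-16)

#' Hypergeometric upper-tail (over-representation) test
#'
#' Probability of drawing at least `r` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `m`
#' are annotated to the term:
#' p = 1 - sum_{k=0}^{r-1} C(m,k) C(N-m,n-k) / C(N,n).
#' Evaluated through the hypergeometric survival function, which works in
#' log space internally; an `r` of 0 gives exactly 1.
#'
#' @param N Background (universe) size: all genes annotated anywhere.
#' @param m Genes annotated to the term.
#' @param n Interesting genes present in the background.
#' @param r Interesting genes annotated to the term.
#' @return The upper-tail probability, in `[0, 1]`.
#' @examples
#' hyper_test(N = 10, m = 5, n = 4, r = 4) # 5 / choose(10, 4)
#' @export
hyper_test <- function(N, m, n, r) {
  if (any(m > N)) stop("invalid counts: m > N", call. = FALSE)
  if (any(n > N)) stop("invalid counts: n > N", call. = FALSE)
  if (any(r > pmin(m, n))) stop("invalid counts: r > min(m, n)",
                                call. = FALSE)
  if (any(c(N, m, n, r) < 0)) stop("invalid counts: negative", call. = FALSE)
  p <- stats::phyper(r - 1, m, N - m, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Weighted significance score
#'
#' The hypergeometric upper-tail test with the annotated count `m` and the
#' overlap count `r` replaced by the floor of the corresponding weight
#' sums: `m_w = floor(sum of weights of the term's genes)` and
#' `r_w = floor(sum of weights of its interesting genes)`. `N` and `n` are
#' unchanged. The result is clamped below at the smallest positive
#' normalized double so its logarithm stays finite.
#'
#' @param N,n Background and interest-set sizes (unweighted).
#' @param m_w,r_w Floored weight sums for the term's genes and its
#'   interesting genes.
#' @return Probability in `[xmin, 1]`; `r_w = 0` gives 1.
#' @export
weighted_hyper_test <- function(N, n, m_w, r_w) {
  if (any(r_w > m_w)) stop("invalid weighted counts: r_w > m_w",
                           call. = FALSE)
  clamp_p(hyper_test(N, m_w, n, pmin(r_w, n)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate control: with p-values sorted
#' ascending, `adjusted_i = min_{j >= i} p_j * M / j`, capped at 1 and
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
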