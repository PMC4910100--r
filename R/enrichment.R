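#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of seeing
#' at least `k` annotated genes in a draw of `n` from a universe of `N`
#' genes of which `K` carry the term.
#'
#' @param k annotated genes observed in the set.
#' @param K annotated genes in the universe.
#' @param n set size.
#' @param N universe size.
#' @return the upper-tail probability (exactly 1 when `k = 0`).
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(k > n) || any(n > N) ||
      any(K > N) || any(k > K))
    stop("require 0 <= k <= min(K, n), n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation test
#'
#' One hypergeometric upper-tail test per annotation term present in
#' the universe, with optional multiple-testing correction. The
#' defensible default universe for expression-derived sets is the
#' presence-filtered gene background, supplied by the caller.
#'
#' @param set character vector of genes of interest (subset of universe).
#' @param annotation data.frame with `gene_id` and `term`.
#' @param universe character vector of background gene ids.
#' @param alpha significance level reported against the adjusted p.
#' @param correction `"none"` (default, raw p), `"bh"` or `"bonferroni"`.
#' @return data.frame sorted by p: `term`, `k`, `K`, `n`, `N`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
enrich <- function(set, annotation, universe, alpha = 0.05,
                   correction = c("none", "bh", "bonferroni")) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set <- unique(set)
  if (!all(set %in% universe)) stop("set must be a subset of the universe")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term))
  N <- length(universe)
  n <- length(set)
  rows <- lapply(terms, function(t) {
    tg <- unique(ann$gene_id[ann$term == t])
    K <- length(tg)
    k <- sum(set %in% tg)
    data.frame(term = t, k = k, K = K, n = n, N = N,
               p = hypergeom_upper(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- switch(correction,
                           none = out$p,
                           bh = stats::p.adjust(out$p, "BH"),
                           bonferroni = stats::p.adjust(out$p, "bonferroni"))
  out <- out[order(out$p, out$term), , drop = FALSE]
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
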