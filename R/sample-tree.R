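#' Spearman correlation matrix over samples
#'
#' Pairwise Spearman rho (midrank ties) between sample expression
#' profiles, computed on `log2(RPKM + 1)` by default (raw RPKM by
#' flag). A constant sample profile has undefined rank correlation; its
#' entries are recorded as 0 with a warning.
#'
#' @param rpkm an rpkm-mode [ExpressionMatrix].
#' @param gene_subset optional gene ids to correlate over (>= 3 genes).
#' @param log2_transform correlate on log2(RPKM+1) (default) or raw.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
spearman_matrix <- function(rpkm, gene_subset = NULL, log2_transform = TRUE) {
  stopifnot(inherits(rpkm, "ExpressionMatrix"))
  v <- rpkm$values
  if (!is.null(gene_subset)) v <- v[gene_subset, , drop = FALSE]
  if (nrow(v) < 3L) stop("need at least 3 genes to correlate")
  if (log2_transform) v <- log2(v + 1)
  rho <- suppressWarnings(stats::cor(v, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant sample profile: undefined rho recorded as 0")
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Average-linkage (UPGMA) sample tree from correlations
#'
#' Clusters samples on the distance `1 - rho` with average linkage.
#' Samples are put in lexicographic label order before clustering so
#' that exact ties merge deterministically (smallest labels first) and
#' the result is invariant to the input sample order.
#'
#' @param corr correlation matrix from [spearman_matrix()].
#' @return an `hclust` merge tree.
#' @export
average_linkage_tree <- function(corr) {
  stopifnot(is.matrix(corr), isTRUE(all.equal(corr, t(corr))))
  ord <- order(colnames(corr))
  d <- stats::as.dist(1 - corr[ord, ord])
  stats::hclust(d, method = "average")
}
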