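#' Soft-thresholded co-expression adjacency
#'
#' Pearson correlation of `log2(RPKM + 1)` gene profiles raised to the
#' soft power `beta`: unsigned `|cor|^beta` (default) or signed
#' `((1 + cor) / 2)^beta`. Zero-variance genes cannot be correlated and
#' are excluded with a warning.
#'
#' @param expr an rpkm-mode [ExpressionMatrix], or a plain genes x
#'   samples numeric matrix taken as already transformed.
#' @param beta soft-thresholding power (default 6).
#' @param signed use the signed transform.
#' @param genes optional gene subset.
#' @return symmetric adjacency matrix in [0, 1] with unit diagonal.
#' @export
adjacency <- function(expr, beta = 6, signed = FALSE, genes = NULL) {
  v <- if (inherits(expr, "ExpressionMatrix")) log2(expr$values + 1) else expr
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (ncol(v) < 4L) stop("need at least 4 samples")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded from the network")
    v <- v[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(v))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivities `k_i = sum_u a_iu` (sums over `u != i, j`);
#' the diagonal is set to 1.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @return symmetric TOM matrix in [0, 1].
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  a <- adj
  diag(a) <- 0
  shared <- a %*% a                       # sum_u a_iu a_uj (u free of i, j via zero diag)
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage clustering of genes on the dissimilarity `1 - TOM`
#' with a static tree cut at `cut_height`; clusters below `min_size`
#' are left unassigned (label 0). Labels are renumbered by decreasing
#' module size (ties by smallest member gene id), and genes are put in
#' canonical id order before clustering, so the labelling is invariant
#' to the input gene order.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param cut_height static cut height on 1 - TOM (default 0.75).
#' @param min_size minimum module size (default 5).
#' @return named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, cut_height = 0.75, min_size = 5L) {
  ord <- order(rownames(tom))
  tom <- tom[ord, ord]
  if (nrow(tom) < 2L) {
    lab <- stats::setNames(if (min_size <= 1L) 1L else 0L, rownames(tom))
    return(lab)
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(h, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- stats::setNames(integer(length(raw)), names(raw))
  if (length(keep)) {
    firsts <- vapply(keep, function(k) min(names(raw)[raw == k]), "")
    keep <- keep[order(-sizes[keep], firsts)]
    for (i in seq_along(keep)) labels[raw == keep[i]] <- i
  }
  labels
}

#' Export network edges above a weight threshold
#'
#' Upper-triangle edge list `(gene_i, gene_j, weight)` with
#' `weight >= min_weight`, importable by common graph tools.
#'
#' @param tom TOM (or adjacency) matrix.
#' @param min_weight minimum retained edge weight.
#' @return data.frame with `gene_i`, `gene_j`, `weight`, `gene_i < gene_j`.
#' @export
export_edges <- function(tom, min_weight = 0.1) {
  ord <- order(rownames(tom))
  tom <- tom[ord, ord]
  ut <- upper.tri(tom)
  sel <- ut & tom >= min_weight
  idx <- which(sel, arr.ind = TRUE)   # column-major, matching tom[sel]
  out <- data.frame(gene_i = rownames(tom)[idx[, 1]],
                    gene_j = colnames(tom)[idx[, 2]],
                    weight = tom[sel], stringsAsFactors = FALSE)
  out <- out[order(out$gene_i, out$gene_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
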