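#' Compute RPKM from counts
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `rpkm[g,s] = 1e9 * count[g,s] / (length_bp[g] * total_mapped[s])`.
#' Gene length is the exon-union length of the gene's longest mRNA (see
#' [gene_lengths()]); the per-sample total is the declared number of
#' mapped reads.
#'
#' @param counts a counts-mode [ExpressionMatrix] with `gene_length`
#'   and `total_mapped` set (error otherwise).
#' @return an rpkm-mode [ExpressionMatrix] sharing the metadata.
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$mode != "counts") stop("input must be in counts mode")
  if (is.null(counts$gene_length)) stop("gene_length missing; RPKM undefined")
  if (is.null(counts$total_mapped)) stop("total_mapped missing; RPKM undefined")
  rpkm <- 1e9 * counts$values /
    outer(counts$gene_length, counts$total_mapped)
  em <- counts
  em$values <- rpkm
  em$mode <- "rpkm"
  em
}

#' Presence filter: genes expressed in enough stages
#'
#' Keeps the genes of one cultivar expressed (RPKM strictly above
#' `min_rpkm`; the default 0 makes positivity the definition of
#' "expressed") in at least `min_stages` of its stage samples. With
#' `scope = "all_samples"` the tally runs over every sample of the
#' panel instead of the cultivar's stages.
#'
#' @param rpkm an rpkm-mode [ExpressionMatrix].
#' @param cultivar cultivar whose stages are tallied.
#' @param min_stages minimum number of expressed stages (default 5).
#' @param min_rpkm expression threshold (exclusive).
#' @param scope `"cultivar"` (default) or `"all_samples"`.
#' @return character vector of retained gene ids.
#' @export
presence_filter <- function(rpkm, cultivar, min_stages = 5L, min_rpkm = 0,
                            scope = c("cultivar", "all_samples")) {
  stopifnot(inherits(rpkm, "ExpressionMatrix"))
  scope <- match.arg(scope)
  cols <- if (scope == "cultivar") cultivar_samples(rpkm, cultivar)
          else rpkm$samples$sample_id
  expressed <- rpkm$values[, cols, drop = FALSE] > min_rpkm
  rownames(rpkm$values)[rowSums(expressed) >= min_stages]
}

#' Per-sample mapping summary
#'
#' Tallies, for each sample, the number of genes with at least one
#' mapped read, the summed counts, and the declared mapped-read total.
#'
#' @param counts a counts-mode [ExpressionMatrix].
#' @return data.frame with one row per sample.
#' @export
mapping_summary <- function(counts) {
  stopifnot(inherits(counts, "ExpressionMatrix"), counts$mode == "counts")
  data.frame(sample_id = colnames(counts$values),
             cultivar = counts$samples$cultivar,
             stage = counts$samples$stage,
             n_genes_detected = colSums(counts$values > 0),
             total_counts = colSums(counts$values),
             total_mapped = if (is.null(counts$total_mapped)) NA_real_
                            else counts$total_mapped,
             row.names = NULL)
}

#' Stage-ordered expression series for one cultivar
#'
#' The clustering substrate: `log2(RPKM + 1)` over the cultivar's
#' stages in order, shifted so stage 1 is 0 for every gene.
#'
#' @param rpkm an rpkm-mode [ExpressionMatrix].
#' @param cultivar cultivar to extract.
#' @param genes optional gene subset (e.g. from [presence_filter()]).
#' @return numeric matrix, genes x stages.
#' @export
expression_series <- function(rpkm, cultivar, genes = NULL) {
  stopifnot(inherits(rpkm, "ExpressionMatrix"))
  cols <- cultivar_samples(rpkm, cultivar)
  v <- log2(rpkm$values[, cols, drop = FALSE] + 1)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  sweep(v, 1L, v[, 1L])
}
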