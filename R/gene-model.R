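#' Construct a strand-aware gene model
#'
#' A gene model is one mRNA context: its exon and CDS intervals in
#' genomic coordinates (1-based, inclusive, always ascending regardless
#' of strand), the strand, and the phase of the first CDS segment in
#' transcription order. All downstream coordinate work in the package
#' stays 1-based inclusive, matching GFF3 and VCF.
#'
#' @param gene_id,mrna_id feature identifiers (one model per mRNA; a
#'   multi-mRNA gene yields multiple models sharing `gene_id`).
#' @param chrom chromosome id.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds two-column matrices of `[start, end]` intervals,
#'   1-based inclusive; stored sorted by start.
#' @param phase integer 0..2: bases to skip at the 5' end of the first
#'   CDS segment (transcription order) to reach the first full codon.
#' @return object of class `GeneModel`. The `coding_frame` field is
#'   `FALSE` when the phase-adjusted CDS length is not a multiple of 3;
#'   such models are excluded from codon-level variant classes.
#' @export
GeneModel <- function(gene_id, mrna_id, chrom, strand, exons, cds, phase = 0L) {
  stopifnot(strand %in% c("+", "-"))
  exons <- normalize_intervals(exons, "exon")
  cds <- normalize_intervals(cds, "CDS")
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    if (!inside)
      stop("CDS interval [", cds[i, 1], ",", cds[i, 2],
           "] of ", mrna_id, " not contained in any exon")
  }
  phase <- as.integer(phase)
  stopifnot(phase %in% 0:2)
  cds_len <- sum(cds[, 2] - cds[, 1] + 1L)
  structure(list(gene_id = gene_id, mrna_id = mrna_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds, phase = phase,
                 coding_frame = ((cds_len - phase) %% 3L == 0L)),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %s:%d-%d [%s] %d exon(s), CDS %d bp%s\n",
              x$mrna_id, x$gene_id, x$chrom, gene_span(x)[1], gene_span(x)[2],
              x$strand, nrow(x$exons), sum(x$cds[, 2] - x$cds[, 1] + 1L),
              if (x$coding_frame) "" else " (non-coding frame)"))
  invisible(x)
}

# [start, end] genomic span of the model (exon extremes)
gene_span <- function(model) c(min(model$exons[, 1]), max(model$exons[, 2]))

normalize_intervals <- function(x, what) {
  x <- matrix(as.integer(x), ncol = 2)
  if (nrow(x) == 0L) stop(what, " interval list is empty")
  if (any(x[, 2] < x[, 1])) stop(what, " interval with end < start")
  x <- x[order(x[, 1]), , drop = FALSE]
  if (nrow(x) > 1L && any(x[-1L, 1] <= x[-nrow(x), 2]))
    stop("overlapping ", what, " intervals")
  colnames(x) <- c("start", "end")
  x
}

# exon-union length (bp) of the longest mRNA per gene; the package's
# gene length definition for RPKM
#' Exon-union gene lengths for RPKM
#'
#' Length of each gene is the total exon length of its longest mRNA
#' (the exon-model length in the RPKM denominator).
#'
#' @param models list of [GeneModel].
#' @return named numeric vector, one entry per gene id.
#' @export
gene_lengths <- function(models) {
  per_mrna <- vapply(models, function(m) sum(m$exons[, 2] - m$exons[, 1] + 1L), 0)
  genes <- vapply(models, function(m) m$gene_id, "")
  tapply(per_mrna, genes, max)[unique(genes)]
}
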