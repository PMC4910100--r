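#' Read a genome FASTA
#'
#' Loads every record, uppercases the sequence, and enforces the
#' pipeline's genome alphabet {A, C, G, T, N}. Lowercase input is
#' accepted and normalized; any other character is a format error, as
#' are duplicate record ids and empty sequences. Record ids are taken
#' up to the first whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase chromosome sequences
#'   (the package's in-memory genome representation).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) stop("empty FASTA sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-{A,C,G,T,N} character in record ", ids[bad][1])
  seqs
}

#' Write a genome FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS rows linked by Parent attributes into one
#' [GeneModel] per mRNA. Coordinates are kept 1-based inclusive as in
#' GFF3 and stored in ascending genomic order regardless of strand. A
#' model whose CDS overhangs its exons is rejected with a warning; a
#' model whose phase-adjusted CDS length is not a multiple of 3 is kept
#' but flagged (`coding_frame = FALSE`) and excluded from codon-level
#' variant classes.
#'
#' @param path GFF3 file.
#' @return list of [GeneModel].
#' @export
read_gff3 <- function(path) {
  df <- as.data.frame(rtracklayer::readGFF(path))
  if (!all(c("type", "start", "end", "strand") %in% names(df)))
    stop("not a parseable GFF3: ", path)
  df$ID <- as.character(df$ID)
  parent1 <- vapply(df$Parent, function(p) {
    p <- as.character(unlist(p))
    if (length(p)) p[1] else NA_character_
  }, "")
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  mrna_parent <- parent1[df$type == "mRNA"]
  models <- list()
  for (i in seq_len(nrow(mrna))) {
    mid <- mrna$ID[i]
    kids <- !is.na(parent1) & parent1 == mid
    ex <- df[kids & df$type == "exon", c("start", "end"), drop = FALSE]
    cd <- df[kids & df$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L || nrow(cd) == 0L) next
    # phase of the first CDS segment in transcription order
    first_cds <- if (mrna$strand[i] == "+") which.min(cd$start) else which.max(cd$start)
    ph <- suppressWarnings(as.integer(as.character(cd$phase[first_cds])))
    if (is.na(ph)) ph <- 0L
    m <- tryCatch(
      GeneModel(gene_id = mrna_parent[i], mrna_id = mid,
                chrom = as.character(mrna$seqid[i]), strand = mrna$strand[i],
                exons = as.matrix(ex), cds = as.matrix(cd[, c("start", "end")]),
                phase = ph),
      error = function(e) {
        warning("model ", mid, " rejected: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  models
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS rows with Parent links and correct
#' per-segment CDS phases; used to serialize synthetic fixtures.
#'
#' @param models list of [GeneModel].
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  rows <- character(0)
  genes <- split(models, vapply(models, function(m) m$gene_id, ""))
  gff_row <- function(chrom, type, start, end, strand, phase, attrs)
    paste(chrom, "pomecourse", type, start, end, ".", strand, phase, attrs,
          sep = "\t")
  for (gid in names(genes)) {
    ms <- genes[[gid]]
    span <- range(unlist(lapply(ms, function(m) gene_span(m))))
    rows <- c(rows, gff_row(ms[[1]]$chrom, "gene", span[1], span[2],
                            ms[[1]]$strand, ".", paste0("ID=", gid)))
    for (m in ms) {
      sp <- gene_span(m)
      rows <- c(rows, gff_row(m$chrom, "mRNA", sp[1], sp[2], m$strand, ".",
                              paste0("ID=", m$mrna_id, ";Parent=", gid)))
      for (i in seq_len(nrow(m$exons)))
        rows <- c(rows, gff_row(m$chrom, "exon", m$exons[i, 1], m$exons[i, 2],
                                m$strand, ".", paste0("Parent=", m$mrna_id)))
      # CDS phases accumulate along transcription order
      ord <- if (m$strand == "+") seq_len(nrow(m$cds)) else rev(seq_len(nrow(m$cds)))
      before <- m$phase
      ph <- integer(nrow(m$cds))
      for (j in ord) {
        ph[j] <- before %% 3L
        seg <- m$cds[j, 2] - m$cds[j, 1] + 1L
        before <- (3L - ((seg - ph[j]) %% 3L)) %% 3L
      }
      for (j in seq_len(nrow(m$cds)))
        rows <- c(rows, gff_row(m$chrom, "CDS", m$cds[j, 1], m$cds[j, 2],
                                m$strand, ph[j], paste0("Parent=", m$mrna_id)))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read single-nucleotide variants from a VCF
#'
#' Keeps only single-base substitutions; multi-allelic rows are split
#' into one variant per ALT allele; indels and symbolic alleles are
#' skipped and tallied in the `n_skipped` attribute. When a genome is
#' supplied, every kept REF allele is checked against it.
#'
#' @param path VCF 4.x file.
#' @param sample_id cultivar label attached to every variant.
#' @param genome optional genome from [read_fasta()] for REF validation.
#' @return data.frame with columns chrom, pos, ref, alt, sample_id and
#'   attribute `n_skipped` (count of dropped row x allele records).
#' @export
read_vcf <- function(path, sample_id, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)    # single-row VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    if (nchar(ref) != 1L || !ref %in% c("A", "C", "G", "T", "N")) {
      n_skipped <- n_skipped + length(alts)
      next
    }
    snv <- nchar(alts) == 1L & alts %in% c("A", "C", "G", "T") & alts != ref
    n_skipped <- n_skipped + sum(!snv)
    if (!any(snv)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = ref, alt = alts[snv], sample_id = sample_id,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), sample_id = character(0))
  if (!is.null(genome)) {
    gb <- genome_base(genome, res$chrom, res$pos)
    bad <- gb != res$ref
    if (any(bad))
      stop("VCF REF mismatch against genome at ", res$chrom[bad][1], ":",
           res$pos[bad][1], " (REF ", res$ref[bad][1], ", genome ", gb[bad][1], ")")
  }
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Write variants as a minimal VCF
#' @param variants data.frame as returned by [read_vcf()].
#' @param path output file.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", v$chrom, v$pos, v$ref, v$alt)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a gene x sample count matrix
#'
#' TSV with the gene id in the first column and one column per sample;
#' every matrix sample must appear in the sample sheet. Cells must be
#' non-negative integers ('.' or missing cells are rejected).
#'
#' @param path TSV file.
#' @param sample_sheet data.frame accepted by [validate_sample_sheet()].
#' @param gene_length,total_mapped optional metadata passed through to
#'   [ExpressionMatrix()].
#' @return a counts-mode [ExpressionMatrix].
#' @export
read_count_matrix <- function(path, sample_sheet, gene_length = NULL,
                              total_mapped = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("count matrix has non-numeric or missing cells")
  if (any(m < 0)) stop("negative count in matrix")
  if (any(m != floor(m))) stop("non-integer count in matrix")
  rownames(m) <- genes
  sheet <- validate_sample_sheet(sample_sheet)
  extra <- setdiff(colnames(m), sheet$sample_id)
  if (length(extra))
    stop("samples in matrix but not in sheet: ", paste(extra, collapse = ", "))
  ExpressionMatrix(m, sheet[sheet$sample_id %in% colnames(m), , drop = FALSE],
                   mode = "counts", gene_length = gene_length,
                   total_mapped = total_mapped)
}

#' Write an expression matrix as TSV
#' @param em an [ExpressionMatrix].
#' @param path output file.
#' @export
write_count_matrix <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a merge tree as Newick
#'
#' Converts an `hclust` merge tree to Newick text under the ultrametric
#' convention: a node merged at height h sits at depth h/2, so two
#' leaves merged at height 0.2 are written `(A:0.1,B:0.1);`. Labels
#' containing characters outside `[A-Za-z0-9_.|-]` are single-quoted.
#'
#' @param tree an `hclust` object, or a length-1 character label for
#'   the degenerate single-leaf tree.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  quote_label <- function(l) {
    if (grepl("[^A-Za-z0-9_.|-]", l))
      paste0("'", gsub("'", "''", l), "'") else l
  }
  if (is.character(tree) && length(tree) == 1L) {
    txt <- paste0(quote_label(tree), ";")
  } else {
    stopifnot(inherits(tree, "hclust"))
    node_txt <- function(idx) {
      # idx < 0: leaf -idx; idx > 0: internal node from merge row idx
      if (idx < 0) list(txt = quote_label(tree$labels[-idx]), h = 0)
      else {
        l <- node_txt(tree$merge[idx, 1]); r <- node_txt(tree$merge[idx, 2])
        h <- tree$height[idx] / 2
        list(txt = sprintf("(%s:%s,%s:%s)", l$txt, format(h - l$h, digits = 10),
                           r$txt, format(h - r$h, digits = 10)), h = h)
      }
    }
    txt <- paste0(node_txt(nrow(tree$merge))$txt, ";")
  }
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

# vectorized single-base lookup with bounds checking
genome_base <- function(genome, chrom, pos) {
  if (!length(pos)) return(character(0))
  bad <- !chrom %in% names(genome)
  if (any(bad)) stop("unknown chromosome: ", chrom[bad][1])
  len <- nchar(genome)[match(chrom, names(genome))]
  if (any(pos < 1L | pos > len))
    stop("position outside chromosome: ", chrom[pos < 1L | pos > len][1])
  substr_vec(genome[chrom], pos, pos)
}

substr_vec <- function(strings, start, stop) {
  vapply(seq_along(strings),
         function(i) substr(strings[i], start[i], stop[i]), "")
}
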