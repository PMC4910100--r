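#' Generate a random genome
#'
#' Uniform A/C/G/T sequence with an optional fraction of positions
#' masked to 'N' (assembly gaps), reproducible for a fixed seed.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp (>= 10000).
#' @param n_fraction fraction of positions set to 'N' (0 <= f < 0.05).
#' @param seed integer RNG seed.
#' @return named character vector of sequences (`chr1`, `chr2`, ...).
#' @export
generate_genome <- function(n_chrom = 2L, chrom_length = 50000L,
                            n_fraction = 0, seed = 1L) {
  stopifnot(chrom_length >= 10000L, n_fraction >= 0, n_fraction < 0.05)
  set.seed(seed)
  genome <- vapply(seq_len(n_chrom), function(i) {
    chars <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
    n_n <- round(n_fraction * chrom_length)
    if (n_n > 0) chars[sample.int(chrom_length, n_n)] <- "N"
    paste(chars, collapse = "")
  }, "")
  names(genome) <- paste0("chr", seq_len(n_chrom))
  genome
}

#' Plant multi-exon gene models into a genome
#'
#' Places non-overlapping genes along the chromosomes, roughly half on
#' the minus strand, separated by at least `intergenic_gap` bp so that
#' the 2 kb upstream/downstream flanks of neighbouring genes never
#' overlap. Each gene's coding sequence is written into the genome on
#' its coding strand: it starts with ATG, ends with a stop codon,
#' contains no internal stop, and its length is a multiple of 3. Exon
#' boundaries may fall inside codons (splice-spanning codons), which is
#' what real multi-exon genes do.
#'
#' @param genome genome from [generate_genome()] (returned modified).
#' @param n_genes number of genes to place.
#' @param exons_per_gene integer vector sampled for the exon count.
#' @param intergenic_gap minimum gap between consecutive gene bodies
#'   (>= 4001 keeps all 2 kb flanks disjoint).
#' @param codon_range min/max number of codons per CDS.
#' @param intron_range min/max intron length (bp).
#' @param seed integer RNG seed.
#' @return list with `models` (list of [GeneModel]) and `genome` (the
#'   genome carrying the planted coding sequences).
#' @export
generate_gene_models <- function(genome, n_genes = 40L, exons_per_gene = 1:4,
                                 intergenic_gap = 4001L,
                                 codon_range = c(60L, 200L),
                                 intron_range = c(60L, 300L), seed = 1L) {
  stopifnot(intergenic_gap >= 4001L)
  set.seed(seed + 1000L)
  margin <- 2101L  # room for a full 2 kb flank inside the chromosome
  chrom_chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  models <- vector("list", n_genes)
  ci <- 1L
  cursor <- margin
  for (g in seq_len(n_genes)) {
    n_ex <- if (length(exons_per_gene) == 1L) exons_per_gene else
      sample(exons_per_gene, 1L)
    n_cod <- sample(codon_range[1]:codon_range[2], 1L)
    cds_len <- 3L * n_cod
    segs <- split_lengths(cds_len, n_ex, min_len = 3L)
    introns <- if (n_ex > 1L)
      sample(intron_range[1]:intron_range[2], n_ex - 1L, replace = TRUE) else integer(0)
    glen <- cds_len + sum(introns)
    while (cursor + glen + margin > nchar(genome[ci])) {
      ci <- ci + 1L
      if (ci > length(genome))
        stop("genome too short for ", n_genes, " genes with gap ", intergenic_gap)
      cursor <- margin
    }
    starts <- cursor + c(0L, cumsum(segs[-n_ex] + introns))
    exons <- cbind(start = starts, end = starts + segs - 1L)
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    coding <- paste0("ATG",
                     paste(sample(NONSTOP_CODONS, n_cod - 2L, replace = TRUE),
                           collapse = ""),
                     sample(STOP_CODONS, 1L))
    # write the coding sequence across exon positions, strand-aware
    exon_pos <- unlist(lapply(seq_len(n_ex), function(i) exons[i, 1]:exons[i, 2]))
    placed <- if (strand == "+") coding else revcomp(coding)
    chrom_chars[[ci]][exon_pos] <- strsplit(placed, "", fixed = TRUE)[[1]]
    gid <- sprintf("g%03d", g)
    models[[g]] <- GeneModel(gene_id = gid, mrna_id = paste0(gid, ".1"),
                             chrom = names(genome)[ci], strand = strand,
                             exons = exons, cds = exons, phase = 0L)
    cursor <- max(exons[, 2]) + intergenic_gap
  }
  genome_out <- vapply(chrom_chars, paste, "", collapse = "")
  names(genome_out) <- names(genome)
  list(models = models, genome = genome_out)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    paste0), c("A", "C", "G", "T"), paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# random composition of `total` into `k` parts, each >= min_len
split_lengths <- function(total, k, min_len = 3L) {
  if (k == 1L) return(total)
  repeat {
    cuts <- sort(sample.int(total - 1L, k - 1L))
    segs <- diff(c(0L, cuts, total))
    if (all(segs >= min_len)) return(segs)
  }
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# codon -> amino acid under the standard nuclear code ("*" = stop)
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}
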