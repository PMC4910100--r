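# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately avoid the package's
# classification/index code paths.

# small planted fixture reused across SNP tests (built once per run)
snp_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    genome0 <- generate_genome(2, 100000, n_fraction = 0.002, seed = 11)
    gm <- generate_gene_models(genome0, n_genes = 40, seed = 11)
    planted <- plant_variants(gm$genome, gm$models, default_variant_spec(45),
                              seed = 11,
                              sample_ids = c("NG", "SK", "HS", "YL", "KX"))
    cache <<- list(genome = gm$genome, models = gm$models,
                   variants = planted$variants, truth = planted$truth,
                   unplantable = planted$unplantable)
    cache
  }
})

# stage-ordered sample columns of one cultivar
cultivar_stage_cols <- function(em, cultivar) {
  sub <- em$samples[em$samples$cultivar == cultivar, ]
  sub$sample_id[order(sub$stage)]
}

tiny_em <- function(values, stages = seq_len(ncol(values)), cultivar = "CV",
                    lengths = NULL, totals = NULL, mode = "counts") {
  genes <- rownames(values)
  sheet <- data.frame(sample_id = colnames(values), cultivar = cultivar,
                      stage = stages,
                      maturity_group = "post_ripening")
  ExpressionMatrix(values, sheet, mode = mode, gene_length = lengths,
                   total_mapped = totals)
}

# ---- independent SNP effect oracle ---------------------------------
# Rebuilds the whole mutant transcript and translates ref and alt
# proteins with Biostrings; region membership by plain interval loops.

oracle_splice <- function(m, pos) {
  if (nrow(m$exons) < 2) return(FALSE)
  for (i in seq_len(nrow(m$exons) - 1)) {
    s <- m$exons[i, 2] + 1; e <- m$exons[i + 1, 1] - 1
    if (pos >= s && pos <= e && (pos - s < 2 || e - pos < 2)) return(TRUE)
  }
  FALSE
}

oracle_spliced_tx <- function(m, genome) {
  parts <- character(0)
  for (i in seq_len(nrow(m$cds)))
    parts <- c(parts, substring(genome[m$chrom], m$cds[i, 1], m$cds[i, 2]))
  tx <- paste(parts, collapse = "")
  if (m$strand == "-")
    tx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  tx
}

oracle_cds_offset <- function(m, pos) {
  asc <- unlist(lapply(seq_len(nrow(m$cds)), function(i) m$cds[i, 1]:m$cds[i, 2]))
  if (m$strand == "-") asc <- rev(asc)
  which(asc == pos)
}

oracle_translate <- function(tx) {
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(tx), if.fuzzy.codon = "X")))
}

# class of one variant within one model context; NA when outside
oracle_model_class <- function(v, m, genome) {
  lo <- min(m$exons[, 1]); hi <- max(m$exons[, 2])
  in_span <- v$pos >= lo && v$pos <= hi
  in_cds <- any(v$pos >= m$cds[, 1] & v$pos <= m$cds[, 2])
  in_exon <- any(v$pos >= m$exons[, 1] & v$pos <= m$exons[, 2])
  if (in_cds) {
    genome2 <- genome
    chrom <- genome2[v$chrom]
    substring(chrom, v$pos, v$pos) <- v$alt
    genome2[v$chrom] <- chrom
    tx_ref <- oracle_spliced_tx(m, genome)
    tx_alt <- oracle_spliced_tx(m, genome2)
    off <- oracle_cds_offset(m, v$pos)
    k <- (off - 1) %/% 3 + 1
    n_cod <- nchar(tx_ref) %/% 3
    first_alt <- substring(tx_alt, 1, 3)
    last_alt <- substring(tx_alt, 3 * n_cod - 2, 3 * n_cod)
    alt_codon <- substring(tx_alt, 3 * k - 2, 3 * k)
    if (k == 1) return(if (first_alt == "ATG") 11L else 5L)
    if (k == n_cod)
      return(if (last_alt %in% c("TAA", "TAG", "TGA")) 10L else 6L)
    if (alt_codon %in% c("TAA", "TAG", "TGA")) return(8L)
    if (oracle_translate(tx_ref) == oracle_translate(tx_alt)) return(7L)
    return(9L)
  }
  if (in_exon) return(NA_integer_)       # UTR: no class in the taxonomy
  if (in_span) return(if (oracle_splice(m, v$pos)) 3L else 4L)
  # strand-aware flanks
  up <- if (m$strand == "+") c(lo - 2000, lo - 1) else c(hi + 1, hi + 2000)
  dn <- if (m$strand == "+") c(hi + 1, hi + 2000) else c(lo - 2000, lo - 1)
  if (v$pos >= up[1] && v$pos <= up[2]) return(1L)
  if (v$pos >= dn[1] && v$pos <= dn[2]) return(2L)
  NA_integer_
}

# primary class over all models (precedence: N > codon > splice >
# intron > upstream > downstream > intergenic)
oracle_classify <- function(v, models, genome) {
  if (substring(genome[v$chrom], v$pos, v$pos) == "N") return(12L)
  classes <- integer(0)
  for (m in models) {
    if (m$chrom != v$chrom) next
    cl <- oracle_model_class(v, m, genome)
    if (!is.na(cl)) classes <- c(classes, cl)
  }
  if (!length(classes)) return(0L)
  rank <- c(`12` = 0, `5` = 1, `6` = 1, `7` = 1, `8` = 1, `9` = 1,
            `10` = 1, `11` = 1, `3` = 3, `4` = 4, `1` = 5, `2` = 6, `0` = 7)
  classes[order(rank[as.character(classes)])][1]
}

# mirror a whole fixture through reverse complement
mirror_fixture <- function(genome, models, variants) {
  L <- nchar(genome)
  genome_rc <- vapply(genome, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  names(genome_rc) <- names(genome)
  flip_iv <- function(iv, len) {
    out <- cbind(len - iv[, 2] + 1L, len - iv[, 1] + 1L)
    out[order(out[, 1]), , drop = FALSE]
  }
  models_rc <- lapply(models, function(m) {
    len <- L[[m$chrom]]
    GeneModel(m$gene_id, m$mrna_id, m$chrom,
              if (m$strand == "+") "-" else "+",
              flip_iv(m$exons, len), flip_iv(m$cds, len), m$phase)
  })
  v <- variants
  v$pos <- L[v$chrom] - v$pos + 1L
  v$ref <- chartr("ACGTN", "TGCAN", v$ref)
  v$alt <- chartr("ACGTN", "TGCAN", v$alt)
  list(genome = genome_rc, models = models_rc, variants = v)
}

# ---- enumeration oracles -------------------------------------------

# hypergeometric upper tail by summing the exact pmf with choose()
hyper_upper_sum <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# TOM by literal double loop over shared neighbours
tom_brute <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}
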