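#' Plant variants of known effect class
#'
#' Chooses genomic sites whose context guarantees a requested effect
#' class and emits one substitution per site, verified at planting time
#' by direct sequence inspection (codon-level classes are derived by
#' substituting into the spliced, strand-corrected CDS and consulting
#' the standard genetic code). REF always equals the genome base; all
#' planted positions are distinct. Classes with no eligible site are
#' reported: class 11 (silent initiation-codon change) is unreachable
#' for ATG starts under the standard code and is listed in
#' `unplantable` rather than raising an error; any other exhausted
#' class raises an error naming it.
#'
#' @param genome genome carrying the models' coding sequences.
#' @param models list of [GeneModel].
#' @param spec named vector of requested counts; names are effect-class
#'   codes `"1"`..`"12"` or `"intergenic"` (alias `"0"`).
#' @param seed integer RNG seed.
#' @param sample_ids cultivar labels cycled over the planted variants.
#' @return list with `variants` (data.frame chrom/pos/ref/alt/sample_id),
#'   `truth` (variants plus `intended_class`, integer 0 = intergenic,
#'   and `gene_id`), and `unplantable` (character vector of class codes).
#' @export
plant_variants <- function(genome, models, spec, seed = 1L,
                           sample_ids = "S1") {
  set.seed(seed + 2000L)
  names(spec)[names(spec) == "intergenic"] <- "0"
  stopifnot(all(names(spec) %in% as.character(0:12)))
  bases <- c("A", "C", "G", "T")

  # genome-wide coverage masks per chromosome
  chrom_len <- nchar(genome)
  in_gene <- lapply(chrom_len, function(L) logical(L))
  n_up <- lapply(chrom_len, function(L) integer(L))
  n_down <- lapply(chrom_len, function(L) integer(L))
  geom <- lapply(models, model_geometry, chrom_len = chrom_len)
  for (gm in geom) {
    ch <- gm$chrom
    in_gene[[ch]][gm$span[1]:gm$span[2]] <- TRUE
    if (length(gm$upstream)) n_up[[ch]][gm$upstream] <- n_up[[ch]][gm$upstream] + 1L
    if (length(gm$downstream)) n_down[[ch]][gm$downstream] <- n_down[[ch]][gm$downstream] + 1L
  }

  base_at <- function(ch, pos) substring(genome[ch], pos, pos)
  rand_alt <- function(ref) vapply(ref, function(r)
    sample(setdiff(bases, r), 1L), "")

  pool_positions <- function(ch, pos, gene_id) {
    if (!length(pos)) return(NULL)
    ref <- base_at(ch, pos)
    keep <- ref != "N"
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, pos = pos[keep], ref = ref[keep],
               alt = rand_alt(ref[keep]), gene_id = gene_id,
               stringsAsFactors = FALSE)
  }

  pools <- list()
  add_pool <- function(cls, df) {
    cls <- as.character(cls)
    pools[[cls]] <<- rbind(pools[[cls]], df)
  }

  for (gm in geom) {
    up_pure <- gm$upstream[!in_gene[[gm$chrom]][gm$upstream] &
                           n_up[[gm$chrom]][gm$upstream] == 1L]
    dn_pure <- gm$downstream[!in_gene[[gm$chrom]][gm$downstream] &
                             n_up[[gm$chrom]][gm$downstream] == 0L &
                             n_down[[gm$chrom]][gm$downstream] == 1L]
    add_pool(1L, pool_positions(gm$chrom, up_pure, gm$gene_id))
    add_pool(2L, pool_positions(gm$chrom, dn_pure, gm$gene_id))
    add_pool(3L, pool_positions(gm$chrom, gm$splice, gm$gene_id))
    add_pool(4L, pool_positions(gm$chrom, gm$intron_interior, gm$gene_id))
  }

  # codon-level candidates, per model
  for (m in models) {
    cs <- coding_context(m, genome)
    if (is.null(cs)) next
    cand <- enumerate_codon_changes(cs, m)
    for (cls in unique(cand$class))
      add_pool(cls, cand[cand$class == cls,
                         c("chrom", "pos", "ref", "alt", "gene_id")])
  }

  # class 12: genome N positions; class 0: pure intergenic
  for (ch in names(genome)) {
    npos <- which(strsplit(genome[ch], "", fixed = TRUE)[[1]] == "N")
    if (length(npos))
      add_pool(12L, data.frame(chrom = ch, pos = npos, ref = "N",
                               alt = sample(bases, length(npos), replace = TRUE),
                               gene_id = NA_character_, stringsAsFactors = FALSE))
    free <- which(!in_gene[[ch]] & n_up[[ch]] == 0L & n_down[[ch]] == 0L)
    add_pool(0L, pool_positions(ch, free, NA_character_))
  }

  used <- character(0)
  out <- list()
  unplantable <- character(0)
  # scarcest class first: classes sharing positions (e.g. the stop-codon
  # classes 6 and 10) then never starve each other unnecessarily
  pool_size <- vapply(names(spec), function(cl) {
    p <- pools[[cl]]
    if (is.null(p)) 0L else length(unique(paste(p$chrom, p$pos)))
  }, 0L)
  for (cls in names(spec)[order(pool_size)]) {
    n_req <- spec[[cls]]
    if (n_req <= 0) next
    pool <- pools[[cls]]
    if (!is.null(pool) && nrow(pool)) {
      pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
      key <- paste(pool$chrom, pool$pos)
      pool <- pool[!duplicated(key) & !(key %in% used), , drop = FALSE]
    }
    if (is.null(pool) || nrow(pool) < n_req) {
      if (cls == "11") { unplantable <- c(unplantable, cls); next }
      stop("insufficient eligible sites for class ", cls, ": need ", n_req,
           ", have ", if (is.null(pool)) 0L else nrow(pool))
    }
    take <- pool[seq_len(n_req), , drop = FALSE]
    used <- c(used, paste(take$chrom, take$pos))
    take$intended_class <- as.integer(cls)
    out[[cls]] <- take
  }
  truth <- do.call(rbind, out)
  rownames(truth) <- NULL
  truth$sample_id <- rep_len(sample_ids, nrow(truth))
  variants <- truth[, c("chrom", "pos", "ref", "alt", "sample_id")]
  truth <- truth[, c("chrom", "pos", "ref", "alt", "sample_id",
                     "intended_class", "gene_id")]
  list(variants = variants, truth = truth, unplantable = unplantable)
}

# strand-aware region geometry of one model (positions, 1-based)
model_geometry <- function(m, chrom_len) {
  span <- gene_span(m)
  L <- chrom_len[[m$chrom]]
  up <- if (m$strand == "+") (span[1] - 2000L):(span[1] - 1L) else
    (span[2] + 1L):(span[2] + 2000L)
  dn <- if (m$strand == "+") (span[2] + 1L):(span[2] + 2000L) else
    (span[1] - 2000L):(span[1] - 1L)
  up <- up[up >= 1L & up <= L]
  dn <- dn[dn >= 1L & dn <= L]
  splice <- integer(0)
  interior <- integer(0)
  if (nrow(m$exons) > 1L) {
    for (i in seq_len(nrow(m$exons) - 1L)) {
      s <- m$exons[i, 2] + 1L
      e <- m$exons[i + 1L, 1] - 1L
      len <- e - s + 1L
      if (len <= 0L) next
      splice <- c(splice, unique(c(s, min(s + 1L, e), max(e - 1L, s), e)))
      if (len >= 5L) interior <- c(interior, (s + 2L):(e - 2L))
    }
    splice <- setdiff(splice, interior)
  }
  list(chrom = m$chrom, gene_id = m$gene_id, span = span, upstream = up,
       downstream = dn, splice = splice, intron_interior = interior)
}

# spliced CDS in transcription order + genomic position map
coding_context <- function(m, genome) {
  asc <- unlist(lapply(seq_len(nrow(m$cds)),
                       function(i) m$cds[i, 1]:m$cds[i, 2]))
  seq_asc <- paste(substring(genome[m$chrom], asc, asc), collapse = "")
  if (m$strand == "+") {
    coding <- seq_asc
    cds_pos <- asc
  } else {
    coding <- revcomp(seq_asc)
    cds_pos <- rev(asc)
  }
  if (m$phase > 0L) {
    coding <- substring(coding, m$phase + 1L)
    cds_pos <- cds_pos[-seq_len(m$phase)]
  }
  if (!m$coding_frame || nchar(coding) < 6L) return(NULL)
  list(coding = coding, cds_pos = cds_pos)
}

# every single-base change of every codon, with its effect class
enumerate_codon_changes <- function(cs, m) {
  n_cod <- nchar(cs$coding) %/% 3L
  codons <- substring(cs$coding, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  if (codons[1] != "ATG" || !(codons[n_cod] %in% STOP_CODONS)) return(NULL)
  bases <- c("A", "C", "G", "T")
  idx <- expand.grid(i = seq_len(n_cod), j = 1:3, a = bases,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ref_codon <- codons[idx$i]
  ref_b <- substring(ref_codon, idx$j, idx$j)
  keep <- ref_b != idx$a & ref_b != "N"
  idx <- idx[keep, ]; ref_codon <- ref_codon[keep]; ref_b <- ref_b[keep]
  alt_codon <- ref_codon
  substring(alt_codon, idx$j, idx$j) <- idx$a
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  cls <- integer(nrow(idx))
  first <- idx$i == 1L
  last <- idx$i == n_cod
  stop_alt <- alt_codon %in% STOP_CODONS
  cls[first] <- ifelse(alt_codon[first] == "ATG", 11L, 5L)
  cls[last] <- ifelse(stop_alt[last], 10L, 6L)
  internal <- !first & !last
  cls[internal & stop_alt] <- 8L
  cls[internal & !stop_alt & ref_aa == alt_aa] <- 7L
  cls[internal & !stop_alt & ref_aa != alt_aa] <- 9L
  # third-position restriction for planted synonymous changes
  drop <- cls == 7L & idx$j != 3L
  gpos <- cs$cds_pos[3L * (idx$i - 1L) + idx$j]
  galt <- if (m$strand == "+") idx$a else comp_base(idx$a)
  gref <- if (m$strand == "+") ref_b else comp_base(ref_b)
  data.frame(chrom = m$chrom, pos = gpos, ref = gref, alt = galt,
             gene_id = m$gene_id, class = cls,
             stringsAsFactors = FALSE)[!drop, ]
}

#' Default planting request covering every reachable effect class
#'
#' At least 500 variants spanning classes 1-10 and 12 plus intergenic
#' sites; class 11 is requested so the generator reports it unplantable
#' (no silent change of an ATG initiator exists under the standard
#' code).
#'
#' @param per_class variants per class.
#' @return named numeric vector usable as `spec` in [plant_variants()].
#' @export
default_variant_spec <- function(per_class = 45L) {
  spec <- stats::setNames(rep(per_class, 13L), c(as.character(1:12), "intergenic"))
  spec[["12"]] <- min(per_class, 30L)  # limited by planted N sites
  spec
}
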