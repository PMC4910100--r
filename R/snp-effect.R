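#' Effect-class codes
#'
#' The twelve-category SNP effectiveness taxonomy plus the intergenic
#' sentinel 0: 1 upstream within 2 kb of the transcription start
#' (strand-aware); 2 downstream within 2 kb; 3 splice boundary (the two
#' intronic bases at each exon-intron junction); 4 intron interior;
#' 5 initiation-codon change that abolishes the initiator; 6
#' termination-codon change that abolishes the stop; 7 exonic
#' synonymous; 8 exonic premature stop; 9 exonic nonsynonymous; 10
#' termination-codon change that keeps a stop; 11 initiation-codon
#' change that keeps an initiator (unreachable for ATG starts under the
#' standard code, kept as a predicate for non-ATG annotated starts); 12
#' the genome base at the site is the assembly gap character N, which
#' trumps every other context.
#'
#' @return named integer vector of class codes.
#' @export
effect_classes <- function() {
  stats::setNames(0:12,
    c("intergenic", "upstream_2kb", "downstream_2kb", "splice_boundary",
      "intron", "start_changed", "stop_changed", "synonymous",
      "premature_stop", "nonsynonymous", "stop_silent", "start_silent",
      "genome_n"))
}

#' Build a transcript index for variant classification
#'
#' Precomputes, per mRNA model: strand-aware 2 kb upstream/downstream
#' flanks (truncated at chromosome ends), intron intervals and the two
#' intronic splice-boundary bases at each junction, and the spliced,
#' phase-trimmed CDS with its genomic-position-to-CDS-offset map.
#' Models whose CDS does not start with ATG or end with a stop on the
#' coding strand are flagged (`canonical = FALSE`) but still
#' classified; models whose phase-adjusted CDS length is not a multiple
#' of 3 are excluded from codon-level classes.
#'
#' @param models list of [GeneModel].
#' @param genome genome from [read_fasta()].
#' @return object of class `transcript_index`.
#' @export
build_transcript_index <- function(models, genome) {
  chrom_len <- nchar(genome)
  entries <- lapply(models, function(m) {
    if (!m$chrom %in% names(genome)) stop("model on unknown chromosome: ", m$chrom)
    geo <- model_geometry(m, chrom_len)
    cs <- coding_context(m, genome)
    canonical <- FALSE
    if (!is.null(cs)) {
      n_cod <- nchar(cs$coding) %/% 3L
      first <- substring(cs$coding, 1L, 3L)
      last <- substring(cs$coding, 3L * n_cod - 2L, 3L * n_cod)
      canonical <- first == "ATG" && last %in% STOP_CODONS
    }
    up_r <- if (length(geo$upstream)) range(geo$upstream) else NULL
    dn_r <- if (length(geo$downstream)) range(geo$downstream) else NULL
    list(model = m, span = geo$span, upstream = up_r, downstream = dn_r,
         splice = geo$splice, coding = cs, canonical = canonical)
  })
  by_chrom <- split(entries, vapply(entries, function(e) e$model$chrom, ""))
  structure(list(by_chrom = by_chrom, chrom_len = chrom_len),
            class = "transcript_index")
}

in_ranges <- function(pos, ranges) {
  any(pos >= ranges[, 1] & pos <= ranges[, 2])
}

#' Classify SNPs into the twelve effect categories
#'
#' For every variant, emits one effect record per overlapping mRNA
#' context (within one mRNA the class is decided by the precedence
#' N > codon > splice > intron) plus, for variants in no gene's
#' extended span, an upstream/downstream/intergenic record. Codon-level
#' classes substitute the strand-corrected allele into the spliced CDS
#' and translate the affected codon under the standard nuclear code.
#' Exonic positions outside the CDS carry the `unclassified_utr` flag
#' (class `NA`); CDS positions of frame-broken models carry
#' `non_coding_frame`.
#'
#' @param variants data.frame from [read_vcf()] or [plant_variants()].
#' @param index a `transcript_index`.
#' @param genome the genome the index was built on; every REF allele is
#'   checked against it (error on mismatch).
#' @return data.frame of effect records: the variant columns plus
#'   `gene_id`, `mrna_id`, `class` (integer 0-12, NA when flagged),
#'   `flag`, `cds_pos`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`.
#' @export
classify_variants <- function(variants, index, genome) {
  stopifnot(inherits(index, "transcript_index"))
  gb <- genome_base(genome, variants$chrom, variants$pos)
  bad <- gb != variants$ref
  if (any(bad))
    stop("REF mismatch at ", variants$chrom[bad][1], ":", variants$pos[bad][1],
         " (REF ", variants$ref[bad][1], ", genome ", gb[bad][1], ")")
  recs <- lapply(seq_len(nrow(variants)), function(i)
    classify_one(variants[i, , drop = FALSE], index))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

record_row <- function(v, gene_id = NA_character_, mrna_id = NA_character_,
                       class = NA_integer_, flag = NA_character_,
                       cds_pos = NA_integer_, ref_codon = NA_character_,
                       alt_codon = NA_character_, ref_aa = NA_character_,
                       alt_aa = NA_character_) {
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             sample_id = v$sample_id, gene_id = gene_id, mrna_id = mrna_id,
             class = class, flag = flag, cds_pos = cds_pos,
             ref_codon = ref_codon, alt_codon = alt_codon, ref_aa = ref_aa,
             alt_aa = alt_aa, stringsAsFactors = FALSE)
}

classify_one <- function(v, index) {
  entries <- index$by_chrom[[v$chrom]]
  if (v$ref == "N") {
    gene <- NA_character_
    for (e in entries)
      if (v$pos >= e$span[1] && v$pos <= e$span[2]) { gene <- e$model$gene_id; break }
    return(record_row(v, gene_id = gene, class = 12L))
  }
  recs <- list()
  for (e in entries) {
    m <- e$model
    if (v$pos >= e$span[1] && v$pos <= e$span[2]) {
      if (in_ranges(v$pos, m$cds)) {
        recs[[length(recs) + 1L]] <- classify_codon(v, e)
      } else if (in_ranges(v$pos, m$exons)) {
        recs[[length(recs) + 1L]] <-
          record_row(v, m$gene_id, m$mrna_id, flag = "unclassified_utr")
      } else if (v$pos %in% e$splice) {
        recs[[length(recs) + 1L]] <- record_row(v, m$gene_id, m$mrna_id, 3L)
      } else {
        recs[[length(recs) + 1L]] <- record_row(v, m$gene_id, m$mrna_id, 4L)
      }
    } else if (!is.null(e$upstream) &&
               v$pos >= e$upstream[1] && v$pos <= e$upstream[2]) {
      recs[[length(recs) + 1L]] <- record_row(v, m$gene_id, m$mrna_id, 1L)
    } else if (!is.null(e$downstream) &&
               v$pos >= e$downstream[1] && v$pos <= e$downstream[2]) {
      recs[[length(recs) + 1L]] <- record_row(v, m$gene_id, m$mrna_id, 2L)
    }
  }
  if (!length(recs)) return(record_row(v, class = 0L))
  do.call(rbind, recs)
}

classify_codon <- function(v, e) {
  m <- e$model
  if (is.null(e$coding) || !m$coding_frame)
    return(record_row(v, m$gene_id, m$mrna_id, flag = "non_coding_frame"))
  off <- match(v$pos, e$coding$cds_pos)
  if (is.na(off))  # phase-trimmed leading base
    return(record_row(v, m$gene_id, m$mrna_id, flag = "unclassified_utr"))
  n_cod <- nchar(e$coding$coding) %/% 3L
  ci <- (off - 1L) %/% 3L + 1L
  cj <- (off - 1L) %% 3L + 1L
  ref_codon <- substring(e$coding$coding, 3L * ci - 2L, 3L * ci)
  alt_tx <- if (m$strand == "+") v$alt else comp_base(v$alt)
  alt_codon <- ref_codon
  substring(alt_codon, cj, cj) <- alt_tx
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  cls <- if (ci == 1L) {
    if (alt_codon == "ATG") 11L else 5L
  } else if (ci == n_cod) {
    if (alt_codon %in% STOP_CODONS) 10L else 6L
  } else if (alt_codon %in% STOP_CODONS) 8L
    else if (ref_aa == alt_aa) 7L else 9L
  record_row(v, m$gene_id, m$mrna_id, cls,
             flag = if (e$canonical) NA_character_ else "noncanonical_cds",
             cds_pos = off, ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa)
}

# precedence rank of one record: lower wins
effect_rank <- function(class, flag) {
  r <- ifelse(!is.na(class) & class == 12L, 0,
       ifelse(!is.na(class) & class %in% 5:11, 1,
       ifelse(!is.na(flag) & flag %in% c("unclassified_utr", "non_coding_frame"), 2,
       ifelse(!is.na(class) & class == 3L, 3,
       ifelse(!is.na(class) & class == 4L, 4,
       ifelse(!is.na(class) & class == 1L, 5,
       ifelse(!is.na(class) & class == 2L, 6, 7)))))))
  r
}

#' Primary effect record per variant
#'
#' Reduces multi-context records to one per variant by the precedence
#' N > codon > exonic-flagged > splice > intron > upstream > downstream
#' > intergenic; ties across genes are broken by lexicographic gene id,
#' then mRNA id.
#'
#' @param records data.frame from [classify_variants()].
#' @return one record per input variant.
#' @export
primary_effects <- function(records) {
  key <- paste(records$sample_id, records$chrom, records$pos, records$alt)
  rank <- effect_rank(records$class, records$flag)
  ord <- order(key, rank, records$gene_id, records$mrna_id,
               method = "radix", na.last = TRUE)
  records <- records[ord, , drop = FALSE]
  records[!duplicated(key[ord]), , drop = FALSE]
}

#' Class-by-cultivar effect summary
#'
#' Counts primary records per effect class and cultivar. Classes sum to
#' the number of classified variants; records carrying only a flag
#' (UTR, frame-broken CDS) appear in the `unclassified` row.
#'
#' @param records data.frame from [classify_variants()].
#' @return data.frame: one row per class code 0-12 plus `unclassified`,
#'   one column per cultivar.
#' @export
effect_summary <- function(records) {
  prim <- primary_effects(records)
  cls <- ifelse(is.na(prim$class), "unclassified", as.character(prim$class))
  lev <- c(as.character(0:12), "unclassified")
  tab <- table(factor(cls, levels = lev), prim$sample_id)
  df <- as.data.frame.matrix(tab)
  data.frame(class = lev, df, row.names = NULL, check.names = FALSE)
}

#' GO-slim term by effect-class cross-tabulation
#'
#' For each annotation term and effect class, the number of distinct
#' genes carrying at least one primary variant of that class; a gene
#' annotated with several terms counts once per term.
#'
#' @param records data.frame from [classify_variants()].
#' @param annotation data.frame with `gene_id` and `term` columns.
#' @param classes effect classes to tabulate (default the
#'   function-changing codon classes 5, 6, 9, 8).
#' @return data.frame: one row per term, one column per class.
#' @export
go_effect_crosstab <- function(records, annotation, classes = c(5L, 6L, 9L, 8L)) {
  prim <- primary_effects(records)
  prim <- prim[!is.na(prim$class) & prim$class %in% classes &
               !is.na(prim$gene_id), , drop = FALSE]
  terms <- sort(unique(annotation$term))
  out <- matrix(0L, length(terms), length(classes),
                dimnames = list(terms, paste0("class_", classes)))
  for (t in terms) {
    tg <- annotation$gene_id[annotation$term == t]
    for (j in seq_along(classes)) {
      g <- unique(prim$gene_id[prim$class == classes[j]])
      out[t, j] <- sum(g %in% tg)
    }
  }
  data.frame(term = terms, out, row.names = NULL, check.names = FALSE)
}
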