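test_that("transcript index builds strand-aware 2 kb flank regions", {
  genome <- setNames(paste(rep("ACGT", 5000), collapse = ""), "c1")
  plus <- GeneModel("gP", "gP.1", "c1", "+",
                    exons = cbind(10001, 12000), cds = cbind(10001, 12000))
  minus <- GeneModel("gM", "gM.1", "c1", "-",
                     exons = cbind(10001, 12000), cds = cbind(10001, 12000))
  genome <- setNames(strrep("A", 20000), "c1")
  idx <- build_transcript_index(list(plus, minus), genome)
  e <- idx$by_chrom$c1
  expect_equal(e[[1]]$upstream, c(8001, 10000))
  expect_equal(e[[1]]$downstream, c(12001, 14000))
  expect_equal(e[[2]]$upstream, c(12001, 14000))     # strand mirror
  expect_equal(e[[2]]$downstream, c(8001, 10000))
})

test_that("each intron contributes two intronic splice bases per end", {
  genome <- setNames(strrep("A", 1000), "c1")
  m <- GeneModel("g", "g.1", "c1", "+",
                 exons = rbind(c(101, 160), c(261, 320)),
                 cds = rbind(c(101, 160), c(261, 320)))
  idx <- build_transcript_index(list(m), genome)
  expect_setequal(idx$by_chrom$c1[[1]]$splice, c(161, 162, 259, 260))
})

test_that("classifier reproduces planting truth and the rebuild oracle", {
  fx <- snp_fixture()
  idx <- build_transcript_index(fx$models, fx$genome)
  recs <- classify_variants(fx$variants, idx, fx$genome)
  prim <- primary_effects(recs)
  expect_identical(nrow(prim), nrow(fx$variants))     # conservation

  merged <- merge(prim, fx$truth,
                  by = c("chrom", "pos", "ref", "alt", "sample_id"))
  expect_identical(nrow(merged), nrow(fx$truth))
  expect_identical(mean(merged$class == merged$intended_class), 1)

  # independent rebuild-and-translate oracle on every planted variant
  oracle <- vapply(seq_len(nrow(fx$variants)), function(i)
    oracle_classify(fx$variants[i, ], fx$models, fx$genome), 0L)
  expect_identical(unname(prim$class[match(
    paste(fx$variants$chrom, fx$variants$pos, fx$variants$alt),
    paste(prim$chrom, prim$pos, prim$alt))]), oracle)
})

test_that("effect classes are invariant under reverse complement", {
  fx <- snp_fixture()
  idx <- build_transcript_index(fx$models, fx$genome)
  cls <- primary_effects(classify_variants(fx$variants, idx, fx$genome))
  mir <- mirror_fixture(fx$genome, fx$models, fx$variants)
  idx2 <- build_transcript_index(mir$models, mir$genome)
  cls2 <- primary_effects(classify_variants(mir$variants, idx2, mir$genome))
  key1 <- paste(cls$sample_id, cls$chrom, cls$pos)
  L <- nchar(fx$genome)
  key2 <- paste(cls2$sample_id, cls2$chrom, L[cls2$chrom] - cls2$pos + 1L)
  expect_identical(cls$class, cls2$class[match(key1, key2)])
})

test_that("spec'd example sites classify as their captioned category", {
  # one plus- and one minus-strand two-exon gene with known sequence
  ex_seq <- "ATGGCTTGGTACCTTGAAACCGGTTAA"  # M A W Y L E T G *
  intron <- "GTAAGCCTTAG"                  # 11 bp intron
  left <- strrep("T", 3000)
  right <- strrep("C", 3000)
  chrom_p <- paste0(left, substring(ex_seq, 1, 12), intron,
                    substring(ex_seq, 13, 27), right)
  e1 <- c(3001, 3012); i1 <- c(3013, 3023); e2 <- c(3024, 3038)
  mP <- GeneModel("gP", "gP.1", "cP", "+",
                  exons = rbind(e1, e2), cds = rbind(e1, e2))
  genome <- c(cP = chrom_p)
  idx <- build_transcript_index(list(mP), genome)
  classify1 <- function(chrom, pos, alt, genome, idx) {
    v <- data.frame(chrom = chrom, pos = pos,
                    ref = substring(genome[chrom], pos, pos), alt = alt,
                    sample_id = "S")
    primary_effects(classify_variants(v, idx, genome))
  }
  # intron positions: 1 bp inside -> splice (3); 3 bp inside -> intron (4)
  expect_identical(classify1("cP", 3013, "C", genome, idx)$class, 3L)
  expect_identical(classify1("cP", 3015, "C", genome, idx)$class, 4L)
  # TGG (Trp) internal codon -> TGA premature stop: exon2 holds TAC...
  # codon 3 TGG sits at tx offsets 7-9 = genomic 3007-3009; G->A at 3009
  got <- classify1("cP", 3009, "A", genome, idx)
  expect_identical(got$class, 8L)
  expect_identical(got$ref_codon, "TGG")
  expect_identical(got$alt_codon, "TGA")
  # GCT (Ala) codon 2 third base 3006: T->C stays Ala -> synonymous
  got7 <- classify1("cP", 3006, "C", genome, idx)
  expect_identical(got7$class, 7L)
  expect_identical(got7$ref_aa, got7$alt_aa)
  # start codon hit -> class 5; stop codon hit -> class 6 or 10
  expect_identical(classify1("cP", 3001, "C", genome, idx)$class, 5L)
  stop_pos <- 3038                        # TAA last base: A->G => TAG stop
  expect_identical(classify1("cP", stop_pos, "G", genome, idx)$class, 10L)
  expect_identical(classify1("cP", 3037, "T", genome, idx)$class, 6L)  # TTA

  # the same gene mirrored to the minus strand via the oracle transformer
  mir <- mirror_fixture(genome, list(mP),
                        data.frame(chrom = "cP", pos = 3009,
                                   ref = substring(chrom_p, 3009, 3009),
                                   alt = "A", sample_id = "S"))
  idxM <- build_transcript_index(mir$models, mir$genome)
  gotM <- primary_effects(classify_variants(mir$variants, idxM, mir$genome))
  expect_identical(gotM$class, 8L)        # minus-strand premature stop
})

test_that("genome N trumps every other context", {
  genome <- c(c1 = paste0(strrep("A", 2999), "N", strrep("A", 7000)))
  m <- GeneModel("g", "g.1", "c1", "+",
                 exons = cbind(2901, 3200), cds = cbind(2901, 3200))
  idx <- build_transcript_index(list(m), genome)
  v <- data.frame(chrom = "c1", pos = 3000, ref = "N", alt = "G",
                  sample_id = "S")
  rec <- classify_variants(v, idx, genome)
  expect_identical(rec$class, 12L)
  expect_identical(nrow(rec), 1L)
})

test_that("intergenic and REF-mismatch handling", {
  genome <- c(c1 = strrep("A", 30000))
  m <- GeneModel("g", "g.1", "c1", "+",
                 exons = cbind(10001, 10300), cds = cbind(10001, 10300))
  idx <- build_transcript_index(list(m), genome)
  v <- data.frame(chrom = "c1", pos = 25000, ref = "A", alt = "G",
                  sample_id = "S")
  expect_identical(classify_variants(v, idx, genome)$class, 0L)
  v$ref <- "C"
  expect_error(classify_variants(v, idx, genome), "REF mismatch")
})

test_that("effect summary counts every variant once per class", {
  fx <- snp_fixture()
  idx <- build_transcript_index(fx$models, fx$genome)
  recs <- classify_variants(fx$variants, idx, fx$genome)
  summ <- effect_summary(recs)
  cultivars <- unique(fx$variants$sample_id)
  expect_identical(sum(summ[, cultivars]), nrow(fx$variants))
  # per-class totals equal the planting request
  planted <- table(fx$truth$intended_class)
  for (cl in names(planted))
    expect_identical(sum(summ[summ$class == cl, cultivars]),
                     as.integer(planted[[cl]]))
})

test_that("GO-by-class cross-tab equals a brute-force tally", {
  fx <- snp_fixture()
  idx <- build_transcript_index(fx$models, fx$genome)
  recs <- classify_variants(fx$variants, idx, fx$genome)
  ann <- generate_annotation(fx$models, n_terms = 8, seed = 2)
  ct <- go_effect_crosstab(recs, ann)
  prim <- primary_effects(recs)
  for (cl in c(5L, 6L, 9L, 8L)) {
    genes_cl <- unique(prim$gene_id[!is.na(prim$class) & prim$class == cl])
    for (t in ct$term) {
      brute <- length(intersect(genes_cl, ann$gene_id[ann$term == t]))
      expect_identical(ct[ct$term == t, paste0("class_", cl)], brute)
    }
  }
  # a gene with two terms contributes one count to each term row
  ann2 <- data.frame(gene_id = rep(prim$gene_id[prim$class == 9][1], 2),
                     term = c("TA", "TB"))
  ct2 <- go_effect_crosstab(recs, ann2, classes = 9L)
  expect_identical(ct2$class_9, c(1L, 1L))
})
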