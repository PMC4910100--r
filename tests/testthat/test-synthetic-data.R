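test_that("genome generation is reproducible with the requested N fraction", {
  g1 <- generate_genome(1, 10000, 0, seed = 1)
  expect_length(g1, 1)
  expect_identical(nchar(g1[[1]]), 10000L)
  expect_false(grepl("N", g1[[1]]))

  g2 <- generate_genome(1, 10000, 0.01, seed = 1)
  n_count <- lengths(regmatches(g2, gregexpr("N", g2)))
  expect_identical(unname(n_count), 100L)

  expect_identical(generate_genome(2, 10000, 0.01, seed = 9),
                   generate_genome(2, 10000, 0.01, seed = 9))
})

test_that("planted genes start with ATG, end with a stop, and respect the gap", {
  gm <- generate_gene_models(generate_genome(1, 60000, 0, seed = 2),
                             n_genes = 8, seed = 2)
  strands <- vapply(gm$models, function(m) m$strand, "")
  expect_true(all(c("+", "-") %in% strands))
  for (m in gm$models) {
    cds_seq <- oracle_spliced_tx(m, gm$genome)   # independent extraction
    expect_identical(substring(cds_seq, 1, 3), "ATG")
    n <- nchar(cds_seq)
    expect_identical(n %% 3L, 0L)
    expect_true(substring(cds_seq, n - 2, n) %in% c("TAA", "TAG", "TGA"))
    prot <- oracle_translate(cds_seq)
    expect_false(grepl("\\*", substring(prot, 1, nchar(prot) - 1)))  # no internal stop
  }
  spans <- t(vapply(gm$models, function(m)
    c(min(m$exons[, 1]), max(m$exons[, 2])), c(0, 0)))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] - spans[-nrow(spans), 2] >= 4001))
})

test_that("generator errors when the genome cannot hold the request", {
  expect_error(generate_gene_models(generate_genome(1, 12000, 0, seed = 1),
                                    n_genes = 50, seed = 1), "too short")
})

test_that("planted variants match their construction contexts", {
  fx <- snp_fixture()
  expect_identical(fx$unplantable, "11")
  # REF equals the genome base everywhere
  gb <- vapply(seq_len(nrow(fx$variants)), function(i)
    substring(fx$genome[fx$variants$chrom[i]], fx$variants$pos[i],
              fx$variants$pos[i]), "")
  expect_identical(gb, fx$variants$ref)
  expect_false(any(duplicated(paste(fx$variants$chrom, fx$variants$pos))))

  # class 12 sites sit on genome N
  expect_true(all(fx$truth$ref[fx$truth$intended_class == 12] == "N"))

  # class 4 sites are > 2 bp from every exon boundary of their gene
  cl4 <- fx$truth[fx$truth$intended_class == 4, ]
  models_by_gene <- setNames(fx$models,
                             vapply(fx$models, function(m) m$gene_id, ""))
  for (i in seq_len(nrow(cl4))) {
    m <- models_by_gene[[cl4$gene_id[i]]]
    bounds <- c(m$exons[, 1], m$exons[, 2])
    expect_true(min(abs(bounds - cl4$pos[i])) > 2)
  }

  # class 7 sites are verified synonymous by the translation oracle
  cl7 <- fx$truth[fx$truth$intended_class == 7, ]
  for (i in seq_len(nrow(cl7))) {
    m <- models_by_gene[[cl7$gene_id[i]]]
    genome2 <- fx$genome
    chrom <- genome2[cl7$chrom[i]]
    substring(chrom, cl7$pos[i], cl7$pos[i]) <- cl7$alt[i]
    genome2[cl7$chrom[i]] <- chrom
    expect_identical(oracle_translate(oracle_spliced_tx(m, fx$genome)),
                     oracle_translate(oracle_spliced_tx(m, genome2)))
  }
})

test_that("zero-noise counts reproduce the planted templates exactly", {
  sheet <- pear_sample_sheet()
  genes <- sprintf("gene%03d", 1:60)

  # all-flat, no maturation change: identical RPKM across stages
  sim <- simulate_counts(genes, sheet, profile_spec = c(flat = 1),
                         maturation_spec = list(
                           up = c(post_ripening = 0, non_post_ripening = 0),
                           down = c(post_ripening = 0, non_post_ripening = 0),
                           cultivar_sd = c(post_ripening = 0, non_post_ripening = 0)),
                         noise = 0, seed = 4)
  rpkm <- compute_rpkm(sim$counts)
  for (cv in unique(sheet$cultivar)) {
    v <- rpkm$values[, cultivar_stage_cols(rpkm, cv)]
    expect_true(all(v == v[, 1]))
  }

  # steady decrease with planted down-regulation: strictly decreasing
  sim2 <- simulate_counts(genes, sheet,
                          profile_spec = c(steady_decrease = 1),
                          maturation_spec = list(
                            up = c(post_ripening = 0, non_post_ripening = 0),
                            down = c(post_ripening = 1, non_post_ripening = 1),
                            cultivar_sd = c(post_ripening = 0, non_post_ripening = 0)),
                          noise = 0, seed = 4)
  rpkm2 <- compute_rpkm(sim2$counts)
  for (cv in unique(sheet$cultivar)) {
    v <- rpkm2$values[, cultivar_stage_cols(rpkm2, cv)]
    expect_true(all(apply(v, 1, function(x) all(diff(x) < 0))))
  }

  # extreme maturation spec: up-proportions exactly 100 vs 0
  sim3 <- simulate_counts(genes, sheet,
                          profile_spec = c(flat = 1),
                          maturation_spec = list(
                            up = c(post_ripening = 1, non_post_ripening = 0),
                            down = c(post_ripening = 0, non_post_ripening = 0),
                            cultivar_sd = c(post_ripening = 0, non_post_ripening = 0)),
                          noise = 0, seed = 4)
  rpkm3 <- compute_rpkm(sim3$counts)
  for (cv in c("NG", "SK"))
    expect_equal(classify_updown(rpkm3, cv)$up_proportion, 100)
  for (cv in c("HS", "YL", "KX"))
    expect_equal(classify_updown(rpkm3, cv)$up_proportion, 0)
})

test_that("count simulation rejects bad fractions and is seed-stable", {
  sheet <- pear_sample_sheet()
  expect_error(simulate_counts(c("g1", "g2"), sheet,
                               profile_spec = c(flat = 1.5)), "sum to 1")
  expect_error(simulate_counts(
    c("g1", "g2"), sheet,
    maturation_spec = list(up = c(post_ripening = 1.2, non_post_ripening = 0),
                           down = c(post_ripening = 0, non_post_ripening = 0),
                           cultivar_sd = c(post_ripening = 0, non_post_ripening = 0))),
    "\\[0, 1\\]")
  s1 <- simulate_counts(sprintf("g%d", 1:30), sheet, seed = 8)
  s2 <- simulate_counts(sprintf("g%d", 1:30), sheet, seed = 8)
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$truth, s2$truth)
})

test_that("annotation generation matches its background and planted odds", {
  genes <- sprintf("g%03d", 1:400)
  ann <- generate_annotation(genes, n_terms = 10, seed = 6)
  expect_identical(generate_annotation(genes, n_terms = 10, seed = 6), ann)
  freq <- table(ann$term) / length(genes)
  expect_true(all(freq > 0.02 & freq < 0.3))

  subset <- genes[1:100]
  ann2 <- generate_annotation(genes, n_terms = 10, seed = 6,
                              enrichment_spec = list(term = "T01",
                                                     genes = subset,
                                                     odds_ratio = 8))
  t01 <- ann2$gene_id[ann2$term == "T01"]
  f_in <- mean(subset %in% t01)
  f_out <- mean(setdiff(genes, subset) %in% t01)
  odds <- (f_in / (1 - f_in)) / (f_out / (1 - f_out))
  expect_gt(odds, 2.5)

  # odds ratio 1 stays at background
  ann3 <- generate_annotation(genes, n_terms = 10, seed = 6,
                              enrichment_spec = list(term = "T01",
                                                     genes = subset,
                                                     odds_ratio = 1))
  t01b <- ann3$gene_id[ann3$term == "T01"]
  expect_lt(abs(mean(subset %in% t01b) - mean(setdiff(genes, subset) %in% t01b)),
            0.12)
})
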