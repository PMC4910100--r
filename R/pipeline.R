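#' Default pipeline configuration
#'
#' Returns the full configuration list: input paths (or the synthetic
#' fixture switch), stage toggles, stage parameters and the global
#' seed. The global seed fans out to per-stage derived seeds (hashed by
#' stage name) so toggling one stage never reshuffles another's
#' randomness.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @return nested configuration list.
#' @export
default_config <- function(out_dir = "pomecourse_out", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    inputs = list(synthetic = TRUE, fasta = NULL, gff3 = NULL,
                  vcf = NULL,        # named list: cultivar -> VCF path
                  counts = NULL, sample_sheet = NULL, annotation = NULL),
    stages = list(tree = TRUE, profiles = TRUE, maturation = TRUE,
                  enrichment = TRUE, coexpression = TRUE, snp = TRUE),
    params = list(
      rpkm = list(min_stages = 5L, min_rpkm = 0),
      stem = list(c = 2L, m = 20L, n_perm = 1000L, alpha = 0.05),
      mat = list(threshold = 1, pseudocount = 1, test = "welch"),
      enrich = list(correction = "none", alpha = 0.05),
      coexpr = list(beta = 6, signed = FALSE, cut_height = 0.75,
                    min_size = 5L, min_weight = 0.1),
      synthetic = list(n_genes = 40L, noise = 0.05, per_class = 20L))
  )
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stage))) %% 2147483L
}

#' Run the full analysis pipeline
#'
#' Executes quantification, presence filtering, the sample tree,
#' profile clustering, the maturation contrast, enrichment,
#' co-expression and SNP effect classification in dependency order,
#' writing TSV/JSON/Newick reports and a reproducibility manifest to
#' `config$out_dir`. Any stage failure halts with a stage-tagged error.
#' Given the same configuration and seed, the text outputs are
#' byte-identical across reruns.
#'
#' @param config configuration list from [default_config()] (possibly
#'   edited), or the path of a YAML file with the same structure.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- utils::modifyList(
    default_config(), yaml::read_yaml(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  res <- list()
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
  }
  outfile <- function(name) file.path(config$out_dir, name)
  tsv <- function(df, name) {
    utils::write.table(df, outfile(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # ---- inputs -------------------------------------------------------
  res$inputs <- in_stage("inputs", {
    if (isTRUE(config$inputs$synthetic)) {
      sd <- stage_seed(config$seed, "synthetic")
      genome0 <- generate_genome(n_chrom = 2L, chrom_length = 100000L,
                                 n_fraction = 0.002, seed = sd)
      gm <- generate_gene_models(genome0, n_genes = p$synthetic$n_genes,
                                 seed = sd)
      sheet <- pear_sample_sheet()
      cultivars <- unique(sheet$cultivar)
      planted <- plant_variants(gm$genome, gm$models,
                                default_variant_spec(p$synthetic$per_class),
                                seed = sd, sample_ids = cultivars)
      sim <- simulate_counts(gm$models, sheet, noise = p$synthetic$noise,
                             seed = sd)
      ann <- generate_annotation(gm$models, seed = sd)
      list(genome = gm$genome, models = gm$models, sheet = sheet,
           variants = planted$variants, truth = planted$truth,
           counts = sim$counts, counts_truth = sim$truth, annotation = ann)
    } else {
      genome <- if (!is.null(config$inputs$fasta)) read_fasta(config$inputs$fasta)
      models <- if (!is.null(config$inputs$gff3)) read_gff3(config$inputs$gff3)
      sheet <- validate_sample_sheet(
        utils::read.delim(config$inputs$sample_sheet))
      counts <- read_count_matrix(config$inputs$counts, sheet,
                                  gene_length = if (!is.null(models)) gene_lengths(models))
      if (is.null(counts$total_mapped))
        counts$total_mapped <- colSums(counts$values)
      variants <- if (!is.null(config$inputs$vcf))
        do.call(rbind, lapply(names(config$inputs$vcf), function(cv)
          read_vcf(config$inputs$vcf[[cv]], cv, genome)))
      ann <- if (!is.null(config$inputs$annotation))
        utils::read.delim(config$inputs$annotation)
      list(genome = genome, models = models, sheet = sheet,
           variants = variants, counts = counts, annotation = ann)
    }
  })
  inp <- res$inputs
  cultivars <- unique(inp$sheet$cultivar)
  groups <- stats::setNames(
    inp$sheet$maturity_group[match(cultivars, inp$sheet$cultivar)], cultivars)

  # ---- quantification + presence filter (always on) -----------------
  res$rpkm <- in_stage("rpkm", compute_rpkm(inp$counts))
  tsv(data.frame(gene_id = rownames(res$rpkm$values),
                 round(res$rpkm$values, 4), check.names = FALSE), "rpkm.tsv")
  res$filtered <- in_stage("rpkm", {
    fl <- lapply(cultivars, function(cv)
      presence_filter(res$rpkm, cv, min_stages = p$rpkm$min_stages,
                      min_rpkm = p$rpkm$min_rpkm))
    stats::setNames(fl, cultivars)
  })
  filtered_union <- sort(unique(unlist(res$filtered)))
  tsv(data.frame(gene_id = filtered_union), "presence_filtered.tsv")
  tsv(mapping_summary(inp$counts), "mapping_summary.tsv")

  # ---- sample tree ---------------------------------------------------
  if (isTRUE(config$stages$tree)) {
    res$corr <- in_stage("tree", spearman_matrix(res$rpkm, filtered_union))
    res$tree <- in_stage("tree", average_linkage_tree(res$corr))
    tsv(data.frame(sample_id = rownames(res$corr), round(res$corr, 6),
                   check.names = FALSE), "correlation.tsv")
    write_newick(res$tree, outfile("sample_tree.nwk"))
  }

  # ---- profile clustering -------------------------------------------
  if (isTRUE(config$stages$profiles)) {
    res$profiles <- in_stage("profiles",
      enumerate_and_select_profiles(T = 7L, c = p$stem$c, m = p$stem$m))
    res$assignments <- in_stage("profiles", {
      lapply(stats::setNames(cultivars, cultivars), function(cv)
        assign_genes(expression_series(res$rpkm, cv, res$filtered[[cv]]),
                     res$profiles))
    })
    asg_tab <- do.call(rbind, lapply(cultivars, function(cv)
      data.frame(cultivar = cv, res$assignments[[cv]])))
    asg_tab$correlation <- round(asg_tab$correlation, 6)
    tsv(asg_tab, "profile_assignments.tsv")
    res$significance <- in_stage("profiles", {
      lapply(stats::setNames(cultivars, cultivars), function(cv)
        cluster_significance(
          expression_series(res$rpkm, cv, res$filtered[[cv]]), res$profiles,
          n_perm = p$stem$n_perm, alpha = p$stem$alpha,
          seed = stage_seed(config$seed, paste0("significance_", cv))))
    })
    jsonlite::write_json(res$significance, outfile("profile_significance.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
    dec_id <- monotone_decrease_profile(res$profiles)
    res$venn <- in_stage("profiles",
      cross_cultivar_overlap(res$assignments, dec_id))
    tsv(res$venn, "profile_overlap.tsv")
  }

  # ---- maturation contrast ------------------------------------------
  if (isTRUE(config$stages$maturation)) {
    res$contrasts <- in_stage("maturation",
      lapply(stats::setNames(cultivars, cultivars), function(cv)
        classify_updown(res$rpkm, cv, threshold = p$mat$threshold,
                        pseudocount = p$mat$pseudocount)))
    ctab <- do.call(rbind, lapply(res$contrasts, function(x)
      data.frame(cultivar = x$cultivar, maturity_group = groups[[x$cultivar]],
                 n_up = length(x$up), n_down = length(x$down),
                 n_unchanged = length(x$unchanged),
                 up_percent = round(x$up_proportion, 4),
                 down_percent = round(x$down_proportion, 4))))
    tsv(ctab, "maturation_contrasts.tsv")
    res$group_test <- in_stage("maturation", {
      a <- ctab$up_percent[ctab$maturity_group == "post_ripening"]
      b <- ctab$up_percent[ctab$maturity_group == "non_post_ripening"]
      welch_t_test(a, b, pooled = identical(p$mat$test, "pooled"))
    })
    jsonlite::write_json(unclass(res$group_test), outfile("group_test.json"),
                         digits = NA, auto_unbox = TRUE)
    res$exclusive <- in_stage("maturation",
      exclusive_gene_sets(res$contrasts, groups))
  }

  # ---- enrichment ----------------------------------------------------
  if (isTRUE(config$stages$enrichment) && !is.null(inp$annotation) &&
      isTRUE(config$stages$profiles)) {
    res$enrichment <- in_stage("enrichment", {
      dec_id <- monotone_decrease_profile(res$profiles)
      core <- Reduce(intersect, lapply(res$assignments, function(a)
        a$gene_id[a$profile_id == dec_id]))
      enrich(core, inp$annotation, filtered_union,
             alpha = p$enrich$alpha, correction = p$enrich$correction)
    })
    tsv(res$enrichment, "enrichment.tsv")
  }

  # ---- co-expression -------------------------------------------------
  if (isTRUE(config$stages$coexpression)) {
    res$network <- in_stage("coexpression", {
      adj <- adjacency(res$rpkm, beta = p$coexpr$beta,
                       signed = p$coexpr$signed, genes = filtered_union)
      tom <- tom_similarity(adj)
      list(tom = tom,
           modules = detect_modules(tom, p$coexpr$cut_height, p$coexpr$min_size),
           edges = export_edges(tom, p$coexpr$min_weight))
    })
    ed <- res$network$edges
    ed$weight <- round(ed$weight, 6)
    tsv(ed, "edges.tsv")
    tsv(data.frame(gene_id = names(res$network$modules),
                   module = res$network$modules), "modules.tsv")
  }

  # ---- SNP effects ---------------------------------------------------
  if (isTRUE(config$stages$snp) && !is.null(inp$variants) &&
      !is.null(inp$models)) {
    res$effects <- in_stage("snp", {
      idx <- build_transcript_index(inp$models, inp$genome)
      classify_variants(inp$variants, idx, inp$genome)
    })
    tsv(primary_effects(res$effects), "snp_effects.tsv")
    tsv(effect_summary(res$effects), "snp_summary.tsv")
    if (!is.null(inp$annotation))
      tsv(go_effect_crosstab(res$effects, inp$annotation), "go_crosstab.tsv")
  }

  # ---- manifest ------------------------------------------------------
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  res$manifest <- list(
    package = "pomecourse",
    version = as.character(utils::packageVersion("pomecourse")),
    seed = config$seed,
    params = p,
    stages = config$stages,
    output_checksums = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(res$manifest$output_checksums) <- files
  jsonlite::write_json(res$manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

# id of the selected profile closest to a strict monotone decrease
monotone_decrease_profile <- function(profiles) {
  tm <- profiles$templates
  target <- seq(0, by = -1, length.out = ncol(tm))
  cors <- apply(tm, 1L, function(t) stats::cor(t, target))
  as.integer(rownames(tm)[which.max(cors)])
}
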