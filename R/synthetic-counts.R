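#' Built-in seven-stage expression templates
#'
#' Log2-scale stage templates used by [simulate_counts()]. Stages 1-6
#' follow the named developmental shape; the stage-7 (post-harvest
#' senescence) value is set per gene and cultivar by the maturation
#' assignment, so only stages 1-6 of the template are consumed.
#'
#' @return named list of length-7 numeric vectors.
#' @export
profile_templates <- function() {
  list(steady_decrease = c(6, 5, 4, 3, 2, 1, 1),
       steady_increase = c(0, 1, 2, 3, 4, 5, 5),
       flat            = c(0, 0, 0, 0, 0, 0, 0),
       late_peak       = c(0, 0, 1, 3, 5, 3, 3))
}

#' Simulate a count matrix with planted expression structure
#'
#' Each gene gets one profile template (its stage 1-6 shape) and, per
#' cultivar, a maturation direction. Counts are drawn around
#' `base * 2^template` means with negative-binomial dispersion `noise`
#' (`noise = 0` gives the exact means). The stage-7 mean is the stage-6
#' mean times `2^(+2)` for genes planted "up", `2^(-2)` for "down", and
#' unchanged for the rest, so the planted per-cultivar up-fraction is
#' exactly the fraction of genes with a 6-to-7 log2 fold change of +2.
#' Per-cultivar up-fractions are drawn around the maturity-group means
#' with the group-level spread in `cultivar_sd`.
#'
#' @param models list of [GeneModel] (gene ids and lengths), or a
#'   character vector of gene ids (lengths then default to 500 bp).
#' @param sample_sheet panel layout, e.g. [pear_sample_sheet()].
#' @param profile_spec named fractions over [profile_templates()] names.
#' @param maturation_spec list with `up` and `down` (named fractions
#'   per maturity group) and `cultivar_sd` (named per-group spread of
#'   the cultivar-level up/down fractions). Defaults plant up-fractions
#'   0.44 (post-ripening) and 0.24 (non-post-ripening).
#' @param noise negative-binomial dispersion (variance = mu + noise*mu^2).
#' @param seed integer RNG seed.
#' @param lib_size declared per-sample total of mapped reads.
#' @return list with `counts` (a counts-mode [ExpressionMatrix] carrying
#'   gene lengths and declared totals) and `truth` (profile label per
#'   gene; per-cultivar up/down gene sets and realized fractions).
#' @export
simulate_counts <- function(models, sample_sheet,
                            profile_spec = c(steady_decrease = 0.35,
                                             steady_increase = 0.25,
                                             flat = 0.25, late_peak = 0.15),
                            maturation_spec = list(
                              up = c(post_ripening = 0.44, non_post_ripening = 0.24),
                              down = c(post_ripening = 0.20, non_post_ripening = 0.20),
                              cultivar_sd = c(post_ripening = 0.005, non_post_ripening = 0.028)),
                            noise = 0.05, seed = 1L, lib_size = 2e6) {
  if (is.character(models)) {
    gene_ids <- models
    glen <- stats::setNames(rep(500, length(gene_ids)), gene_ids)
  } else {
    glen <- gene_lengths(models)
    gene_ids <- names(glen)
  }
  sheet <- validate_sample_sheet(sample_sheet)
  tmpl <- profile_templates()
  if (any(profile_spec < 0) || abs(sum(profile_spec) - 1) > 1e-8)
    stop("profile_spec fractions must be non-negative and sum to 1")
  if (any(unlist(maturation_spec[c("up", "down")]) < 0) ||
      any(unlist(maturation_spec[c("up", "down")]) > 1))
    stop("maturation fractions must lie in [0, 1]")
  stopifnot(all(names(profile_spec) %in% names(tmpl)))
  set.seed(seed + 3000L)
  n <- length(gene_ids)

  # profile labels by planted fractions (largest-remainder rounding)
  n_per <- floor(profile_spec * n)
  rem <- n - sum(n_per)
  if (rem > 0) {
    frac <- profile_spec * n - n_per
    n_per[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      n_per[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  labels <- sample(rep(names(profile_spec), times = n_per))
  base <- sample(2^(4:8), n, replace = TRUE)

  cultivars <- unique(sheet$cultivar)
  group_of <- sheet$maturity_group[match(cultivars, sheet$cultivar)]
  delta <- matrix(0, n, length(cultivars),
                  dimnames = list(gene_ids, cultivars))
  up_sets <- down_sets <- stats::setNames(vector("list", length(cultivars)), cultivars)
  up_frac <- down_frac <- stats::setNames(numeric(length(cultivars)), cultivars)
  sd_of <- maturation_spec$cultivar_sd
  for (k in seq_along(cultivars)) {
    g <- group_of[k]
    fu <- min(max(stats::rnorm(1, maturation_spec$up[[g]], sd_of[[g]]), 0), 1)
    fd <- min(max(stats::rnorm(1, maturation_spec$down[[g]], sd_of[[g]]), 0), 1 - fu)
    n_up <- round(fu * n); n_dn <- round(fd * n)
    pick <- sample(gene_ids, n_up + n_dn)
    up_sets[[k]] <- pick[seq_len(n_up)]
    down_sets[[k]] <- if (n_dn > 0) pick[n_up + seq_len(n_dn)] else character(0)
    delta[up_sets[[k]], k] <- 2
    delta[down_sets[[k]], k] <- -2
    up_frac[k] <- n_up / n; down_frac[k] <- n_dn / n
  }

  values <- matrix(0, n, nrow(sheet),
                   dimnames = list(gene_ids, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    st <- sheet$stage[j]
    cv <- sheet$cultivar[j]
    expo <- vapply(seq_len(n), function(g) {
      tv <- tmpl[[labels[g]]]
      if (st == 7L) tv[6] + delta[g, cv] else tv[st]
    }, 0)
    mu <- base * 2^expo
    values[, j] <- if (noise > 0)
      stats::rnbinom(n, mu = mu, size = 1 / noise) else round(mu)
  }
  em <- ExpressionMatrix(values, sheet, mode = "counts", gene_length = glen,
                         total_mapped = stats::setNames(rep(lib_size, nrow(sheet)),
                                                        sheet$sample_id))
  truth <- list(profiles = data.frame(gene_id = gene_ids, profile = labels,
                                      stringsAsFactors = FALSE),
                up = up_sets, down = down_sets,
                up_fraction = up_frac, down_fraction = down_frac)
  list(counts = em, truth = truth)
}

#' Generate a gene-to-term annotation table
#'
#' Every term has its own background frequency; an optional enrichment
#' plants one term inside a chosen gene subset at a stated odds ratio.
#'
#' @param genes character vector of gene ids (or list of [GeneModel]).
#' @param n_terms number of terms (`T01`, `T02`, ...).
#' @param enrichment_spec `NULL`, or list with `term` (term id),
#'   `genes` (enriched subset) and `odds_ratio`.
#' @param seed integer RNG seed.
#' @param base_freq_range background term frequency range.
#' @return data.frame with columns `gene_id`, `term` (long format).
#' @export
generate_annotation <- function(genes, n_terms = 20L, enrichment_spec = NULL,
                                seed = 1L, base_freq_range = c(0.05, 0.2)) {
  if (is.list(genes)) genes <- unique(vapply(genes, function(m) m$gene_id, ""))
  set.seed(seed + 4000L)
  terms <- sprintf("T%02d", seq_len(n_terms))
  p0 <- stats::runif(n_terms, base_freq_range[1], base_freq_range[2])
  names(p0) <- terms
  out <- list()
  for (t in terms) {
    p <- rep(p0[[t]], length(genes))
    if (!is.null(enrichment_spec) && identical(enrichment_spec$term, t)) {
      odds <- p0[[t]] / (1 - p0[[t]]) * enrichment_spec$odds_ratio
      p[genes %in% enrichment_spec$genes] <- odds / (1 + odds)
    }
    hit <- stats::runif(length(genes)) < p
    if (any(hit))
      out[[t]] <- data.frame(gene_id = genes[hit], term = t,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
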