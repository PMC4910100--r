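#' Log2 fold change between maturity and senescence
#'
#' Per-gene `log2((rpkm7 + pseudocount) / (rpkm6 + pseudocount))` for
#' one cultivar's stage-6 (maturity) and stage-7 (post-harvest
#' senescence) samples.
#'
#' @param rpkm an rpkm-mode [ExpressionMatrix].
#' @param cultivar cultivar to contrast.
#' @param pseudocount stabilizing offset (default 1).
#' @return named numeric vector of fold changes.
#' @export
log2_fold_change <- function(rpkm, cultivar, pseudocount = 1) {
  stopifnot(inherits(rpkm, "ExpressionMatrix"))
  cols <- cultivar_samples(rpkm, cultivar)
  stages <- rpkm$samples$stage[match(cols, rpkm$samples$sample_id)]
  if (!all(c(6L, 7L) %in% stages)) stop("cultivar lacks stage 6 or 7")
  s6 <- rpkm$values[, cols[stages == 6L]]
  s7 <- rpkm$values[, cols[stages == 7L]]
  log2((s7 + pseudocount) / (s6 + pseudocount))
}

#' Classify genes up/down between maturity and senescence
#'
#' Partitions the expressed genes of one cultivar into up
#' (`fc >= threshold`), down (`fc <= -threshold`) and unchanged sets,
#' with proportions in percent over the full denominator. The
#' denominator is every gene expressed (RPKM > `min_expr`) in stage 6
#' or stage 7.
#'
#' @param rpkm an rpkm-mode [ExpressionMatrix].
#' @param cultivar cultivar to contrast.
#' @param threshold absolute log2 fold-change cutoff (default 1).
#' @param pseudocount offset passed to [log2_fold_change()].
#' @param min_expr expression floor defining the denominator.
#' @return list of class `MaturationContrast`: cultivar, up/down/
#'   unchanged gene id vectors, `up_proportion` and `down_proportion`
#'   in percent.
#' @export
classify_updown <- function(rpkm, cultivar, threshold = 1, pseudocount = 1,
                            min_expr = 0) {
  cols <- cultivar_samples(rpkm, cultivar)
  stages <- rpkm$samples$stage[match(cols, rpkm$samples$sample_id)]
  expressed <- rpkm$values[, cols[stages == 6L]] > min_expr |
               rpkm$values[, cols[stages == 7L]] > min_expr
  genes <- rownames(rpkm$values)[expressed]
  if (length(genes) == 0L) stop("no expressed gene in stages 6/7 for ", cultivar)
  fc <- log2_fold_change(rpkm, cultivar, pseudocount)[genes]
  # at threshold 0 a fold change of exactly 0 stays "unchanged"
  up <- genes[fc >= threshold & fc > -threshold]
  down <- genes[fc <= -threshold & fc < threshold]
  unchanged <- setdiff(genes, c(up, down))
  structure(list(cultivar = cultivar, up = up, down = down,
                 unchanged = unchanged,
                 up_proportion = 100 * length(up) / length(genes),
                 down_proportion = 100 * length(down) / length(genes)),
            class = "MaturationContrast")
}

#' @export
print.MaturationContrast <- function(x, ...) {
  cat(sprintf("MaturationContrast %s: up %.2f%% (%d), down %.2f%% (%d), unchanged %d\n",
              x$cultivar, x$up_proportion, length(x$up), x$down_proportion,
              length(x$down), length(x$unchanged)))
  invisible(x)
}

#' Welch two-sample t-test on group percentages
#'
#' Unequal-variance two-sample t-test (Welch-Satterthwaite degrees of
#' freedom, two-tailed) comparing the per-cultivar up-regulation
#' percentages of the post-ripening and non-post-ripening groups. A
#' pooled-variance variant is available by flag.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @param pooled use the equal-variance pooled test instead of Welch.
#' @return list of class `GroupTest`: `t`, `df`, `p`, group means.
#' @export
welch_t_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    # both groups constant: t.test refuses; the limit of the Welch
    # statistic is 0 (equal means) or +/-Inf (separated constants)
    eq <- mean(group_a) == mean(group_b)
    return(structure(list(
      t = if (eq) 0 else sign(mean(group_a) - mean(group_b)) * Inf,
      df = length(group_a) + length(group_b) - 2,
      p = if (eq) 1 else .Machine$double.xmin,
      mean_a = mean(group_a), mean_b = mean(group_b),
      method = if (pooled) "pooled" else "welch"), class = "GroupTest"))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = pooled)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
                 method = if (pooled) "pooled" else "welch"),
            class = "GroupTest")
}

#' @export
print.GroupTest <- function(x, ...) {
  cat(sprintf("GroupTest (%s): t = %.4f, df = %.3f, p = %.6g (means %.2f vs %.2f)\n",
              x$method, x$t, x$df, x$p, x$mean_a, x$mean_b))
  invisible(x)
}

#' Group-exclusive up/down gene sets
#'
#' Genes up-regulated in every post-ripening cultivar but in no
#' non-post-ripening cultivar (`only_up_in_post`), and the dual set for
#' down-regulation (`only_down_in_non`). With `mode = "any"`, membership
#' in one cultivar of the group suffices on the inclusion side.
#'
#' @param contrasts list of [classify_updown()] results, one per cultivar.
#' @param groups named character vector mapping cultivar to
#'   `"post_ripening"` / `"non_post_ripening"`.
#' @param mode `"all"` (intersection over the group, default) or `"any"`.
#' @return list with `only_up_in_post` and `only_down_in_non`.
#' @export
exclusive_gene_sets <- function(contrasts, groups, mode = c("all", "any")) {
  mode <- match.arg(mode)
  cultivars <- vapply(contrasts, function(x) x$cultivar, "")
  names(contrasts) <- cultivars
  post <- cultivars[groups[cultivars] == "post_ripening"]
  non <- cultivars[groups[cultivars] == "non_post_ripening"]
  combine <- function(sets) {
    if (!length(sets)) return(character(0))
    if (mode == "all") Reduce(intersect, sets) else Reduce(union, sets)
  }
  up_post <- combine(lapply(contrasts[post], function(x) x$up))
  up_non_any <- Reduce(union, c(lapply(contrasts[non], function(x) x$up),
                                list(character(0))))
  down_non <- combine(lapply(contrasts[non], function(x) x$down))
  down_post_any <- Reduce(union, c(lapply(contrasts[post], function(x) x$down),
                                   list(character(0))))
  list(only_up_in_post = setdiff(up_post, up_non_any),
       only_down_in_non = setdiff(down_non, down_post_any))
}
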