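#' Enumerate and select model expression profiles
#'
#' Candidate templates are all length-`T` integer series starting at 0
#' with successive differences in `-c..c`, excluding the all-flat one.
#' From these, `m` model profiles are chosen by greedy max-min
#' selection on the distance `1 - Pearson correlation`: the selection
#' starts from the most distant candidate pair and repeatedly adds the
#' candidate whose minimum distance to the chosen set is largest. Ties
#' are broken toward the lexicographically smallest template, so the
#' selection is fully deterministic.
#'
#' @param T number of time points (stages).
#' @param c maximum absolute unit change between consecutive stages.
#' @param m number of profiles to select.
#' @return object of class `ModelProfileSet`: a list with `templates`
#'   (m x T integer matrix, rownames = 0-based profile ids) and the
#'   parameters.
#' @export
enumerate_and_select_profiles <- function(T = 7L, c = 2L, m = 20L) {
  key <- paste(T, c, m, sep = "_")
  cached <- .profile_cache[[key]]
  if (!is.null(cached)) return(cached)
  diffs <- as.matrix(expand.grid(rep(list(seq(-c, c)), T - 1L),
                                 KEEP.OUT.ATTRS = FALSE))
  keep <- rowSums(diffs != 0L) > 0L          # drop the all-flat template
  diffs <- diffs[keep, , drop = FALSE]
  templates <- cbind(0L, t(apply(diffs, 1L, cumsum)))
  # lexicographic template order (first-index tie-break substrate)
  ord <- do.call(order, as.data.frame(templates))
  templates <- templates[ord, , drop = FALSE]
  n <- nrow(templates)
  if (m > n) stop("m = ", m, " exceeds the ", n, " distinct non-flat candidates")
  z <- t(scale(t(templates)))                # row-standardized
  # most distant pair = minimum correlation; on ties the first (i, j)
  # pair in lexicographic scan order, i.e. the lexicographically
  # smallest templates. Two chunked passes: global minimum, then the
  # first pair attaining it.
  chunk <- 2000L
  starts <- seq(1L, n, by = chunk)
  chunk_cor <- function(i0) {
    i1 <- min(i0 + chunk - 1L, n)
    cc <- (z[i0:i1, , drop = FALSE] %*% t(z)) / (T - 1L)
    list(cc = cc, upper = outer(i0:i1, seq_len(n), `<`))
  }
  gmin <- Inf
  for (i0 in starts) {
    ch <- chunk_cor(i0)
    gmin <- min(gmin, ch$cc[ch$upper])
  }
  chosen <- NULL
  for (i0 in starts) {
    ch <- chunk_cor(i0)
    hit <- which(ch$upper & ch$cc <= gmin + 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      chosen <- c(i0 + hit[1, 1] - 1L, hit[1, 2])
      break
    }
  }
  cor_all <- (z %*% t(z[chosen, , drop = FALSE])) / (T - 1L)
  min_dist <- pmin(1 - cor_all[, 1L], 1 - cor_all[, 2L])
  min_dist[chosen] <- -Inf
  while (length(chosen) < m) {
    nxt <- which.max(min_dist)               # first index wins ties
    chosen <- c(chosen, nxt)
    d_new <- 1 - as.vector(z %*% z[nxt, ]) / (T - 1L)
    min_dist <- pmin(min_dist, d_new)
    min_dist[nxt] <- -Inf
  }
  sel <- templates[chosen, , drop = FALSE]
  rownames(sel) <- as.character(seq_len(length(chosen)) - 1L)
  colnames(sel) <- paste0("stage", seq_len(T))
  out <- structure(list(templates = sel, T = T, c = c, m = m),
                   class = "ModelProfileSet")
  .profile_cache[[key]] <- out
  out
}

# the selection is deterministic, so it is computed once per (T, c, m)
.profile_cache <- new.env(parent = emptyenv())

#' @export
print.ModelProfileSet <- function(x, ...) {
  cat(sprintf("ModelProfileSet: %d profiles, %d stages, max unit change %d\n",
              x$m, x$T, x$c))
  invisible(x)
}

#' Assign genes to model profiles by correlation
#'
#' Each gene series (rows of the matrix from [expression_series()]) is
#' assigned to the profile with maximal Pearson correlation; exact ties
#' go to the lowest profile id. Genes with zero variance across stages
#' cannot be correlated and are excluded (listed in the `unassigned`
#' attribute).
#'
#' @param series genes x stages numeric matrix.
#' @param profiles a `ModelProfileSet`.
#' @return data.frame with `gene_id`, `profile_id` (0-based integer)
#'   and `correlation`; attribute `unassigned` holds the zero-variance
#'   gene ids.
#' @export
assign_genes <- function(series, profiles) {
  stopifnot(inherits(profiles, "ModelProfileSet"),
            ncol(series) == profiles$T)
  sds <- apply(series, 1L, stats::sd)
  flat <- sds == 0 | is.na(sds)
  z <- t(scale(t(series[!flat, , drop = FALSE])))
  zt <- t(scale(t(profiles$templates)))
  cc <- (z %*% t(zt)) / (profiles$T - 1L)
  best <- max.col(cc, ties.method = "first")
  out <- data.frame(gene_id = rownames(series)[!flat],
                    profile_id = as.integer(rownames(profiles$templates)[best]),
                    correlation = cc[cbind(seq_len(nrow(cc)), best)],
                    stringsAsFactors = FALSE)
  attr(out, "unassigned") <- rownames(series)[flat]
  out
}

#' Permutation significance of profile gene counts
#'
#' Under the null that a gene's stage order is exchangeable, each
#' gene's series is permuted and re-assigned; the expected count of a
#' profile is its mean count over permutations. The p-value is the
#' binomial upper tail `P(X >= observed)` with success probability
#' `expected / total` over the `total` assigned genes, Bonferroni
#' corrected over the `m` profiles.
#'
#' @param series genes x stages matrix (as given to [assign_genes()]).
#' @param profiles a `ModelProfileSet`.
#' @param n_perm number of permutations (warning below 100).
#' @param seed integer RNG seed.
#' @param alpha significance level applied to the corrected p.
#' @param exhaustive permute over all `T!` stage orders instead of
#'   sampling (ignores `n_perm`).
#' @return data.frame with `profile_id`, `observed`, `expected`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
cluster_significance <- function(series, profiles, n_perm = 1000L, seed = 1L,
                                 alpha = 0.05, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 100L)
    warning("n_perm < 100 gives unstable expected counts")
  asg <- assign_genes(series, profiles)
  m <- profiles$m
  Tn <- profiles$T
  obs <- tabulate(asg$profile_id + 1L, nbins = m)
  total <- nrow(asg)
  keep <- rownames(series) %in% asg$gene_id
  z <- t(scale(t(series[keep, , drop = FALSE])))
  zt <- t(scale(t(profiles$templates)))
  n <- nrow(z)
  set.seed(seed)
  perms <- if (exhaustive) all_permutations(Tn) else NULL
  B <- if (exhaustive) nrow(perms) else n_perm
  count_sum <- numeric(m)
  for (b in seq_len(B)) {
    if (exhaustive) {
      zp <- z[, perms[b, ], drop = FALSE]
    } else {
      # independent column permutation per gene, vectorized
      keys <- matrix(stats::runif(n * Tn), n, Tn)
      lin <- order(row(keys), keys)
      cols <- ((lin - 1L) %/% n) + 1L
      zp <- matrix(z[cbind(rep(seq_len(n), each = Tn), cols)], n, Tn,
                   byrow = TRUE)
    }
    cc <- (zp %*% t(zt)) / (Tn - 1L)
    count_sum <- count_sum + tabulate(max.col(cc, ties.method = "first"),
                                      nbins = m)
  }
  expected <- count_sum / B
  p <- stats::pbinom(obs - 1L, total, pmin(expected / total, 1),
                     lower.tail = FALSE)
  p_bonf <- pmin(1, p * m)
  data.frame(profile_id = as.integer(rownames(profiles$templates)),
             observed = obs, expected = expected, p = p,
             p_bonferroni = p_bonf, significant = p_bonf < alpha)
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i)) |> unname()
  }))
}

#' Cross-cultivar membership overlap for one profile
#'
#' Exact set algebra over the per-cultivar gene memberships of one
#' profile: the count of genes in every non-empty cultivar-subset
#' region of the Venn diagram (31 regions for five cultivars), plus the
#' all-cultivar core.
#'
#' @param assignments named list (one entry per cultivar) of
#'   [assign_genes()] data.frames, or directly of gene id vectors.
#' @param profile_id profile to compare (ignored for plain gene sets).
#' @return data.frame with `subset` (ampersand-joined cultivar names)
#'   and `count`, one row per non-empty cultivar combination; attribute
#'   `core` holds the all-cultivar intersection size.
#' @export
cross_cultivar_overlap <- function(assignments, profile_id = NULL) {
  sets <- lapply(assignments, function(a) {
    if (is.data.frame(a)) {
      if (is.null(profile_id)) stop("profile_id needed for assignment tables")
      a$gene_id[a$profile_id == profile_id]
    } else as.character(a)
  })
  k <- length(sets)
  cultivars <- names(sets)
  if (is.null(cultivars)) cultivars <- paste0("set", seq_len(k))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(r) paste(which(r), collapse = ","))
  combos <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(k, sz, function(ix) paste(ix, collapse = ","), simplify = TRUE)))
  counts <- vapply(combos, function(cb) sum(pattern == cb), 0L)
  labels <- vapply(combos, function(cb)
    paste(cultivars[as.integer(strsplit(cb, ",")[[1]])], collapse = "&"), "")
  out <- data.frame(subset = labels, count = counts, row.names = NULL)
  attr(out, "core") <- counts[[length(combos)]]
  out
}
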