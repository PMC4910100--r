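test_that("profile selection matches brute force on the 3-stage case", {
  sel <- enumerate_and_select_profiles(T = 3, c = 1, m = 2)
  expect_identical(dim(sel$templates), c(2L, 3L))
  # independent brute force: the max-distance pair over all 8 non-flat
  # candidates is a strictly decreasing / strictly increasing pair
  cand <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1))
  cand <- cand[rowSums(cand != 0) > 0, ]
  tmpl <- cbind(0, t(apply(cand, 1, cumsum)))
  best <- c(Inf, NA, NA)
  for (i in seq_len(nrow(tmpl) - 1)) for (j in (i + 1):nrow(tmpl)) {
    cc <- stats::cor(tmpl[i, ], tmpl[j, ])
    if (cc < best[1] - 1e-12) best <- c(cc, i, j)
  }
  expect_equal(best[1], -1)
  got <- sel$templates[order(sel$templates[, 2]), ]
  expect_true(all(diff(got[1, ]) < 0))   # strictly decreasing
  expect_true(all(diff(got[2, ]) > 0))   # strictly increasing
})

test_that("default selection is deterministic and contains a monotone decrease", {
  s1 <- enumerate_and_select_profiles(7, 2, 20)
  s2 <- enumerate_and_select_profiles(7, 2, 20)
  expect_identical(s1$templates, s2$templates)
  expect_identical(nrow(s1$templates), 20L)
  mono_dec <- apply(s1$templates, 1, function(t) all(diff(t) <= 0) && any(diff(t) < 0))
  expect_true(any(mono_dec))
  # no flat template, all start at 0, unit changes bounded by c
  expect_true(all(s1$templates[, 1] == 0))
  expect_true(all(abs(apply(s1$templates, 1, diff)) <= 2))
  expect_true(all(apply(s1$templates, 1, function(t) any(diff(t) != 0))))
  expect_error(enumerate_and_select_profiles(3, 1, 100), "exceeds")
})

test_that("genes are assigned to their best-correlated profile", {
  prof <- enumerate_and_select_profiles(7, 2, 20)
  dec_id <- which(apply(prof$templates, 1, function(t)
    all(diff(t) <= 0) && any(diff(t) < 0)))[1]
  series <- rbind(exact = prof$templates[3, ],
                  scaled = 5 + 2 * prof$templates[3, ],   # affine invariance
                  decreasing = seq(10, 4, length.out = 7),
                  flat = rep(2, 7))
  asg <- assign_genes(series, prof)
  expect_identical(attr(asg, "unassigned"), "flat")
  expect_identical(asg$profile_id[asg$gene_id == "exact"],
                   as.integer(rownames(prof$templates)[3]))
  expect_equal(asg$correlation[asg$gene_id == "exact"], 1)
  expect_identical(asg$profile_id[asg$gene_id == "scaled"],
                   asg$profile_id[asg$gene_id == "exact"])
  expect_identical(asg$profile_id[asg$gene_id == "decreasing"],
                   as.integer(rownames(prof$templates)[dec_id]))
})

test_that("correlation ties resolve to the lowest profile id", {
  # two mirrored templates: an orthogonal flat-ish series ties at cor 0;
  # construct an explicit tie instead via a series equidistant from two
  # profiles of a tiny set
  sel <- enumerate_and_select_profiles(T = 3, c = 1, m = 2)
  series <- matrix(c(0, 1, 0), 1, dimnames = list("tie", NULL))
  cc <- apply(sel$templates, 1, function(t) stats::cor(series[1, ], t))
  expect_equal(unname(abs(cc[1])), unname(abs(cc[2])))  # genuinely equidistant
  asg <- assign_genes(series, sel)
  expect_identical(asg$profile_id, min(as.integer(rownames(sel$templates)[
    abs(cc - max(cc)) < 1e-12])))
})

test_that("planted monotone-decrease genes are recovered at noise sd 0.25", {
  prof <- enumerate_and_select_profiles(7, 2, 20)
  dec_row <- which(apply(prof$templates, 1, function(t) all(diff(t) == -1)))
  if (!length(dec_row))
    dec_row <- which(apply(prof$templates, 1, function(t) all(diff(t) <= 0)))[1]
  dec_id <- as.integer(rownames(prof$templates)[dec_row])
  set.seed(21)
  n <- 400
  series <- matrix(rep(prof$templates[dec_row, ], each = n), n, 7) +
    matrix(rnorm(n * 7, 0, 0.25), n, 7)
  rownames(series) <- sprintf("g%03d", seq_len(n))
  asg <- assign_genes(series, prof)
  expect_gte(mean(asg$profile_id == dec_id), 0.95)
})

test_that("permutation significance flags the planted profile and spares the null", {
  prof <- enumerate_and_select_profiles(7, 2, 20)
  dec_row <- which(apply(prof$templates, 1, function(t)
    all(diff(t) <= 0) && any(diff(t) < 0)))[1]
  dec_id <- as.integer(rownames(prof$templates)[dec_row])
  set.seed(33)
  n <- 120
  planted <- matrix(rep(prof$templates[dec_row, ], each = n / 2), n / 2, 7) +
    matrix(rnorm(n / 2 * 7, 0, 0.1), n / 2, 7)
  noise <- matrix(rnorm(n / 2 * 7, 0, 0.5), n / 2, 7)
  series <- rbind(planted, noise)
  rownames(series) <- sprintf("g%03d", seq_len(n))
  sig <- cluster_significance(series, prof, n_perm = 500, seed = 7)
  expect_lt(sig$p[sig$profile_id == dec_id], 1e-5)
  expect_true(sig$significant[sig$profile_id == dec_id])
  # conservation: observed counts sum to the assigned genes
  expect_identical(sum(sig$observed), nrow(assign_genes(series, prof)))
  # expected counts are a distribution over profiles
  expect_equal(sum(sig$expected), sum(sig$observed))
  expect_warning(cluster_significance(series, prof, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("flat-null series yield no significant profile in most seeded runs", {
  prof <- enumerate_and_select_profiles(7, 2, 20)
  n_sig <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    series <- matrix(rnorm(80 * 7, 0, 0.3), 80, 7,
                     dimnames = list(sprintf("g%02d", 1:80), NULL))
    sig <- cluster_significance(series, prof, n_perm = 300, seed = s)
    sum(sig$significant)
  }, 0L)
  expect_gte(sum(n_sig == 0L), 19L)
})

test_that("exact p-value behaviour at the binomial centre", {
  # observed == expected -> upper tail includes the centre, p > 0.5
  prof <- enumerate_and_select_profiles(T = 3, c = 1, m = 2)
  set.seed(5)
  series <- matrix(rnorm(60 * 3), 60, 3,
                   dimnames = list(sprintf("g%02d", 1:60), NULL))
  sig <- cluster_significance(series, prof, n_perm = 400, seed = 2)
  near <- abs(sig$observed - sig$expected) < 2
  expect_true(all(sig$p[near] > 0.2))
  expect_true(all(sig$p > 0 & sig$p <= 1))
})

test_that("cross-cultivar overlap performs exact set algebra", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3"), C = c("g3", "g4"))
  ov <- cross_cultivar_overlap(sets)
  expect_identical(nrow(ov), 7L)                       # 2^3 - 1 regions
  get <- function(s) ov$count[ov$subset == s]
  expect_identical(get("A"), 1L)                       # g1 only
  expect_identical(get("A&B"), 1L)                     # g2
  expect_identical(get("A&B&C"), 1L)                   # g3
  expect_identical(get("C"), 1L)                       # g4
  expect_identical(get("B"), 0L)
  expect_identical(attr(ov, "core"), 1L)
  expect_identical(sum(ov$count), 4L)                  # union size

  # identical membership: everything in the core
  same <- list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y"))
  expect_identical(attr(cross_cultivar_overlap(same), "core"), 2L)
  # disjoint membership: empty core
  dis <- list(A = "x", B = "y", C = "z")
  expect_identical(attr(cross_cultivar_overlap(dis), "core"), 0L)
})

test_that("overlap accepts assignment tables filtered by profile", {
  a1 <- data.frame(gene_id = c("g1", "g2"), profile_id = c(3L, 5L))
  a2 <- data.frame(gene_id = c("g1", "g3"), profile_id = c(3L, 3L))
  ov <- cross_cultivar_overlap(list(NG = a1, SK = a2), profile_id = 3L)
  expect_identical(ov$count[ov$subset == "NG&SK"], 1L)
  expect_identical(ov$count[ov$subset == "SK"], 1L)
  expect_identical(ov$count[ov$subset == "NG"], 0L)
})
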