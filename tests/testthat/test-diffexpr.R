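test_that("benjamini_hochberg matches the closed form and the definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "within")
  set.seed(21)
  p <- runif(20)
  expect_equal(benjamini_hochberg(p), brute_bh(p), tolerance = 1e-12)
  # permutation equivariance
  perm <- sample(20)
  expect_equal(benjamini_hochberg(p[perm]), benjamini_hochberg(p)[perm])
})

planted_em <- function(n_genes = 1000L, n_planted = 10L, l2fc = 4,
                       mu = 200, disp = 0.01, n = 3L) {
  m <- matrix(rnbinom(n_genes * 2L * n, mu = mu, size = 1 / disp),
              nrow = n_genes)
  if (n_planted > 0L)
    m[seq_len(n_planted), seq_len(n)] <-
      rnbinom(n_planted * n, mu = mu * 2^l2fc, size = 1 / disp)
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%d", seq_len(2L * n))
  meta <- data.frame(sample_id = colnames(m),
                     chemical = rep(c("drugA", "vehicle"), each = n),
                     concentration = rep(c(10, 0), each = n),
                     batch = 1L, replicate = rep(seq_len(n), 2L),
                     panel = "ST",
                     is_vehicle = rep(c(FALSE, TRUE), each = n),
                     stringsAsFactors = FALSE)
  expression_matrix(m, toy_probes(rownames(m)), meta)
}

test_that("call_degs recovers planted effects and stays quiet under the null", {
  set.seed(22)
  em <- planted_em()
  tab <- call_degs(em, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                   batch_mode = "separate")
  expect_true(all(tab$is_deg[1:10]))
  expect_gt(min(tab$l2fc[1:10]), 2)
  # null: label permutation within control-like data
  set.seed(23)
  em0 <- planted_em(n_planted = 0L)
  tab0 <- call_degs(em0, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                    batch_mode = "separate")
  expect_lte(sum(tab0$is_deg), 2L)
  # alpha = 0 gives zero DEGs
  tab_a0 <- call_degs(em, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                      alpha = 0, batch_mode = "separate")
  expect_equal(sum(tab_a0$is_deg), 0L)
  expect_error(call_degs(em, "s1", sprintf("s%d", 4:6)), "2 replicates")
})

test_that("DEG count is non-decreasing in planted effect size", {
  counts <- vapply(c(0, 0.5, 1, 2, 4), function(ef) {
    set.seed(24)
    em <- planted_em(n_genes = 400L, n_planted = 20L, l2fc = ef)
    sum(call_degs(em, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                  batch_mode = "separate")$is_deg)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("batch-corrected calling absorbs an additive batch shift", {
  set.seed(25)
  n_genes <- 500L
  mu <- matrix(80, n_genes, 12)
  mu[1:10, 7:12] <- 80 * 2^3            # treatment effect
  batch_fac <- rep(rep(c(1, 2.5), each = 3), 2)
  m <- matrix(rnbinom(n_genes * 12, mu = t(t(mu) * batch_fac), size = 20),
              nrow = n_genes)
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%d", 1:12)
  meta <- data.frame(sample_id = colnames(m),
                     chemical = rep(c("vehicle", "drugA"), each = 6),
                     concentration = rep(c(0, 10), each = 6),
                     batch = rep(rep(1:2, each = 3), 2),
                     replicate = rep(1:3, 4), panel = "ST",
                     is_vehicle = rep(c(TRUE, FALSE), each = 6),
                     stringsAsFactors = FALSE)
  em <- expression_matrix(m, toy_probes(rownames(m)), meta)
  tab <- call_degs(em, sprintf("s%d", 7:12), sprintf("s%d", 1:6),
                   batch_mode = "corrected")
  expect_true(all(tab$is_deg[1:10]))
  expect_lte(sum(tab$is_deg[-(1:10)]), 5L)
})

test_that("deg_overlap reports set partition and correlation symmetrically", {
  mk <- function(genes, deg, l2fc) {
    structure(data.frame(gene = genes, l2fc = l2fc, stat = l2fc,
                         p = 0.5, adj_p = 0.5, is_deg = genes %in% deg,
                         stringsAsFactors = FALSE),
              class = c("deg_table", "data.frame"))
  }
  genes <- sprintf("g%d", 1:10)
  a <- mk(genes, genes[1:4], seq(1, 2, length.out = 10))
  # identical tables: full overlap, r = 1
  oa <- deg_overlap(a, a)
  expect_equal(oa$frac_overlap, 1)
  expect_equal(oa$pearson_r_overlap, 1)
  # disjoint: no overlap, r undefined
  b <- mk(genes, genes[5:6], seq(1, 2, length.out = 10))
  ob <- deg_overlap(a, b)
  expect_equal(ob$n_overlap, 0L)
  expect_false(ob$r_defined)
  # negated l2fc on overlap: r = -1
  cneg <- mk(genes, genes[1:4], -seq(1, 2, length.out = 10))
  expect_equal(deg_overlap(a, cneg)$pearson_r_overlap, -1)
  # symmetry
  o1 <- deg_overlap(a, b); o2 <- deg_overlap(b, a)
  expect_equal(o1$n_only_a, o2$n_only_b)
  expect_equal(o1$n_overlap, o2$n_overlap)
})

test_that("union_deg_matrix collects the union of DEGs with l2fc values", {
  mk <- function(deg, l2fc) {
    structure(data.frame(gene = sprintf("g%d", 1:5), l2fc = l2fc,
                         stat = l2fc, p = 0.5, adj_p = 0.5,
                         is_deg = sprintf("g%d", 1:5) %in% deg,
                         stringsAsFactors = FALSE),
              class = c("deg_table", "data.frame"))
  }
  tabs <- list(t1 = mk("g1", 1:5), t2 = mk("g3", 11:15))
  m <- union_deg_matrix(tabs)
  expect_equal(rownames(m), c("g1", "g3"))
  expect_equal(m["g3", "t1"], 3)        # non-significant entry still present
  expect_equal(m["g1", "t2"], 11)
  expect_warning(u0 <- union_deg_matrix(list(t1 = mk(character(0), 1:5))),
                 "no DEGs")
  expect_equal(nrow(u0), 0L)
  # union size equals brute-force set union on simulated tables
  set.seed(26)
  tabs2 <- lapply(1:4, function(i)
    mk(sample(sprintf("g%d", 1:5), sample(0:3, 1)), rnorm(5)))
  names(tabs2) <- paste0("t", 1:4)
  has_deg <- any(vapply(tabs2, function(t) any(t$is_deg), logical(1)))
  expected <- sort(unique(unlist(lapply(tabs2,
                                        function(t) t$gene[t$is_deg]))))
  if (has_deg) expect_equal(rownames(union_deg_matrix(tabs2)), expected)
})

test_that("venn_counts partitions two sets exactly", {
  expect_equal(venn_counts(c("1", "2"), c("2", "3")),
               c(only_a = 1L, shared = 1L, only_b = 1L))
  expect_equal(venn_counts(letters[1:4], letters[1:4]),
               c(only_a = 0L, shared = 4L, only_b = 0L))
  set.seed(27)
  for (i in 1:10) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    v <- venn_counts(a, b)
    expect_equal(sum(v), length(union(a, b)))
    expect_equal(v[["shared"]], length(intersect(a, b)))
  }
})

test_that("shared genes give identical raw p across nested universes", {
  # multiplicative library structure keeps size factors identical after
  # subsetting rows, so the per-gene statistic depends only on that gene
  set.seed(28)
  libs <- c(2, 3, 4, 2, 3, 4)
  scaffold <- outer(seq(20, 78, by = 2), libs)      # exact multiplicative
  interesting <- matrix(rpois(60, 50) + 1, nrow = 10)
  m <- rbind(interesting, scaffold)
  rownames(m) <- sprintf("g%02d", 1:40)
  colnames(m) <- sprintf("s%d", 1:6)
  meta <- toy_samples(colnames(m), chemical = rep(c("a", "vehicle"),
                                                  each = 3),
                      concentration = rep(c(10, 0), each = 3),
                      replicate = rep(1:3, 2),
                      is_vehicle = rep(c(FALSE, TRUE), each = 3))
  wt <- expression_matrix(m, toy_probes(rownames(m)), meta)
  # nested universe: all 10 interesting genes plus 15 scaffold rows, so the
  # median ratio (hence every size factor) is unchanged by the subsetting
  st_genes <- rownames(m)[c(1:10, 11:25)]
  st <- expression_matrix(m[st_genes, ], toy_probes(st_genes), meta)
  twt <- call_degs(wt, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                   batch_mode = "separate")
  tst <- call_degs(st, sprintf("s%d", 1:3), sprintf("s%d", 4:6),
                   batch_mode = "separate")
  # compare over the noisy genes; the exact-fit scaffold rows have zero
  # residuals and their t statistics are numerically meaningless
  shared <- sprintf("g%02d", 1:10)
  expect_equal(tst$p[match(shared, tst$gene)],
               twt$p[match(shared, twt$gene)], tolerance = 1e-12)
  # BH differs because the universes differ
  expect_false(isTRUE(all.equal(tst$adj_p,
                                twt$adj_p[match(shared, twt$gene)])))
})
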