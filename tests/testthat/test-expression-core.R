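test_that("load_counts round-trips a written matrix and validates input", {
  m <- matrix(c(1L, 0L, 5L, 2L, 3L, 4L), nrow = 3,
              dimnames = list(c("p01", "p02", "p03"), c("s01", "s02")))
  em <- toy_em(m)
  expect_equal(dim(em), c(3L, 2L))
  d <- withr::local_tempdir()
  paths <- file.path(d, c("c.tsv", "a.tsv", "m.tsv"))
  write_counts(em, paths[1], paths[2], paths[3])
  back <- suppressMessages(load_counts(paths[1], paths[2], paths[3]))
  expect_identical(back$counts, em$counts)
  expect_equal(back$samples$concentration, em$samples$concentration)

  # probe missing from annotation is a named hard error
  ann <- read.delim(paths[2])
  writeLines(capture.output(write.table(ann[-2, ], sep = "\t", quote = FALSE,
                                        row.names = FALSE)), paths[2])
  expect_error(suppressMessages(load_counts(paths[1], paths[2], paths[3])),
               "p02")
})

test_that("load_counts rejects non-integer counts", {
  d <- withr::local_tempdir()
  writeLines(c("probe_id\ts1\ts2", "p1\t1.5\t2", "p2\t1\t2"),
             file.path(d, "c.tsv"))
  writeLines(c("probe_id\tgene_symbol\tpanel", "p1\tG1\tST", "p2\tG2\tST"),
             file.path(d, "a.tsv"))
  writeLines(c(paste("sample_id", "chemical", "concentration_uM", "batch",
                     "replicate", "panel", "is_vehicle", sep = "\t"),
               "s1\tx\t1\t1\t1\tST\tFALSE", "s2\tx\t1\t1\t2\tST\tFALSE"),
             file.path(d, "m.tsv"))
  expect_error(load_counts(file.path(d, "c.tsv"), file.path(d, "a.tsv"),
                           file.path(d, "m.tsv")), "non-integer")
})

test_that("simulated matrix round-trips through TSV exactly", {
  cfg <- small_cfg(seed = 3L)
  uni <- make_universe(cfg)
  em <- simulate_counts(cfg, uni$truth, "WT")
  d <- withr::local_tempdir()
  paths <- file.path(d, c("c.tsv", "a.tsv", "m.tsv"))
  write_counts(em, paths[1], paths[2], paths[3])
  back <- suppressMessages(load_counts(paths[1], paths[2], paths[3]))
  expect_identical(back$counts, em$counts)
})

test_that("filter_low_counts uses a strict less-than rule and is idempotent", {
  # probe means 12, 9.9, 10.0 over 2 samples
  m <- matrix(c(12, 12, 9.8, 10, 10, 10), nrow = 3, byrow = TRUE)
  em <- toy_em(m)
  f <- filter_low_counts(em, min_mean = 10)
  expect_identical(rownames(f$counts), c("p01", "p03"))
  expect_identical(colnames(f$counts), colnames(em$counts))
  # min_mean 0 is the identity
  expect_identical(filter_low_counts(em, 0)$counts, em$counts)
  # idempotent
  expect_identical(filter_low_counts(f, 10)$counts, f$counts)
  # all removed: warning, not error
  expect_warning(filter_low_counts(em, 1e6), "all probes")
})

test_that("retained set under filtering matches brute-force row means", {
  set.seed(11)
  cfg <- small_cfg(seed = 11L)
  uni <- make_universe(cfg)
  em <- simulate_counts(cfg, uni$truth, "WT")
  f <- filter_low_counts(em, 10)
  keep <- apply(em$counts, 1L, function(r) sum(r) / length(r) >= 10)
  expect_identical(rownames(f$counts), rownames(em$counts)[keep])
})

test_that("aggregate_isoforms sums probes per gene and conserves totals", {
  m <- matrix(c(3, 4, 1, 0, 7, 7), nrow = 3, byrow = TRUE)
  em <- toy_em(m, genes = c("G", "G", "H"))
  agg <- aggregate_isoforms(em)
  expect_equal(unname(agg$counts["G", ]), c(4, 4))
  expect_equal(unname(agg$counts["H", ]), c(7, 7))
  expect_equal(colSums(agg$counts), colSums(em$counts))
  # unique symbols: identity up to row ordering
  em2 <- toy_em(m, genes = c("a", "b", "c"))
  agg2 <- aggregate_isoforms(em2)
  expect_equal(sort(rownames(agg2$counts)), c("a", "b", "c"))
  expect_equal(agg2$counts[order(rownames(agg2$counts)), ],
               unname(em2$counts)[order(c("a", "b", "c")), ],
               ignore_attr = TRUE)
})

test_that("column sums conserved by isoform aggregation on simulated data", {
  cfg <- small_cfg(seed = 5L)
  uni <- make_universe(cfg)
  em <- simulate_counts(cfg, uni$truth, "WT")
  # give some probes shared gene symbols
  em$probes$gene_symbol[1:100] <- rep(sprintf("GENE%02d", 1:20), each = 5)
  agg <- aggregate_isoforms(em)
  expect_identical(colSums(agg$counts), colSums(em$counts))
})

test_that("compute_l2fc_profile handles counts and intensity modes", {
  m <- matrix(c(8, 8, 2, 2,
                4, 4, 4, 4), nrow = 2, byrow = TRUE)
  em <- toy_em(m, replicate = 1:4)
  p <- compute_l2fc_profile(em, c("s01", "s02"), c("s03", "s04"),
                            pseudocount = 0)
  expect_equal(unname(p$values[1]), 2.0)
  expect_equal(unname(p$values[2]), 0.0)
  # intensity mode is a difference of means
  mi <- matrix(c(5, 3.5), nrow = 1)
  emi <- toy_em(mi, replicate = 1:2)
  pi <- compute_l2fc_profile(emi, "s01", "s02", mode = "intensity")
  expect_equal(unname(pi$values), 1.5)
  # zero pseudocount with zero control mean errors
  mz <- matrix(c(3, 0), nrow = 1)
  emz <- toy_em(mz, replicate = 1:2)
  expect_error(compute_l2fc_profile(emz, "s01", "s02", pseudocount = 0),
               "pseudocount")
})

test_that("l2fc antisymmetry: swapping groups negates the profile", {
  set.seed(2)
  m <- matrix(rpois(60, 30), nrow = 10)
  em <- toy_em(m, replicate = 1:6)
  a <- compute_l2fc_profile(em, c("s01", "s02", "s03"),
                            c("s04", "s05", "s06"), 0.5)
  b <- compute_l2fc_profile(em, c("s04", "s05", "s06"),
                            c("s01", "s02", "s03"), 0.5)
  expect_equal(a$values, -b$values)
})

test_that("collapse_probes_to_genes applies the requested rule", {
  ann <- toy_probes(c("p1", "p2", "p3"), c("G", "G", "H"))
  pr <- l2fc_profile("t", c(p1 = 1.0, p2 = 3.0, p3 = -0.5))
  expect_equal(unname(collapse_probes_to_genes(pr, ann, "mean")$values["G"]),
               2.0)
  pr2 <- l2fc_profile("t", c(p1 = 1.0, p2 = -3.0, p3 = -0.5))
  expect_equal(unname(
    collapse_probes_to_genes(pr2, ann, "max_abs")$values["G"]), -3.0)
  # single-probe genes unchanged
  expect_equal(unname(collapse_probes_to_genes(pr, ann, "mean")$values["H"]),
               -0.5)
  expect_error(collapse_probes_to_genes(pr, ann, "median"))
  # mean rule commutes with a global sign flip
  neg <- l2fc_profile("t", -pr$values)
  expect_equal(collapse_probes_to_genes(neg, ann, "mean")$values,
               -collapse_probes_to_genes(pr, ann, "mean")$values)
})

test_that("relative_viability is a percentage of vehicle mean", {
  expect_equal(relative_viability(c(10, 12), c(10, 12)), 100)
  expect_equal(relative_viability(c(5, 6), c(10, 12)), 50)
  expect_error(relative_viability(c(5), c(0, 0)), "positive")
})

test_that("treatment ids round-trip through the parser", {
  id <- make_treatment_id("Valproic acid", 400, study = "e-mtab-797")
  expect_identical(id, "valproic-acid-400.00uM-24h-rn-hep-e-mtab-797")
  p <- parse_treatment_id(id)
  expect_identical(p$chemical, "valproic-acid")
  expect_equal(p$concentration, 400)
  expect_identical(p$study, "e-mtab-797")
  # hyphen- and digit-bearing chemical names survive the right split
  p2 <- parse_treatment_id(make_treatment_id("wy-14643", 8, study = "x"))
  expect_identical(p2$chemical, "wy-14643")
  expect_equal(p2$concentration, 8)
})

test_that("profile database round-trips through TSV", {
  genes <- sprintf("g%02d", 1:20)
  profs <- lapply(1:3, function(i) {
    id <- make_treatment_id(paste0("chem", i), 10, study = "ref")
    l2fc_profile(id, stats::setNames(round(stats::rnorm(20), 6), genes))
  })
  ids <- vapply(profs, function(p) p$treatment_id, character(1))
  db <- profile_database(profs, stats::setNames(paste0("chem", 1:3), ids))
  d <- withr::local_tempdir()
  write_profile_db(db, file.path(d, "db.tsv"))
  back <- read_profile_db(file.path(d, "db.tsv"))
  expect_identical(names(back$profiles), ids)
  for (id in ids)
    expect_equal(back$profiles[[id]]$values[genes],
                 db$profiles[[id]]$values[genes])
  expect_identical(unname(back$chemical_of), paste0("chem", 1:3))
})
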