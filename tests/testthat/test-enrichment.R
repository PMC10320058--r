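test_that("hypergeometric upper tail matches enumeration on the worked case", {
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), oracle_hyper(10, 5, 4, 4),
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(20, 7, 6, 0), 1.0)   # P(X >= 0) = 1
  expect_equal(hypergeom_pvalue(8, 8, 3, 3), 1.0)    # fully marked background
})

test_that("hypergeometric p is monotone in k and validates its counts", {
  p <- hypergeom_pvalue(30, 10, 8, 0:8)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeom_pvalue(10, 11, 4, 1), "'K'")
  expect_error(hypergeom_pvalue(10, 5, 11, 1), "'n'")
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "'k'")
  expect_error(hypergeom_pvalue(-1, 0, 0, 0), "'N'")
})

test_that("adjustment procedures reproduce hand-derived values", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)  # m = 1 identity
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p, "bh"), rep(0.04, 4), tolerance = 1e-12)
  expect_equal(adjust_pvalues(p, "by"), rep(0.04 * 25 / 12, 4),
               tolerance = 1e-12)
  expect_equal(adjust_pvalues(p, "bonferroni"), pmin(1, p * 4))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
  expect_error(adjust_pvalues(numeric(), "bh"), "length")
})

test_that("adjusted values dominate raw values and preserve input order", {
  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    for (m in c("bonferroni", "bh", "by")) {
      adj <- adjust_pvalues(p, m)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      # order-equivariance: adjusting a permutation permutes the adjustment
      o <- sample(seq_along(p))
      expect_equal(adjust_pvalues(p[o], m), adj[o], tolerance = 1e-12)
    }
    expect_true(all(adjust_pvalues(p, "by") >= adjust_pvalues(p, "bh") - 1e-15))
  }
})

test_that("run_enrichment reports the worked single-set configuration", {
  res <- run_enrichment(paste0("g", 1:4), demo_collection())
  row <- res$table[res$table$set_id == "S1", ]
  expect_equal(row[, c("N", "K", "n", "k")],
               data.frame(N = 10L, K = 5L, n = 4L, k = 4L),
               ignore_attr = TRUE)
  expect_equal(row$p_raw, 5 / 210, tolerance = 1e-12)
  expect_equal(row$fold_enrichment, 2.0)
  expect_equal(row$overlap_members, "g1|g2|g3|g4")
  # family of two tests: bonferroni doubles, and bh here equals it
  expect_equal(row$p_bonferroni, 2 * 5 / 210, tolerance = 1e-12)
  expect_equal(res$n_tested, 2L)
})

test_that("an input outside every set yields k = 0 rows and full uncoverage", {
  coll <- demo_collection()
  # an input entirely outside the annotated universe cannot be tested at all
  expect_error(
    run_enrichment(c("g9", "g10"),
                   gene_set_collection(list(S1 = paste0("g", 1:5))),
                   background = paste0("g", 1:10)),
    "no input genes remain")

  res2 <- run_enrichment(c("zz1", "g6"), coll)
  s1 <- res2$table[res2$table$set_id == "S1", ]
  expect_equal(s1$k, 0L)
  expect_equal(s1$p_raw, 1.0)
  expect_equal(res2$uncovered$fraction, 0)  # g6 is in S2

  expect_error(run_enrichment(c("zz1", "zz2"), coll), "no input genes")
})

test_that("uncovered genes are input genes outside every set of the collection", {
  coll <- gene_set_collection(list(S1 = c("g1", "g2"), S2 = c("g2", "g3")))
  res <- run_enrichment(c("g1", "g3"), coll)
  expect_length(res$uncovered$genes, 0)
  # a user background wider than the universe is clipped and reported
  bg <- resolve_background(coll, c("g1", "g2", "g3", "outside"))
  expect_equal(bg$n_discarded, 1L)
  expect_equal(bg$genes, c("g1", "g2", "g3"))
})

test_that("cutoffs filter the chosen column after adjustment", {
  coll <- demo_collection()
  res <- run_enrichment(paste0("g", 1:4), coll, p_cutoff = 0.05,
                        cutoff_on = "raw")
  expect_equal(res$table$set_id, "S1")
  # bonferroni with a single tested set degenerates to the raw cutoff
  one <- gene_set_collection(list(S1 = paste0("g", 1:5)))
  a <- run_enrichment(paste0("g", 1:4), one, p_cutoff = 0.05,
                      cutoff_on = "bonferroni")
  b <- run_enrichment(paste0("g", 1:4), one, p_cutoff = 0.05,
                      cutoff_on = "raw")
  expect_identical(a$table, b$table)
  # a cutoff nothing survives leaves an empty table but keeps metadata
  none <- run_enrichment(paste0("g", 1:4), coll, p_cutoff = 1e-6,
                         cutoff_on = "raw")
  expect_equal(nrow(none$table), 0)
  expect_equal(none$n_tested, 2L)
})

test_that("results are invariant to input order and duplicate entries", {
  coll <- demo_collection()
  base <- run_enrichment(c("g1", "g2", "g3", "g4"), coll)
  shuf <- run_enrichment(c("g4", "g2", "g1", "g3"), coll)
  dupd <- run_enrichment(c("g1", "g1", "g2", "g3", "g4", "g4"), coll)
  expect_identical(base$table, shuf$table)
  expect_identical(base$table, dupd$table)
})

test_that("shrinking the background never changes the overlap count", {
  set.seed(13)
  genes <- paste0("g", 1:40)
  coll <- gene_set_collection(list(S1 = sample(genes, 12),
                                   S2 = sample(genes, 8),
                                   S3 = sample(genes, 25)))
  input <- sample(coll$universe, 10)
  full <- run_enrichment(input, coll)
  shrunk_bg <- union(input, coll$sets$S1)
  shrunk <- run_enrichment(input, coll, background = shrunk_bg)
  for (s in intersect(full$table$set_id, shrunk$table$set_id)) {
    if (s == "S1") {
      expect_equal(full$table$k[full$table$set_id == "S1"],
                   shrunk$table$k[shrunk$table$set_id == "S1"])
    }
  }
})

test_that("min_set_size restricts the multiple-testing family", {
  coll <- gene_set_collection(list(BIG = paste0("g", 1:8),
                                   TINY = "g9",
                                   MID = paste0("g", 5:10)))
  res <- run_enrichment(c("g1", "g2"), coll, min_set_size = 2)
  expect_setequal(res$table$set_id, c("BIG", "MID"))
  # adjustments use the tested family size (2), not the collection size (3)
  expect_equal(res$table$p_bonferroni,
               pmin(1, res$table$p_raw * 2), tolerance = 1e-12)
})

test_that("result TSV round-trips through the writer", {
  res <- run_enrichment(paste0("g", 1:4), demo_collection())
  out <- tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, out)
  tab <- read.delim(out, stringsAsFactors = FALSE)
  expect_equal(tab$set_id, res$table$set_id)
  expect_equal(tab$p_raw, res$table$p_raw, tolerance = 1e-9)
  expect_true(file.exists(paste0(out, ".uncovered.tsv")))
})
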