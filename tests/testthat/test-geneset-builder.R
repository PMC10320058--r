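test_that("GAF reader handles comments, qualifiers and empty files", {
  path <- write_gaf_file(c(gaf_row("g1", "T:1", "IDA"),
                           gaf_row("g2", "T:2", "IEA",
                                   qualifier = "NOT|involved_in")))
  rec <- read_gaf(path)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$negated, c(FALSE, TRUE))
  expect_equal(rec$aspect, c("P", "P"))

  empty <- write_gaf_file(character())
  expect_equal(nrow(read_gaf(empty)), 0)

  bad <- tempfile()
  writeLines(c("!gaf-version: 2.2", "only\tthree\tcolumns"), bad)
  expect_error(read_gaf(bad), "line 2")
})

test_that("evidence filtering drops pairs only when every code is excluded", {
  rows <- c(gaf_row("g1", "T:1", "IEA"),        # computational only
            gaf_row("g2", "T:1", "IEA"),
            gaf_row("g2", "T:1", "IDA"),        # rescued by direct assay
            gaf_row("g3", "T:1", "HDA"),        # HTP only
            gaf_row("g4", "T:1", "IMP", qualifier = "NOT"))
  rec <- read_gaf(write_gaf_file(rows))

  all_mode <- filter_by_evidence(rec, "all")
  expect_false("g4" %in% all_mode$gene_id)  # NOT removed even in mode=all
  expect_identical(filter_by_evidence(all_mode, "all"), all_mode)

  exp_only <- filter_by_evidence(rec, "experimental_only")
  expect_false("g1" %in% exp_only$gene_id)
  expect_true("g2" %in% exp_only$gene_id)
  expect_equal(sum(exp_only$gene_id == "g2"), 2)  # pairs keep all their rows
  expect_true("g3" %in% exp_only$gene_id)         # HDA is not computational

  no_htp <- filter_by_evidence(rec, "exclude_htp_only")
  expect_false("g3" %in% no_htp$gene_id)
  expect_true(all(c("g1", "g2") %in% no_htp$gene_id))

  expect_error(filter_by_evidence(rec, "bogus"))
})

test_that("the two evidence code groups are the curated lists and disjoint", {
  expect_setequal(evidence_code_groups$computational,
                  c("IEA", "IBA", "IBD", "IKR", "IRD", "ISS", "ISO", "ISA",
                    "ISM", "IGC", "RCA"))
  expect_setequal(evidence_code_groups$htp,
                  c("HTP", "HDA", "HMP", "HGI", "HEP"))
  expect_length(intersect(evidence_code_groups$computational,
                          evidence_code_groups$htp), 0)
})

test_that("GO set construction propagates annotations up a chain", {
  ont <- read_obo(write_obo_file(list(A = character(), B = "A", C = "B")))
  rec <- read_gaf(write_gaf_file(gaf_row("g1", "C", "IDA")))

  direct <- build_go_sets(rec, ont, propagate = FALSE)
  expect_equal(names(direct$sets), "C")
  expect_equal(direct$sets$C, "g1")

  prop <- build_go_sets(rec, ont, propagate = TRUE)
  expect_equal(sort(names(prop$sets)), c("A", "B", "C"))
  expect_true(all(vapply(prop$sets, identical, logical(1), "g1")))
})

test_that("propagated sets union sibling annotations and slims re-express them", {
  ont <- read_obo(write_obo_file(list(A = character(), B = "A", C = "A")))
  rec <- read_gaf(write_gaf_file(c(gaf_row("g1", "B", "IDA"),
                                   gaf_row("g2", "C", "IMP"))))
  prop <- build_go_sets(rec, ont, propagate = TRUE)
  expect_setequal(prop$sets$A, c("g1", "g2"))

  slimmed <- build_go_sets(rec, ont, propagate = TRUE, slim = "A")
  expect_equal(names(slimmed$sets), "A")
  expect_setequal(slimmed$sets$A, c("g1", "g2"))

  slim_direct <- build_go_sets(rec, ont, propagate = FALSE, slim = "A")
  expect_setequal(slim_direct$sets$A, c("g1", "g2"))
})

test_that("records with unknown or obsolete terms are skipped with a warning", {
  ont <- read_obo(write_obo_file(list(A = character(), B = "A"),
                                 obsolete = "B"))
  rec <- read_gaf(write_gaf_file(c(gaf_row("g1", "A", "IDA"),
                                   gaf_row("g2", "GHOST", "IDA"),
                                   gaf_row("g3", "B", "IDA"))))
  expect_warning(coll <- build_go_sets(rec, ont), "skipped")
  expect_equal(attr(coll, "skipped"), 2L)
  expect_equal(names(coll$sets), "A")
})

test_that("GMT round trip preserves sets and rejects malformed input", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc one\tg1\tg2\tg2", "S2\tdesc two\tg3"), gmt)
  coll <- read_gmt(gmt)
  expect_equal(coll$sets$S1, c("g1", "g2"))  # duplicate member stored once
  expect_equal(coll$universe, c("g1", "g2", "g3"))

  out <- tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  back <- read_gmt(out)
  expect_identical(back$sets, coll$sets)
  expect_true(file.exists(paste0(out, ".json")))

  dup <- tempfile(); writeLines(c("S1\td\tg1", "S1\td\tg2"), dup)
  expect_error(read_gmt(dup), "duplicate")
  short <- tempfile(); writeLines("S1\tdesc", short)
  expect_error(read_gmt(short), "fewer than 3")
})

test_that("collection invariants hold: unique sorted members, exact universe", {
  coll <- gene_set_collection(list(S1 = c("b", "a", "a"), S2 = c("c"),
                                   EMPTY = character()))
  expect_equal(names(coll$sets), c("S1", "S2"))  # empty set dropped
  expect_equal(coll$sets$S1, c("a", "b"))
  expect_equal(coll$universe, sort(unique(unlist(coll$sets))))
  expect_error(gene_set_collection(list(S1 = "a", S1 = "b")), "duplicate")
})

test_that("phenotype sets apply the single-allele rule and propagate", {
  ont <- read_obo(write_obo_file(list(P0 = character(), P1 = "P0")))
  tsv <- tempfile()
  writeLines(c("genotype\tgene_ids\tallele_class\tphenotype_term_id",
               "gA[1]\tgA\tclassical\tP1",
               "gB[ins]\tgB\tinsertional\tP1",
               "gC[1] gD[1]\tgC|gD\tclassical\tP1",   # two genes implicated
               "gE[UAS]\tgE\tother\tP1"), tsv)       # transgenic construct
  rec <- read_genotype_phenotype(tsv)
  coll <- build_phenotype_sets(rec, ont)
  expect_setequal(coll$sets$P1, c("gA", "gB"))
  expect_setequal(coll$sets$P0, c("gA", "gB"))  # flattened to the parent
  expect_equal(attr(coll, "n_excluded"), 2L)

  flat <- build_phenotype_sets(rec)  # no ontology: no propagation
  expect_equal(names(flat$sets), "P1")
})

test_that("direct membership is a subset of propagated membership on random DAGs", {
  set.seed(42)
  for (rep in 1:10) {
    parents <- random_dag_parents(sample(5:25, 1))
    ont <- read_obo(write_obo_file(parents))
    ids <- ont$terms$term_id
    genes <- paste0("g", 1:20)
    rows <- vapply(1:30, function(i)
      gaf_row(sample(genes, 1), sample(ids, 1), "IDA"), character(1))
    rec <- read_gaf(write_gaf_file(rows))
    d <- build_go_sets(rec, ont, propagate = FALSE)
    p <- build_go_sets(rec, ont, propagate = TRUE)
    for (s in names(d$sets)) {
      expect_true(all(d$sets[[s]] %in% p$sets[[s]]))
    }
    expect_equal(p$universe, d$universe)
  }
})
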