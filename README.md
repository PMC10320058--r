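# gsora — configurable gene set over-representation analysis

`gsora` asks the routine first question about any experimental gene list —
screen hits, differentially expressed genes, proteomics candidates — *what
do these genes have in common?* It answers it with over-representation
analysis against gene-set collections the user builds and filters
themselves, instead of a fixed bundled knowledgebase, and it is aimed at
people analysing model-organism data where the choice of annotation subset
(evidence codes, propagation, phenotype curation rules, tissue expression)
materially changes the answer.

## The statistic

For a background universe of `N` genes, a gene set covering `K` of them,
and an input list of `n` genes overlapping the set in `k`, the null
distribution of the overlap is hypergeometric and the reported p-value is
the one-sided upper tail:

    P(X >= k) = sum_{j=k}^{min(n,K)} C(K,j) C(N-K, n-j) / C(N,n)

computed via the survival function for numerical stability. Fold
enrichment is `(k/n) / (K/N)`. Each run adjusts the p-values over the
family of sets tested in that call by Bonferroni, Benjamini–Hochberg and
Benjamini–Yekutieli (`stats::p.adjust`); all columns are reported and
cut-offs can be placed on any of them.

Around that core, the package builds the collections themselves:

* **GO-style sets from OBO + GAF** — direct or propagated up the ontology
  DAG (`is_a`/`part_of`), with pair-level evidence-code filters
  (experimental-only; excluding annotations supported only by
  high-throughput codes) and GO-slim re-expression;
* **pathways/complexes/groups from GMT** files;
* **phenotype sets** from genotype–phenotype tables under the
  single-allele rule (exactly one gene perturbed via a classical or
  insertional allele);
* **tissue-preferential expression sets** from an RPKM matrix (assigned
  when a gene's in-group mean is ≥ 10 RPKM and ≥ 3-fold every other
  group's mean);
* **identifier mapping** with an exact-first, case-fallback lookup that
  reports unmapped, ambiguous and duplicate inputs instead of dropping
  them;
* **multi-list comparison matrices** and **bipartite gene ↔ gene-set
  graphs** (TSV/GraphML/JSON plot data, PNG rendering);
* a deterministic **synthetic fixture generator** with planted ground
  truth, used throughout the test suite.

## Worked example

Four input genes all fall inside a five-member set within a ten-gene
universe:

```r
library(gsora)
coll <- gene_set_collection(list(S1 = paste0("g", 1:5),
                                 S2 = paste0("g", 6:10)),
                            collection_id = "demo")
res <- run_enrichment(paste0("g", 1:4), coll)
res
#> ora_result 'list': 4 genes vs 2 sets (background 10, collection_universe)
#> uncovered input genes: 0 (0.0%)
#>  set_id K k      p_raw       p_bh fold_enrichment
#>      S1 5 4 0.02380952 0.04761905               2
#>      S2 5 0 1.00000000 1.00000000               0
```

`p_raw = 0.0238` is exactly `5/210`: of the `C(10,4) = 210` equally likely
draws of 4 genes from 10, only 5 contain at least four S1 members. The
overlap is twice its expectation (`fold_enrichment = 2`), and BH adjusts
over the family of 2 tested sets. S2, with zero overlap, is still reported
(p = 1) so multi-list matrices stay dense.

The same run over generated files, end to end:

```r
fx <- generate_fixture(fixture_spec(seed = 1), "demo-fx")
pw <- read_gmt("demo-fx/pathways.gmt")
ml <- map_gene_list(read_gene_list("demo-fx/list_strong.txt"),
                    read_id_map("demo-fx/id_map.tsv"), label = "strong")
run_enrichment(ml, pw, p_cutoff = 0.05, cutoff_on = "bh")
#> ora_result 'strong': 8 genes vs 8 sets (background 47, collection_universe)
#> cutoff: bh <= 0.05 -> 1 set(s) pass
#> uncovered input genes: 0 (0.0%)
#>  set_id  K k       p_raw         p_bh fold_enrichment
#>    PW01 12 8 1.57414e-06 1.259312e-05        3.916667
```

The list was planted to overlap pathway PW01, and PW01 is the one set
passing the BH 0.05 cut-off.

A command-line interface covering the same pipeline
(`map-ids`, `build-sets`, `tissue-sets`, `enrich`, `enrich-multi`,
`graph-export`, `plot`, `fixtures`) ships as a thin launcher:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "gsora.R", package = "gsora"))')" --help
```

See `vignettes/gene-set-enrichment.Rmd` for the model, the conventions
(background and multiple-testing family), the filter semantics, and known
limitations.

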