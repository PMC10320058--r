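---
title: "Configurable gene-set over-representation analysis with gsora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configurable gene-set over-representation analysis with gsora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsora)
```

## The problem

Given a list of genes that came out of an experiment — screen hits,
differentially expressed genes, proteomics candidates — the standard first
question is *what do these genes have in common?* Over-representation
analysis (ORA) answers it by comparing the list against predefined gene
sets: groups of genes sharing a Gene Ontology (GO) term, a pathway, a
protein complex, a mutant phenotype, or a tissue in which they are
preferentially expressed. `gsora` covers the whole workflow: building those
collections from standard annotation formats with configurable filters,
synchronising gene identifiers, running the test for one or many lists, and
exporting comparison matrices and gene/gene-set graphs.

## The statistical model

For one gene set, membership of the input list in the set is modelled as
sampling without replacement. With a background universe of $N$ genes, of
which $K$ belong to the set, and an input list of $n$ genes, the overlap
count $X$ under the null hypothesis of no association is hypergeometric,
and the reported p-value is the one-sided upper tail

$$
P(X \ge k) \;=\; \sum_{j=k}^{\min(n,K)}
\frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},
$$

computed through the distribution's survival function
(`stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)`), which is stable
far into the tail. Only over-representation is tested; depletion is out of
scope. Alongside the p-value, fold enrichment $(k/n)/(K/N)$ expresses the
overlap relative to its expectation.

Because a collection holds many sets, every run adjusts the p-values three
ways over the family of sets actually tested in that call: Bonferroni
($\min(1, m\,p)$), Benjamini–Hochberg step-up, and Benjamini–Yekutieli (BH
scaled by $c(m) = \sum_{i=1}^{m} 1/i$), all via `stats::p.adjust`. Raw and
all three adjusted columns are always reported; cut-offs can be placed on
any of them. Note that BY is not bounded by Bonferroni: for
$p = (0.01, 0.02, 0.03, 0.04)$, BY gives $0.0833$ for every element while
Bonferroni gives $0.04$ for the first — the guaranteed orderings are
raw $\le$ BH $\le$ BY and raw $\le$ Bonferroni.

### The multiple-testing family and the background

Two conventions had to be fixed because common practice varies:

* **Family.** The adjustment family is the sets tested within one
  (list × collection) call, after the `min_set_size` filter. This makes
  every adjusted value reproducible from the call's own inputs. In
  multi-list runs the family stays per list: pooling would make one list's
  adjusted values depend on how many other lists were uploaded with it.
* **Background.** By default the background is the collection universe —
  the union of all member genes, i.e. every gene annotated in the selected
  category. This is the conservative standard: genes that no set could ever
  contain do not inflate significance. A user-supplied background (e.g. the
  genes actually present in a kinase sub-library) is intersected with the
  universe before testing and the discarded count is reported, so $K \le N$
  always holds.

Zero-overlap sets are reported with $p = 1$ rather than dropped, so that
multi-list comparison matrices are dense; `min_set_size` defaults to 1 (no
filtering). Results are ordered by raw p-value with the set id as a
deterministic tie-break, making all outputs byte-stable.

## Building collections

### Ontology propagation ("flattening")

GO-style annotation is hierarchical: a gene annotated to a specific term is
implicitly annotated to every ancestor of that term. `read_obo()` parses
the ontology into a DAG — following `is_a` and `part_of` links only, with
`part_of` confined to a single namespace so propagation never crosses
aspects — and `build_go_sets(..., propagate = TRUE)` extends each gene's
membership to the full ancestor closure. The regulates-family links are
deliberately not traversed: propagating across them mixes regulators into
process sets and is not standard annotation semantics. Direct
(unpropagated) collections can be built too; they are mainly useful for
inspecting annotation depth, while the propagated form is the one to use
for enrichment. Obsolete terms are dropped from propagation, alternate ids
resolve silently to their primary term, and a record whose term is unknown
is skipped with a warning and counted rather than failing the build —
annotation files and ontology releases routinely drift apart.

GO slim subsets (broad, cut-down views of the ontology) use
propagate-then-intersect semantics: a term maps to *every* slim term among
itself and its ancestors, not just the nearest one, which is what treating
the slim as an annotation set requires.

### Evidence-code filters

Each GO annotation carries an evidence code. Two curated code groups drive
the filters: the computational codes (IEA, IBA, IBD, IKR, IRD, ISS, ISO,
ISA, ISM, IGC, RCA) and the high-throughput codes (HTP, HDA, HMP, HGI,
HEP). Filtering is at the (gene, term) pair level with "only supported by"
semantics: a pair is removed only when *every* record supporting it carries
an excluded code, so one direct assay rescues a pair that also has an IEA
record. `NOT`-qualified records never contribute to membership under any
mode.

### Phenotype sets: the single-allele rule

Phenotypes are curated against genotypes, and a genotype may perturb
several genes — in which case the phenotype cannot be attributed to any one
of them. `build_phenotype_sets()` therefore uses only records where exactly
one gene is implicated through a single classical or insertional allele;
transgenic constructs and multi-gene genotypes are counted and set aside.
Which allele classes qualify is externalised to the `allele_class` column
of the input table, because that judgment belongs to whoever produced the
genotype data. When a phenotype-vocabulary ontology is supplied, membership
propagates up it exactly as for GO.

### Tissue-preferential expression

From a gene × sample RPKM matrix and a sample → tissue-group map, the
classifier first averages RPKM per gene per group (unweighted across
samples), then assigns gene $g$ to group $G$ iff

* mean RPKM of $g$ in $G$ is at least `min_rpkm` (default 10), and
* that mean is at least `fold_threshold` (default 3) times the mean in
  *every* other group.

Both comparisons are inclusive (`>=`), reading "3-fold or higher" and the
RPKM-10 exclusion literally. The floor is applied to the candidate group's
mean — the wording "average RPKM lower than 10" is ambiguous between the
candidate group, the maximum group, and the global mean, and the per-group
reading keeps the rule local; this is a documented choice. A zero mean in
another group satisfies the fold condition in the limit, so no special
case for division by zero exists. With any `fold_threshold > 1` the rule
can hold in at most one group (two groups would need each mean to be 3×
the other), so the resulting tissue sets are disjoint by construction.

## Identifier mapping

Gene lists arrive with symbols, Entrez ids, database ids from different
releases, and typos. `map_gene_list()` partitions every input into exactly
one of four bins — mapped, unmapped, ambiguous, duplicate — so that
`|input| = mapped + unmapped + ambiguous + duplicates` always holds and
nothing disappears silently. Exact matches win; a case-insensitive fallback
is tried only when the exact lookup fails, and it unions the candidates of
every alias sharing the folded spelling. That makes a folded hit that
collides with a distinct exact alias ambiguous rather than silently
resolved — necessary for *Drosophila*, where case distinguishes genes
(`dl`, *dorsal*, vs `Dl`, *Delta*). Ambiguous aliases are excluded from
the mapped set by default, since adding uncertain members inflates the
overlap count and biases enrichment upward.

## Comparison matrices and graphs

`run_enrichment_multi()` analyses several lists against one collection and
assembles a set × list matrix over the union of sets passing the cut-off in
at least one list. Cells are copied verbatim from the per-list results —
never recomputed — and pairs that passed nowhere carry the $p = 1$ marker
so the matrix has no holes. `build_graph()` exports the bipartite
gene ↔ gene-set view of selected results: set nodes connect to the input
genes they contain, a gene in several sets gets one edge per set, and sets
with empty overlap are omitted so no orphan nodes appear. Plot-data
documents (bar heights $-\log_{10} p_{adj}$, heatmap matrices, dot sizes
$k$) serialize with fixed key order; p-values below $10^{-300}$ are clamped
so every plot coordinate stays finite.

## The synthetic fixture generator

`generate_fixture()` produces a desk-scale miniature of the real inputs:
a random layered DAG written as OBO (acyclic by construction, edges only
point toward earlier layers), a 17-column GAF whose evidence codes are
drawn from a configurable experimental/computational/HTP mix, pathway-style
GMT sets, an RPKM matrix with genes planted to satisfy the tissue rule in
exactly one group (in-group means of 40–60 against a baseline under 2, so
recovery is unambiguous), a genotype–phenotype table with known qualifying
and non-qualifying records, an identifier table including reference symbol
rows, and gene lists with planted overlap against designated pathway sets.
Ground truth for every planted fact goes to `truth.json` and SHA-256
checksums to `manifest.json`; one explicitly seeded RNG stream drives all
sampling, so a seed reproduces every file byte for byte, and the caller's
RNG state is restored afterwards.

Defaults are 100 genes, 40 terms, 4 tissue groups × 3 samples, 5 planted
tissue-specific genes, an evidence mix of 60/30/10
experimental/computational/HTP, and two planted lists (overlap fractions
1.0 and 0.3). These sizes keep every property test exhaustive-checkable in
seconds while still exercising all code paths; they are miniatures, and
passing on them shows the machinery is correct, not that any biological
conclusion transfers. What the generator does *not* emulate: correlated
annotations (real GO terms overlap heavily), set-size distributions with
heavy tails, expression-level noise structure (library-size effects,
zero inflation), and curation artifacts such as retracted or duplicated
records. Results on real data therefore still depend on the quality of
the supplied annotation files, and the conservative defaults (annotated
universe as background, ambiguous ids excluded) matter more there than in
the fixtures.

## Numerical and edge-case choices

* p-values come from the survival function, never `1 - cdf`, avoiding
  cancellation in the far tail.
* Ranking ties are broken lexicographically by set id; all file exports
  sort their keys — identical inputs give byte-identical outputs.
* Empty gene sets are dropped at collection construction: they cannot be
  enriched and would distort the multiple-testing family size.
* An input with no gene in the background is an error carrying diagnostic
  counts, not an empty result.
* Test oracles are independent of the implementation path: exhaustive draw
  enumeration for the hypergeometric tail, a hand-written step-up reference
  for the adjustments, and igraph reachability for ancestor closures.

## Worked example

```{r worked}
coll <- gene_set_collection(list(S1 = paste0("g", 1:5),
                                 S2 = paste0("g", 6:10)),
                            collection_id = "demo")
res <- run_enrichment(paste0("g", 1:4), coll)
res$table[, c("set_id", "N", "K", "n", "k", "p_raw", "p_bh",
              "fold_enrichment")]
```

Four input genes all fall inside the five-member set S1 within a ten-gene
universe; the upper-tail probability is $5/210 \approx 0.0238$ (five of the
$\binom{10}{4} = 210$ possible draws contain at least four S1 members), and
the overlap is twice its expectation.

## Known limitations

* ORA treats genes as exchangeable: no gene-level weights, scores or
  rank-based statistics (use a rank-based GSEA for scored lists).
* Depletion is not tested.
* Ontology handling targets OBO flat files; OWL and reasoner-grade
  inference are out of scope.
* Identifier mapping is table-driven; no remote lookups and no
  cross-species orthology.
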