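#' Specification for a synthetic desk-scale fixture
#'
#' Describes a self-contained miniature of the real inputs the pipeline
#' consumes: a random ontology DAG, a GAF annotation file with a controlled
#' mix of evidence codes, pathway-style GMT sets, an RPKM matrix with
#' planted tissue-preferential genes, a genotype-phenotype table with known
#' single-allele records, an identifier-mapping table, and input gene lists
#' with planted overlap against chosen sets. The same seed always yields
#' byte-identical files.
#'
#' @param seed RNG seed (single pseudo-random stream for the whole fixture).
#' @param n_genes Number of genes in the synthetic genome.
#' @param n_terms Number of ontology terms.
#' @param dag_depth Number of rank levels in the random DAG.
#' @param n_tissue_groups Number of tissue groups in the expression matrix.
#' @param n_samples_per_group Samples per tissue group.
#' @param n_planted_specific Genes planted to satisfy the 3-fold / RPKM>=10
#'   preferential-expression rule in exactly one group.
#' @param evidence_mix Named proportions over
#'   `c(experimental, computational, htp)` governing the GAF evidence codes.
#' @param annotations_per_gene Mean number of GAF records per gene.
#' @param n_pathways Number of GMT pathway sets.
#' @param planted_enrichment Named numeric vector: for each generated gene
#'   list, the fraction of a designated pathway set its members are drawn
#'   from (the rest are random background genes). Defaults to one strongly
#'   and one weakly overlapping list.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_genes = 100L,
                         n_terms = 40L,
                         dag_depth = 4L,
                         n_tissue_groups = 4L,
                         n_samples_per_group = 3L,
                         n_planted_specific = 5L,
                         evidence_mix = c(experimental = 0.6,
                                          computational = 0.3, htp = 0.1),
                         annotations_per_gene = 2,
                         n_pathways = 8L,
                         planted_enrichment = c(strong = 1.0, weak = 0.3)) {
  stopifnot(n_genes > 0, n_terms > 1, dag_depth > 0, n_tissue_groups > 1,
            n_samples_per_group > 0, n_planted_specific >= 0,
            n_pathways > 0, all(evidence_mix >= 0))
  if (abs(sum(evidence_mix) - 1) > 1e-9) {
    stop("evidence_mix proportions must sum to 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic fixture on disk
#'
#' Writes all files described by the [fixture_spec()] into `out_dir`,
#' together with `truth.json` (every planted fact: evidence-filter survivor
#' counts, propagated set sizes, planted tissue genes, planted list
#' overlaps) and `manifest.json` (SHA-256 of every file). Re-running with
#' the same spec reproduces every file byte for byte; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named paths), `manifest` and
#'   `truth`.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  genes <- sprintf("GN%04d", seq_len(spec$n_genes))
  terms <- sprintf("TT:%04d", seq_len(spec$n_terms))

  ## --- ontology: random DAG with rank levels (edges point to lower ranks) --
  level <- sort(c(1L, 1L + (seq_len(spec$n_terms - 1L) %%
                              spec$dag_depth)))  # level 1 = root layer
  parents <- stats::setNames(vector("list", spec$n_terms), terms)
  for (i in seq_len(spec$n_terms)) {
    if (level[i] == 1L) next
    pool <- terms[level < level[i]]
    k <- min(length(pool), 1L + stats::rbinom(1, 1, 0.4))
    parents[[terms[i]]] <- sort(sample(pool, k))
  }
  alt_src <- terms[spec$n_terms]  # give the last term an alternate id
  obo_lines <- c("format-version: 1.2", "ontology: synthetic-demo")
  for (i in seq_len(spec$n_terms)) {
    t <- terms[i]
    obo_lines <- c(obo_lines, "", "[Term]", paste0("id: ", t),
                   paste0("name: synthetic term ", i),
                   "namespace: synthetic_process",
                   if (t == alt_src) "alt_id: TT:ALT1",
                   if (length(parents[[t]])) paste0("is_a: ", parents[[t]]))
  }
  obo_path <- file.path(out_dir, "ontology.obo")
  writeLines(obo_lines, obo_path)

  ## --- GAF annotations with a controlled evidence mix ----------------------
  codes <- list(experimental = c("IDA", "IMP", "IGI", "EXP"),
                computational = evidence_code_groups$computational,
                htp = evidence_code_groups$htp)
  n_ann <- max(1L, round(spec$n_genes * spec$annotations_per_gene))
  ann_gene <- sample(genes, n_ann, replace = TRUE)
  ann_term <- sample(terms, n_ann, replace = TRUE)
  cls <- sample(names(spec$evidence_mix), n_ann, replace = TRUE,
                prob = spec$evidence_mix)
  ann_code <- vapply(cls, function(cl) sample(codes[[cl]], 1), character(1))
  gaf_rows <- paste("SYN", ann_gene, ann_gene, "", ann_term, "SYN:ref",
                    ann_code, "", "P", paste("synthetic gene", ann_gene), "",
                    "gene", "taxon:0000", "20240101", "SYN", "", "",
                    sep = "\t")
  gaf_path <- file.path(out_dir, "annotations.gaf")
  writeLines(c("!gaf-version: 2.2", "! synthetic annotation fixture",
               gaf_rows), gaf_path)

  ## --- pathway GMT (disjoint-ish random sets) ------------------------------
  pw_ids <- sprintf("PW%02d", seq_len(spec$n_pathways))
  pw_sets <- stats::setNames(lapply(pw_ids, function(p)
    sort(sample(genes, sample(5:12, 1)))), pw_ids)
  gmt_path <- file.path(out_dir, "pathways.gmt")
  writeLines(vapply(pw_ids, function(p)
    paste(c(p, paste("synthetic pathway", p), pw_sets[[p]]), collapse = "\t"),
    character(1)), gmt_path)

  ## --- expression matrix with planted tissue-preferential genes -----------
  gm <- spec$n_tissue_groups
  groups <- sprintf("tissue%02d", seq_len(gm))
  samples <- as.vector(vapply(groups, function(g)
    paste0(g, "_s", seq_len(spec$n_samples_per_group)),
    character(spec$n_samples_per_group)))
  sample_group <- rep(groups, each = spec$n_samples_per_group)
  # baseline: low flat expression well under the RPKM floor
  expr <- matrix(round(stats::runif(spec$n_genes * length(samples), 0, 2), 3),
                 nrow = spec$n_genes,
                 dimnames = list(genes, samples))
  planted_genes <- if (spec$n_planted_specific > 0)
    sample(genes, spec$n_planted_specific) else character()
  planted_group <- stats::setNames(
    sample(groups, length(planted_genes), replace = TRUE), planted_genes)
  for (g in planted_genes) {
    cols <- samples[sample_group == planted_group[[g]]]
    # in-group mean >= 10x baseline and comfortably above the floor
    expr[g, cols] <- round(stats::runif(length(cols), 40, 60), 3)
  }
  expr_path <- file.path(out_dir, "expression.tsv")
  df <- data.frame(gene_id = genes, expr, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  groups_path <- file.path(out_dir, "sample_groups.tsv")
  utils::write.table(data.frame(sample = samples, group = sample_group),
                     groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- genotype-phenotype table with known single-allele records ----------
  pheno_terms <- terms[seq_len(min(5L, spec$n_terms))]
  gp <- data.frame(
    genotype = c(paste0(genes[1], "[1]"),          # single classical
                 paste0(genes[2], "[ins1]"),       # single insertional
                 paste0(genes[3], "[1] ", genes[4], "[2]"),  # two genes
                 paste0(genes[5], "[UAS]")),       # non-qualifying class
    gene_ids = c(genes[1], genes[2],
                 paste(genes[3], genes[4], sep = "|"), genes[5]),
    allele_class = c("classical", "insertional", "classical", "other"),
    phenotype_term_id = pheno_terms[c(1, 1, 2, 3)],
    stringsAsFactors = FALSE
  )
  gp_path <- file.path(out_dir, "genotype_phenotype.tsv")
  utils::write.table(gp, gp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- identifier map (canonical ids + symbol aliases + reference rows) ---
  idmap <- data.frame(
    alias = c(paste0("sym_", genes), "wg", "wingless", "WNT1"),
    canonical_id = c(genes, "FBgn0284084", "FBgn0284084", "HGNC:12774"),
    alias_type = c(rep("symbol", length(genes)), "symbol", "fullname",
                   "symbol"),
    stringsAsFactors = FALSE
  )
  idmap_path <- file.path(out_dir, "id_map.tsv")
  utils::write.table(idmap, idmap_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- gene lists with planted overlap against pathway sets ---------------
  pw_universe <- sort(unique(unlist(pw_sets, use.names = FALSE)))
  list_paths <- character()
  planted_lists <- list()
  target_sets <- pw_ids[seq_along(spec$planted_enrichment)]
  for (j in seq_along(spec$planted_enrichment)) {
    lab <- names(spec$planted_enrichment)[j]
    frac <- spec$planted_enrichment[[j]]
    target <- pw_sets[[target_sets[j]]]
    n_list <- max(4L, min(length(target), 8L))
    n_in <- round(frac * n_list)
    inside <- sample(target, min(n_in, length(target)))
    outside <- sample(setdiff(pw_universe, target),
                      n_list - length(inside))
    members <- sort(c(inside, outside))
    p <- file.path(out_dir, paste0("list_", lab, ".txt"))
    writeLines(c(paste0("# planted list '", lab, "'"), members), p)
    list_paths[paste0("list_", lab)] <- p
    planted_lists[[lab]] <- list(target_set = target_sets[j],
                                 fraction = frac, n = n_list,
                                 members = members,
                                 n_inside = length(inside))
  }

  ## --- ground truth --------------------------------------------------------
  pair_key <- paste(ann_gene, ann_term)
  pair_codes <- split(ann_code, pair_key)
  surv <- function(excl) sum(!vapply(pair_codes, function(cc)
    all(cc %in% excl), logical(1)))
  ont <- read_obo(obo_path)
  clo <- .ancestor_closure(ont)
  direct <- lapply(split(ann_gene, ann_term), unique)
  prop <- new.env(parent = emptyenv())
  for (t in names(direct)) {
    for (tt in c(t, clo[[t]])) prop[[tt]] <- union(prop[[tt]], direct[[t]])
  }
  prop_list <- as.list(prop)

  truth <- list(
    seed = spec$seed,
    n_genes = spec$n_genes,
    n_terms = spec$n_terms,
    n_annotation_records = n_ann,
    n_annotation_pairs = length(pair_codes),
    evidence_survivors = list(
      all = length(pair_codes),
      experimental_only = surv(evidence_code_groups$computational),
      exclude_htp_only = surv(evidence_code_groups$htp)
    ),
    direct_set_sizes = lapply(direct, length),
    propagated_set_sizes = lapply(prop_list, length),
    planted_tissue = list(
      genes = as.list(planted_group),
      n = length(planted_genes)
    ),
    single_allele_genes = list(genes[1], genes[2]),
    pathway_sizes = lapply(pw_sets, length),
    planted_lists = planted_lists
  )
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  files <- c(ontology = obo_path, gaf = gaf_path, gmt = gmt_path,
             expression = expr_path, sample_groups = groups_path,
             genotype_phenotype = gp_path, id_map = idmap_path,
             list_paths, truth = truth_path)

  manifest <- list(
    seed = spec$seed,
    files = lapply(stats::setNames(as.list(files), names(files)), function(f)
      list(name = basename(f),
           sha256 = digest::digest(f, algo = "sha256", file = TRUE)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(files = c(files, manifest = manifest_path),
                 manifest = manifest, truth = truth))
}
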