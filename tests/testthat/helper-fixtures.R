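# Shared builders and independent oracles for the test suite.

# Write a minimal OBO file from a named list term -> character vector of
# is_a parents. `part_of` links may be given via the `part_of` list.
write_obo_file <- function(parents, path = tempfile(fileext = ".obo"),
                           namespace = "demo", obsolete = character(),
                           alt_ids = list(), part_of = list(),
                           namespaces = NULL) {
  terms <- unique(c(names(parents),
                    unlist(parents, use.names = FALSE),
                    unlist(part_of, use.names = FALSE),
                    names(part_of)))
  lines <- c("format-version: 1.2")
  for (t in terms) {
    ns <- if (!is.null(namespaces)) namespaces[[t]] else namespace
    lines <- c(lines, "", "[Term]", paste0("id: ", t),
               paste0("name: name of ", t),
               paste0("namespace: ", ns),
               if (t %in% names(alt_ids))
                 paste0("alt_id: ", alt_ids[[t]]),
               if (t %in% obsolete) "is_obsolete: true",
               if (length(parents[[t]]))
                 paste0("is_a: ", parents[[t]]),
               if (length(part_of[[t]]))
                 paste0("relationship: part_of ", part_of[[t]]))
  }
  writeLines(lines, path)
  path
}

# One 17-column GAF data row.
gaf_row <- function(gene, term, code, qualifier = "", aspect = "P") {
  paste("DB", gene, gene, qualifier, term, "REF:1", code, "", aspect,
        paste("name of", gene), "", "gene", "taxon:1", "20240101", "DB",
        "", "", sep = "\t")
}

write_gaf_file <- function(rows, path = tempfile(fileext = ".gaf")) {
  writeLines(c("!gaf-version: 2.2", rows), path)
  path
}

# Random layered DAG as a parent list: term i may take is_a parents among
# terms with smaller index, so the graph is acyclic by construction.
random_dag_parents <- function(n_terms, p_edge = 0.3, max_parents = 3) {
  ids <- sprintf("RT:%03d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  for (i in seq_len(n_terms)[-1]) {
    k <- min(i - 1L, stats::rbinom(1, max_parents, p_edge))
    if (k > 0) parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], k)
  }
  parents
}

# Independent reachability oracle over a parent list: ancestors of `id` by
# exhaustive path following through igraph (child -> parent edges).
oracle_ancestors <- function(parents, id) {
  edges <- do.call(rbind, lapply(names(parents), function(ch) {
    if (length(parents[[ch]])) cbind(ch, parents[[ch]])
  }))
  all_ids <- unique(c(names(parents), unlist(parents, use.names = FALSE)))
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character())
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = TRUE, vertices = all_ids)
  reach <- igraph::subcomponent(g, id, mode = "out")
  sort(setdiff(names(reach), id))
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability: enumerate every draw of n from N (first K marked) and count
# draws with at least k marked elements.
oracle_hyper <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Independent step-up / scaling reference for the adjustment procedures,
# written from the procedure definitions (not via p.adjust).
oracle_adjust <- function(p, method) {
  m <- length(p)
  if (method == "bonferroni") return(pmin(1, p * m))
  cm <- if (method == "by") sum(1 / seq_len(m)) else 1
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(cm * m / seq(i, m) * ps[seq(i, m)]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-set collection whose universe is 10 genes, holding the worked
# (N, K, n, k) = (10, 5, 4, 4) configuration for S1 with input g1..g4.
demo_collection <- function() {
  gene_set_collection(list(S1 = paste0("g", 1:5), S2 = paste0("g", 6:10)),
                      collection_id = "demo", category = "demo")
}
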