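#' Enrichment of several gene lists with a cross-list comparison matrix
#'
#' Runs [run_enrichment()] independently for every list (the
#' multiple-testing family stays per list, so one list's adjusted values
#' never depend on another list's size). The matrix rows are the sets
#' passing the cutoff in at least one list; cells carry the per-list
#' adjusted p, fold enrichment and overlap count exactly as the single-list
#' runs produced them. Pairs never tested or failing everywhere carry the
#' p = 1 marker, not blanks, so the matrix is dense.
#'
#' @param lists A list of [map_gene_list()] results or character vectors;
#'   names (or `mapped_list` labels) must be unique.
#' @param collection,background,min_set_size Passed to [run_enrichment()].
#' @param p_cutoff Cutoff defining which sets enter the matrix (applied per
#'   list on `cutoff_on`); default 0.05.
#' @param cutoff_on Adjustment column used for the cutoff and stored in the
#'   matrix cells.
#' @return Object of class `ora_multi`: list with `results` (named list of
#'   `ora_result`, each *unfiltered*) and `matrix`, a `comparison_matrix`
#'   holding numeric set x list matrices `p_adj`, `fold` and `k` plus the
#'   `method` used.
#' @export
run_enrichment_multi <- function(lists, collection, background = NULL,
                                 min_set_size = 1L, p_cutoff = 0.05,
                                 cutoff_on = c("bh", "raw", "bonferroni", "by")) {
  cutoff_on <- match.arg(cutoff_on)
  if (length(lists) < 1) stop("need at least one gene list", call. = FALSE)
  labels <- names(lists)
  if (is.null(labels)) labels <- rep(NA_character_, length(lists))
  for (i in seq_along(lists)) {
    if (is.na(labels[i]) || !nzchar(labels[i])) {
      labels[i] <- if (inherits(lists[[i]], "mapped_list"))
        lists[[i]]$label else paste0("list", i)
    }
  }
  if (anyDuplicated(labels)) {
    stop("duplicate list labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }

  results <- stats::setNames(vector("list", length(lists)), labels)
  for (i in seq_along(lists)) {
    r <- run_enrichment(lists[[i]], collection, background = background,
                        min_set_size = min_set_size)  # cutoff applied below
    r$label <- labels[i]
    results[[i]] <- r
  }

  col <- switch(cutoff_on, raw = "p_raw", bonferroni = "p_bonferroni",
                bh = "p_bh", by = "p_by")
  pass <- lapply(results, function(r)
    r$table$set_id[r$table[[col]] <= p_cutoff])
  row_ids <- sort(unique(unlist(pass, use.names = FALSE)))

  p_adj <- matrix(1, nrow = length(row_ids), ncol = length(labels),
                  dimnames = list(row_ids, labels))
  fold <- matrix(0, nrow = length(row_ids), ncol = length(labels),
                 dimnames = list(row_ids, labels))
  kmat <- matrix(0L, nrow = length(row_ids), ncol = length(labels),
                 dimnames = list(row_ids, labels))
  for (lab in labels) {
    tab <- results[[lab]]$table
    hit <- tab$set_id %in% row_ids
    idx <- tab$set_id[hit]
    p_adj[idx, lab] <- tab[[col]][hit]
    fold[idx, lab] <- tab$fold_enrichment[hit]
    kmat[idx, lab] <- tab$k[hit]
  }

  set_names <- if (length(row_ids)) collection$set_names[row_ids] else character()
  structure(
    list(results = results,
         matrix = structure(list(p_adj = p_adj, fold = fold, k = kmat,
                                 set_names = set_names, method = cutoff_on,
                                 p_cutoff = p_cutoff),
                            class = "comparison_matrix")),
    class = "ora_multi"
  )
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("comparison_matrix:", nrow(x$p_adj), "gene set(s) x",
      ncol(x$p_adj), "list(s); cells:", x$method, "adjusted p (cutoff",
      x$p_cutoff, ")\n")
  if (nrow(x$p_adj)) print(signif(x$p_adj, 3))
  invisible(x)
}

#' @export
print.ora_multi <- function(x, ...) {
  cat("ora_multi:", length(x$results), "list(s)\n")
  print(x$matrix)
  invisible(x)
}

#' Bipartite gene/gene-set graph for selected result sets
#'
#' Gene-set nodes connect to the input genes they contain (the overlap
#' members of the enrichment result); a gene overlapping several selected
#' sets gets one edge per set. Sets with an empty overlap are omitted so the
#' graph carries no orphan nodes.
#'
#' @param result An `ora_result`.
#' @param selected_set_ids Set ids to include (must appear in the result).
#' @return Object of class `bipartite_graph`: list with `nodes` (data frame
#'   `id`, `kind` in gene/gene_set, `label`) and `edges` (data frame
#'   `gene_set_id`, `gene_id`), both deterministically sorted.
#' @export
build_graph <- function(result, selected_set_ids) {
  stopifnot(inherits(result, "ora_result"))
  unknown <- setdiff(selected_set_ids, result$table$set_id)
  if (length(unknown)) {
    stop("set id(s) not in the results: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tab <- result$table[result$table$set_id %in% selected_set_ids, ,
                      drop = FALSE]
  edges <- do.call(rbind, c(list(
    data.frame(gene_set_id = character(), gene_id = character(),
               stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(tab)), function(i) {
      members <- strsplit(tab$overlap_members[i], "|", fixed = TRUE)[[1]]
      members <- members[nzchar(members)]
      if (!length(members)) return(NULL)
      data.frame(gene_set_id = tab$set_id[i], gene_id = members,
                 stringsAsFactors = FALSE)
    })))
  edges <- edges[order(edges$gene_set_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL

  set_ids <- sort(unique(edges$gene_set_id))
  gene_ids <- sort(unique(edges$gene_id))
  nodes <- rbind(
    data.frame(id = set_ids, kind = rep("gene_set", length(set_ids)),
               label = unname(stats::setNames(tab$name, tab$set_id)[set_ids]),
               stringsAsFactors = FALSE),
    data.frame(id = gene_ids, kind = rep("gene", length(gene_ids)),
               label = gene_ids, stringsAsFactors = FALSE)
  )
  structure(list(nodes = nodes, edges = edges), class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("bipartite_graph:", sum(x$nodes$kind == "gene_set"), "gene-set node(s),",
      sum(x$nodes$kind == "gene"), "gene node(s),", nrow(x$edges), "edge(s)\n")
  invisible(x)
}

#' Write a bipartite graph as node/edge TSVs or GraphML
#'
#' @param graph A [build_graph()] result.
#' @param path Output path. For `format = "tsv"`, `path` is a prefix:
#'   `<path>.nodes.tsv` and `<path>.edges.tsv` are written.
#' @param format `"tsv"` or `"graphml"` (via igraph).
#' @return `path`, invisibly.
#' @export
write_graph_files <- function(graph, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(graph, "bipartite_graph"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(graph$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(graph$edges, paste0(path, ".edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      graph$edges, directed = FALSE,
      vertices = graph$nodes[, c("id", "kind", "label")])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Serializable plot data for bar, heatmap and dot-plot views
#'
#' Bar: per-set `-log10(p_adj)` heights with a fold-enrichment colour
#' channel (from a single `ora_result`). Heatmap: set x list matrix of
#' `-log10(p_adj)` (from a `comparison_matrix`); missing pairs carry the
#' p = 1 marker, i.e. height 0. Dot plot: long records with dot size `k`
#' and colour `-log10(p_adj)`. p-values below 1e-300 are clamped so every
#' coordinate stays finite. Keys and row order are fixed, so identical
#' inputs serialize byte-identically.
#'
#' @param x An `ora_result` (bar) or `comparison_matrix` (heatmap/dotplot).
#' @param kind `"bar"`, `"heatmap"` or `"dotplot"`.
#' @param method Adjustment column used for `ora_result` input (default bh).
#' @return A list ready for [write_plot_data()].
#' @export
export_plot_data <- function(x, kind = c("bar", "heatmap", "dotplot"),
                             method = c("bh", "raw", "bonferroni", "by")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  neglog <- function(p) -log10(pmax(p, 1e-300))
  if (kind == "bar") {
    stopifnot(inherits(x, "ora_result"))
    tab <- x$table
    if (nrow(tab) == 0) stop("no enrichment results to plot", call. = FALSE)
    col <- switch(method, raw = "p_raw", bonferroni = "p_bonferroni",
                  bh = "p_bh", by = "p_by")
    list(kind = "bar", method = method,
         sets = tab$set_id, labels = unname(tab$name),
         height = neglog(tab[[col]]),
         colour = tab$fold_enrichment, k = tab$k)
  } else {
    stopifnot(inherits(x, "comparison_matrix"))
    if (nrow(x$p_adj) == 0) {
      stop("comparison matrix is empty; nothing to plot", call. = FALSE)
    }
    if (kind == "heatmap") {
      list(kind = "heatmap", method = x$method,
           sets = rownames(x$p_adj), lists = colnames(x$p_adj),
           neglog10_p = lapply(unname(apply(x$p_adj, 1, neglog,
                                            simplify = FALSE)), unname))
    } else {
      cells <- expand.grid(set = rownames(x$p_adj), list = colnames(x$p_adj),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      cells <- cells[order(cells$set, cells$list), , drop = FALSE]
      list(kind = "dotplot", method = x$method,
           set = cells$set, list = cells$list,
           size = as.integer(x$k[cbind(cells$set, cells$list)]),
           colour = neglog(x$p_adj[cbind(cells$set, cells$list)]))
    }
  }
}

#' Write plot data as deterministic JSON
#'
#' @param data [export_plot_data()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plot_data <- function(data, path) {
  jsonlite::write_json(data, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Draw enrichment plots
#'
#' Base-graphics renderings of the three plot-data kinds: a horizontal bar
#' chart of `-log10(p)`, a heatmap of the comparison matrix, or a dot plot
#' with dot size proportional to the overlap count.
#'
#' @inheritParams export_plot_data
#' @param top For bars: show at most this many sets (most significant
#'   first).
#' @return Invisibly, the plot data used.
#' @export
plot_enrichment <- function(x, kind = c("bar", "heatmap", "dotplot"),
                            method = c("bh", "raw", "bonferroni", "by"),
                            top = 20L) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  pd <- export_plot_data(x, kind, method)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old), add = TRUE)
  if (kind == "bar") {
    n <- min(top, length(pd$sets))
    graphics::par(mar = c(4, 10, 2, 1))
    graphics::barplot(rev(pd$height[seq_len(n)]),
                      names.arg = rev(pd$sets[seq_len(n)]),
                      horiz = TRUE, las = 1,
                      xlab = expression(-log[10](p[adj])),
                      main = "over-represented gene sets")
  } else if (kind == "heatmap") {
    m <- do.call(rbind, pd$neglog10_p)
    dimnames(m) <- list(pd$sets, pd$lists)
    graphics::par(mar = c(6, 10, 2, 1))
    graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                    axes = FALSE, main = "-log10 adjusted p")
    graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                   labels = pd$lists, las = 2)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                   labels = rev(pd$sets), las = 1)
  } else {
    sets <- sort(unique(pd$set)); lists <- sort(unique(pd$list))
    xi <- match(pd$list, lists); yi <- match(pd$set, sets)
    graphics::par(mar = c(6, 10, 2, 1))
    graphics::plot(xi, yi, cex = sqrt(pd$size) + 0.2,
                   pch = 16,
                   col = grDevices::hcl.colors(100, "viridis")[
                     pmin(100L, 1L + round(99 * pd$colour /
                                             max(pd$colour, 1e-9)))],
                   axes = FALSE, xlab = "", ylab = "",
                   xlim = c(0.5, length(lists) + 0.5),
                   ylim = c(0.5, length(sets) + 0.5),
                   main = "overlap size / -log10 adjusted p")
    graphics::axis(1, at = seq_along(lists), labels = lists, las = 2)
    graphics::axis(2, at = seq_along(sets), labels = sets, las = 1)
    graphics::box()
  }
  invisible(pd)
}

#' @export
plot.ora_result <- function(x, kind = "bar", ...) {
  plot_enrichment(x, kind = kind, ...)
}

#' @export
plot.comparison_matrix <- function(x, kind = "heatmap", ...) {
  plot_enrichment(x, kind = kind, ...)
}
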