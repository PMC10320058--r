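#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more list members inside a gene set when
#' `n` genes are drawn without replacement from a background of `N` genes of
#' which `K` belong to the set: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Computed with the survival function
#' (`stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)`), which is
#' numerically stable for extreme tails.
#'
#' @param N Background size.
#' @param K Set size within the background.
#' @param n Input-list size within the background.
#' @param k Overlap size. All four may be vectors (recycled).
#' @return Numeric vector of one-sided upper-tail p-values in `(0, 1]`.
#' @examples
#' hypergeom_pvalue(10, 5, 4, 4)  # 5/210
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  v <- cbind(N = N, K = K, n = n, k = k)
  if (any(v < 0 | v != floor(v))) {
    bad <- colnames(v)[which(apply(v < 0 | v != floor(v), 2, any))[1]]
    stop("count '", bad, "' must be a non-negative integer", call. = FALSE)
  }
  if (any(v[, "K"] > v[, "N"])) stop("count 'K' exceeds N", call. = FALSE)
  if (any(v[, "n"] > v[, "N"])) stop("count 'n' exceeds N", call. = FALSE)
  if (any(v[, "k"] > pmin(v[, "n"], v[, "K"]))) {
    stop("count 'k' exceeds min(n, K)", call. = FALSE)
  }
  unname(stats::phyper(v[, "k"] - 1, v[, "K"], v[, "N"] - v[, "K"], v[, "n"],
                       lower.tail = FALSE))
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, p * m)`), Benjamini-Hochberg step-up, or
#' Benjamini-Yekutieli (BH scaled by `c(m) = sum(1/i)`), all capped at 1 and
#' returned in input order. Thin wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"bonferroni"`, `"bh"`, `"by"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "by")) {
  method <- match.arg(method)
  if (length(p) < 1) stop("p must have length >= 1", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = switch(method, bonferroni = "bonferroni",
                                     bh = "BH", by = "BY"))
}

#' Resolve the background gene universe
#'
#' @param collection A [gene_set_collection()].
#' @param background `NULL` (use the collection universe, i.e. every gene
#'   annotated in the category) or a character vector of user-supplied gene
#'   ids, which is intersected with the collection universe; genes outside
#'   the universe cannot be tested and their count is reported.
#' @return List with `genes`, `source` and `n_discarded`.
#' @export
resolve_background <- function(collection, background = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(background)) {
    list(genes = collection$universe, source = "collection_universe",
         n_discarded = 0L)
  } else {
    bg <- unique(as.character(background))
    kept <- intersect(bg, collection$universe)
    list(genes = sort(kept), source = "user_supplied",
         n_discarded = length(bg) - length(kept))
  }
}

#' Hypergeometric over-representation test of a gene list
#'
#' Tests every gene set in the collection whose in-background size is at
#' least `min_set_size`, using `N = |background|`,
#' `K = |set & background|`, `n = |input & background|`,
#' `k = |input & set & background|`. All three adjustment procedures are
#' computed over the family of sets tested in this call. Results are sorted
#' by raw p-value, ties broken by set id. Zero-overlap sets are reported
#' (with p = 1) unless a cutoff removes them, which keeps multi-list
#' comparison matrices dense.
#'
#' @param genes A [map_gene_list()] result or a character vector of
#'   canonical gene ids.
#' @param collection A [gene_set_collection()].
#' @param background See [resolve_background()].
#' @param min_set_size Sets smaller than this within the background are not
#'   tested (default 1: no filtering).
#' @param p_cutoff Optional cutoff applied after adjustment.
#' @param cutoff_on Which column the cutoff filters: `"raw"`,
#'   `"bonferroni"`, `"bh"` or `"by"`.
#' @return Object of class `ora_result`: a list with
#'   \describe{
#'     \item{table}{data frame with columns `set_id`, `name`, `category`,
#'       `N`, `K`, `n`, `k`, `p_raw`, `p_bonferroni`, `p_bh`, `p_by`,
#'       `fold_enrichment` and `overlap_members` (`|`-joined).}
#'     \item{uncovered}{list: `genes` in the input covered by no set of the
#'       full collection, and `fraction` of the in-background input.}
#'     \item{label, background, n_tested, params}{run metadata.}
#'   }
#' @examples
#' coll <- gene_set_collection(
#'   list(S1 = paste0("g", 1:5), S2 = paste0("g", 6:10)),
#'   collection_id = "demo")
#' res <- run_enrichment(paste0("g", 1:4), coll)
#' res$table[, c("set_id", "N", "K", "n", "k", "p_raw", "fold_enrichment")]
#' @export
run_enrichment <- function(genes, collection, background = NULL,
                           min_set_size = 1L, p_cutoff = NULL,
                           cutoff_on = c("bh", "raw", "bonferroni", "by")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  cutoff_on <- match.arg(cutoff_on)
  if (!is.null(p_cutoff) && (p_cutoff <= 0 || p_cutoff > 1)) {
    stop("p_cutoff must lie in (0, 1]", call. = FALSE)
  }
  if (min_set_size < 1) stop("min_set_size must be >= 1", call. = FALSE)

  label <- "list"
  if (inherits(genes, "mapped_list")) {
    label <- genes$label
    genes <- genes$mapped
  }
  genes <- unique(as.character(genes))

  bg <- resolve_background(collection, background)
  input <- intersect(genes, bg$genes)
  if (length(input) == 0) {
    stop("no input genes remain after background intersection (",
         length(genes), " input, ", length(bg$genes), " background, ",
         bg$n_discarded, " background genes outside the universe)",
         call. = FALSE)
  }

  N <- length(bg$genes)
  n <- length(input)

  sets_bg <- lapply(collection$sets, intersect, bg$genes)
  Ks <- lengths(sets_bg)
  test_ids <- names(sets_bg)[Ks >= min_set_size]
  if (length(test_ids) == 0) {
    stop("no gene set passes min_set_size = ", min_set_size, call. = FALSE)
  }

  overlap <- lapply(sets_bg[test_ids], intersect, input)
  k <- lengths(overlap)
  K <- Ks[test_ids]
  p_raw <- hypergeom_pvalue(N, K, n, k)
  fold <- ifelse(K > 0, (k / n) / (K / N), NA_real_)

  tab <- data.frame(
    set_id = test_ids,
    name = unname(collection$set_names[test_ids]),
    category = collection$category,
    N = N, K = unname(K), n = n, k = unname(k),
    p_raw = unname(p_raw),
    p_bonferroni = unname(adjust_pvalues(p_raw, "bonferroni")),
    p_bh = unname(adjust_pvalues(p_raw, "bh")),
    p_by = unname(adjust_pvalues(p_raw, "by")),
    fold_enrichment = unname(fold),
    overlap_members = vapply(overlap, function(g)
      paste(sort(g), collapse = "|"), character(1)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$p_raw, tab$set_id), , drop = FALSE]
  rownames(tab) <- NULL

  n_tested <- nrow(tab)
  if (!is.null(p_cutoff)) {
    col <- switch(cutoff_on, raw = "p_raw", bonferroni = "p_bonferroni",
                  bh = "p_bh", by = "p_by")
    tab <- tab[tab[[col]] <= p_cutoff, , drop = FALSE]
  }

  covered <- unique(unlist(collection$sets, use.names = FALSE))
  unc <- sort(setdiff(input, covered))

  structure(
    list(table = tab,
         uncovered = list(genes = unc, fraction = length(unc) / n),
         label = label,
         background = bg[c("source", "n_discarded")],
         background_size = N, input_size = n, n_tested = n_tested,
         params = list(min_set_size = min_set_size, p_cutoff = p_cutoff,
                       cutoff_on = cutoff_on)),
    class = "ora_result"
  )
}

#' @export
print.ora_result <- function(x, n = 10L, ...) {
  cat("ora_result '", x$label, "': ", x$input_size, " genes vs ",
      x$n_tested, " sets (background ", x$background_size, ", ",
      x$background$source, ")\n", sep = "")
  if (!is.null(x$params$p_cutoff)) {
    cat("cutoff:", x$params$cutoff_on, "<=", x$params$p_cutoff, "->",
        nrow(x$table), "set(s) pass\n")
  }
  cat("uncovered input genes:", length(x$uncovered$genes),
      sprintf("(%.1f%%)\n", 100 * x$uncovered$fraction))
  show <- utils::head(x$table[, c("set_id", "K", "k", "p_raw", "p_bh",
                                  "fold_enrichment")], n)
  if (nrow(show)) print(show, row.names = FALSE) else cat("(no results)\n")
  invisible(x)
}

#' @export
summary.ora_result <- function(object, alpha = 0.05, ...) {
  cat("Over-representation analysis of '", object$label, "'\n", sep = "")
  cat("  background:", object$background_size, "genes (",
      object$background$source, ",", object$background$n_discarded,
      "discarded )\n")
  cat("  sets tested:", object$n_tested, "\n")
  for (m in c("p_raw", "p_bonferroni", "p_bh", "p_by")) {
    cat(sprintf("  %-13s <= %.3g: %d set(s)\n", m, alpha,
                sum(object$table[[m]] <= alpha)))
  }
  invisible(object)
}

#' @export
as.data.frame.ora_result <- function(x, ...) x$table

#' Write enrichment results and the uncovered-genes report as TSV
#'
#' @param x An `ora_result`.
#' @param path Output path for the result table; the uncovered report goes
#'   to `paste0(path, ".uncovered.tsv")` when `uncovered = TRUE`.
#' @param uncovered Also write the uncovered-genes report.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(x, path, uncovered = TRUE) {
  stopifnot(inherits(x, "ora_result"))
  tab <- x$table
  num <- c("p_raw", "p_bonferroni", "p_bh", "p_by", "fold_enrichment")
  for (cn in num) tab[[cn]] <- sprintf("%.10g", tab[[cn]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (uncovered) {
    udf <- data.frame(gene_id = x$uncovered$genes,
                      fraction_of_input = rep(sprintf("%.10g", x$uncovered$fraction),
                                              length(x$uncovered$genes)))
    utils::write.table(udf, paste0(path, ".uncovered.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
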