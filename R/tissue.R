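#' Read an RPKM expression matrix with a sample-to-tissue map
#'
#' The matrix is TSV: first column gene ids, header row of sample ids,
#' non-negative RPKM values. The group map is a two-column TSV (header
#' `sample`, `group`) assigning every sample to a tissue group.
#'
#' @param path Path to the expression TSV.
#' @param groups Either the path to the sample->group TSV or a named
#'   character vector (names = samples, values = group labels).
#' @return Object of class `expression_matrix`: list with `values` (numeric
#'   gene x sample matrix) and `sample_groups` (named character vector).
#' @export
read_expression_matrix <- function(path, groups) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    gdf <- utils::read.delim(groups, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("sample", "group") %in% names(gdf))) {
      stop("group map needs columns 'sample' and 'group'", call. = FALSE)
    }
    groups <- stats::setNames(gdf$group, gdf$sample)
  }
  expression_matrix(m, groups)
}

#' Construct an expression matrix object
#'
#' @param values Numeric gene x sample matrix of RPKM values (dimnames
#'   required).
#' @param sample_groups Named character vector: sample id -> tissue-group
#'   label; every column of `values` must be covered.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("RPKM values must be non-negative", call. = FALSE)
  missing <- setdiff(colnames(values), names(sample_groups))
  if (length(missing)) {
    stop("sample(s) without a tissue group: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(values = values,
                 sample_groups = sample_groups[colnames(values)]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples in", length(unique(x$sample_groups)), "tissue group(s)\n")
  invisible(x)
}

#' Per-tissue-group mean expression
#'
#' Arithmetic mean RPKM of each gene over the samples of each tissue group,
#' unweighted across samples.
#'
#' @param matrix An [expression_matrix()].
#' @return Numeric gene x group matrix of means.
#' @export
group_means <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  groups <- sort(unique(matrix$sample_groups))
  out <- vapply(groups, function(g) {
    cols <- names(matrix$sample_groups)[matrix$sample_groups == g]
    rowMeans(matrix$values[, cols, drop = FALSE])
  }, numeric(nrow(matrix$values)))
  if (nrow(matrix$values) == 1) out <- t(as.matrix(out))  # keep gene x group
  dimnames(out) <- list(rownames(matrix$values), groups)
  out
}

#' Classify genes as preferentially expressed in one tissue group
#'
#' A gene is assigned to group `G` when its mean RPKM in `G` is at least
#' `min_rpkm` *and* at least `fold_threshold` times its mean in every other
#' group (both comparisons inclusive). With `fold_threshold > 1` a gene can
#' satisfy the rule in at most one group, so tissue sets are disjoint by
#' construction. The `min_rpkm` floor is applied to the candidate group's
#' mean. A zero mean in another group never blocks assignment (the fold
#' condition holds in the limit).
#'
#' @param means Gene x group matrix from [group_means()] (needs >= 2
#'   groups).
#' @param fold_threshold Minimum ratio over every other group's mean
#'   (default 3).
#' @param min_rpkm Minimum mean RPKM in the assigned group (default 10).
#' @return Object of class `tissue_assignment`: list with `assignment`
#'   (named character vector gene -> group, unassigned genes absent) and
#'   `params`.
#' @examples
#' m <- rbind(ga = c(nerve = 30, gut = 10, muscle = 5),
#'            gb = c(nerve = 9,  gut = 1,  muscle = 1),
#'            gc = c(nerve = 30, gut = 11, muscle = 1))
#' classify_preferential(m)$assignment  # only 'ga' is assigned (to nerve)
#' @export
classify_preferential <- function(means, fold_threshold = 3, min_rpkm = 10) {
  if (!is.matrix(means) || ncol(means) < 2) {
    stop("need a gene x group matrix with >= 2 groups", call. = FALSE)
  }
  if (fold_threshold <= 0 || min_rpkm <= 0) {
    stop("fold_threshold and min_rpkm must be positive", call. = FALSE)
  }
  groups <- colnames(means)
  assign <- character()
  for (g in rownames(means)) {
    row <- means[g, ]
    for (G in groups) {
      others <- row[setdiff(groups, G)]
      if (row[[G]] >= min_rpkm && all(row[[G]] >= fold_threshold * others)) {
        assign[[g]] <- G
        break  # uniqueness holds for fold_threshold > 1; first hit is the only hit
      }
    }
  }
  structure(list(assignment = assign,
                 params = list(fold_threshold = fold_threshold,
                               min_rpkm = min_rpkm)),
            class = "tissue_assignment")
}

#' @export
print.tissue_assignment <- function(x, ...) {
  cat("tissue_assignment:", length(x$assignment), "gene(s) assigned",
      "( fold >=", x$params$fold_threshold, ", mean RPKM >=",
      x$params$min_rpkm, ")\n")
  if (length(x$assignment)) print(table(x$assignment))
  invisible(x)
}

#' Turn a tissue assignment into a gene-set collection
#'
#' One gene set per tissue group with at least one assigned gene; sets are
#' disjoint because each gene carries at most one assignment.
#'
#' @param assignment A [classify_preferential()] result.
#' @inheritParams gene_set_collection
#' @return A [gene_set_collection()] with category
#'   `"tissue-preferential-expression"`.
#' @export
tissue_collection <- function(assignment, collection_id = "tissue",
                              species = NA_character_) {
  stopifnot(inherits(assignment, "tissue_assignment"))
  sets <- if (length(assignment$assignment)) {
    split(names(assignment$assignment), unname(assignment$assignment))
  } else {
    list()
  }
  gene_set_collection(sets, collection_id = collection_id, species = species,
                      category = "tissue-preferential-expression")
}
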