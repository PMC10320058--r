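#' Read an identifier-mapping table
#'
#' Tab-separated with header columns `alias`, `canonical_id` and
#' `alias_type` (free text: symbol, entrez, secondary id, ...). Every
#' canonical id is also registered as an alias of itself, so canonical ids
#' always map through unchanged. An alias may map to several canonical ids;
#' such aliases are reported as ambiguous at mapping time.
#'
#' @param path Path to the TSV file.
#' @param species Species tag stored on the table.
#' @return Object of class `id_map` with elements `entries` (named list:
#'   alias -> character vector of canonical ids), `fold_index` (named list:
#'   lower-cased alias -> aliases with that folding) and `species`.
#' @export
read_id_map <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("id map file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("alias", "canonical_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("id map lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  blank <- !nzchar(trimws(df$alias)) | !nzchar(trimws(df$canonical_id))
  if (any(blank)) {
    stop("blank alias or canonical_id on data line ", which(blank)[1],
         call. = FALSE)
  }
  id_map_table(df$alias, df$canonical_id, species = species)
}

#' Build an identifier map from alias/canonical pairs
#'
#' @param alias Character vector of aliases.
#' @param canonical_id Character vector of the same length.
#' @param species Species tag.
#' @return An `id_map` (see [read_id_map()]).
#' @export
id_map_table <- function(alias, canonical_id, species = NA_character_) {
  stopifnot(length(alias) == length(canonical_id))
  # canonical ids are self-aliases
  alias <- c(alias, canonical_id)
  canonical_id <- c(canonical_id, canonical_id)
  entries <- lapply(split(canonical_id, alias), function(x) sort(unique(x)))
  fold_index <- lapply(split(names(entries), tolower(names(entries))), unique)
  structure(list(entries = entries, fold_index = fold_index,
                 species = species),
            class = "id_map")
}

#' @export
print.id_map <- function(x, ...) {
  cat("id_map:", length(x$entries), "aliases,",
      length(unique(unlist(x$entries, use.names = FALSE))),
      "canonical ids (species:", x$species, ")\n")
  invisible(x)
}

#' Map a gene list onto canonical identifiers
#'
#' Each input string is looked up exactly first; when that fails, a
#' case-insensitive fallback is tried. The fallback unions the candidates of
#' every alias sharing the folded spelling, so a case-insensitive hit that
#' collides with a distinct exact alias (as fly symbol pairs like `dl`/`Dl`
#' do) is reported ambiguous rather than silently case-folded. Every input
#' lands in exactly one of four bins, and
#' `length(input) == length(mapped) + length(unmapped) + length(ambiguous) +
#' duplicates_removed` always holds.
#'
#' @param input Character vector of gene identifiers.
#' @param table An `id_map`.
#' @param include_ambiguous When `TRUE`, all candidates of ambiguous aliases
#'   are added to `mapped` as well (they stay listed under `ambiguous`).
#' @param label Name for the list, carried into downstream reports.
#' @return Object of class `mapped_list`: `label`, `mapped` (canonical ids,
#'   deduplicated, sorted), `unmapped` (inputs with no hit), `ambiguous`
#'   (named list: input -> candidate canonical ids), `duplicates_removed`
#'   (count of inputs dropped as duplicates, pre- or post-mapping) and
#'   `n_input`.
#' @examples
#' tab <- id_map_table(c("wg", "wingless"), c("FBgn0284084", "FBgn0284084"))
#' map_gene_list(c("wg", "wg", "nonsense"), tab)
#' @export
map_gene_list <- function(input, table, include_ambiguous = FALSE,
                          label = "list") {
  stopifnot(inherits(table, "id_map"))
  input <- as.character(input)
  n_input <- length(input)

  dup_removed <- 0L
  seen_input <- character()
  mapped <- character()
  unmapped <- character()
  ambiguous <- list()

  for (x in input) {
    if (x %in% seen_input) { dup_removed <- dup_removed + 1L; next }
    seen_input <- c(seen_input, x)
    cand <- table$entries[[x]]
    if (is.null(cand)) {
      aliases <- table$fold_index[[tolower(x)]]
      cand <- sort(unique(unlist(table$entries[aliases], use.names = FALSE)))
    }
    if (is.null(cand) || length(cand) == 0) {
      unmapped <- c(unmapped, x)
    } else if (length(cand) == 1) {
      if (cand %in% mapped) dup_removed <- dup_removed + 1L
      else mapped <- c(mapped, cand)
    } else {
      ambiguous[[x]] <- cand
      if (include_ambiguous) mapped <- unique(c(mapped, cand))
    }
  }

  structure(
    list(label = label, mapped = sort(mapped), unmapped = unmapped,
         ambiguous = ambiguous, duplicates_removed = dup_removed,
         n_input = n_input),
    class = "mapped_list"
  )
}

#' @export
print.mapped_list <- function(x, ...) {
  cat("mapped_list '", x$label, "': ", x$n_input, " inputs -> ",
      length(x$mapped), " mapped, ", length(x$unmapped), " unmapped, ",
      length(x$ambiguous), " ambiguous, ", x$duplicates_removed,
      " duplicate(s) removed\n", sep = "")
  invisible(x)
}

#' Write the mapping report as TSV
#'
#' Columns: `input`, `status` (`mapped`/`unmapped`/`ambiguous`),
#' `canonical_ids` (`|`-joined candidates).
#'
#' @param x A `mapped_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_report <- function(x, path) {
  stopifnot(inherits(x, "mapped_list"))
  rows <- rbind(
    if (length(x$mapped))
      data.frame(input = x$mapped, status = "mapped",
                 canonical_ids = x$mapped, stringsAsFactors = FALSE),
    if (length(x$unmapped))
      data.frame(input = x$unmapped, status = "unmapped",
                 canonical_ids = "", stringsAsFactors = FALSE),
    if (length(x$ambiguous))
      data.frame(input = names(x$ambiguous), status = "ambiguous",
                 canonical_ids = vapply(x$ambiguous, paste,
                                        character(1), collapse = "|"),
                 stringsAsFactors = FALSE)
  )
  if (is.null(rows)) {
    rows <- data.frame(input = character(), status = character(),
                       canonical_ids = character())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the file.
#' @return Character vector of identifiers (duplicates preserved; they are
#'   accounted for during mapping).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("\\s*#.*$", "", lines)
  lines[nzchar(lines)]
}
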