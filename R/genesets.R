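#' Construct a gene-set collection
#'
#' A collection is the unit enrichment runs against: a named category of
#' gene sets plus the universe of genes they cover. Empty sets are dropped
#' (they cannot be enriched and would inflate the multiple-testing family),
#' members are deduplicated, and the universe is recomputed as the exact
#' union of members.
#'
#' @param sets Named list; each element a character vector of gene ids.
#' @param collection_id Identifier for the collection.
#' @param species Species tag (free text, e.g. `"dm"`).
#' @param category Source tag, e.g. `"GO-BP-propagated"` or `"pathway"`.
#' @param set_names Optional named character vector of human-readable labels
#'   (defaults to the set ids).
#' @return Object of class `gene_set_collection` with elements `sets`
#'   (named list of sorted member vectors), `set_names`, `universe`,
#'   `collection_id`, `species`, `category`.
#' @export
gene_set_collection <- function(sets, collection_id = "collection",
                                species = NA_character_,
                                category = NA_character_,
                                set_names = NULL) {
  if (length(sets) && is.null(names(sets))) {
    stop("sets must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set ids: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(m) sort(unique(as.character(m))))
  sets <- sets[lengths(sets) > 0]
  if (is.null(names(sets))) names(sets) <- character(length(sets))
  sets <- sets[order(names(sets))]
  labels <- stats::setNames(names(sets), names(sets))
  if (!is.null(set_names)) {
    hit <- intersect(names(sets), names(set_names))
    labels[hit] <- set_names[hit]
  }
  structure(
    list(sets = sets, set_names = labels,
         universe = sort(unique(unlist(sets, use.names = FALSE))),
         collection_id = collection_id, species = species,
         category = category),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection '", x$collection_id, "' (category: ", x$category,
      ", species: ", x$species, ")\n", sep = "")
  cat(" ", length(x$sets), "sets,", length(x$universe), "genes in universe\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' One set per line: set id, description, then members, tab-separated.
#' Duplicate members within a line are stored once; duplicate set ids are an
#' error.
#'
#' @param path Path to a GMT file.
#' @inheritParams gene_set_collection
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, collection_id = basename(path),
                     species = NA_character_, category = "gmt") {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1], " has fewer than 3 fields",
         call. = FALSE)
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate GMT set id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  sets <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  descs <- stats::setNames(vapply(fields, `[`, character(1), 2L), ids)
  gene_set_collection(sets, collection_id = collection_id, species = species,
                      category = category, set_names = descs)
}

#' Write a collection as GMT plus a JSON sidecar
#'
#' The sidecar (same path with `.json` appended) records collection id,
#' category, species and per-set sizes, so provenance survives the GMT
#' round trip.
#'
#' @param collection A `gene_set_collection`.
#' @param path Output GMT path.
#' @param sidecar Write the JSON sidecar too (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, sidecar = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$set_names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  if (sidecar) {
    meta <- list(
      collection_id = collection$collection_id,
      species = collection$species,
      category = collection$category,
      n_sets = length(collection$sets),
      universe_size = length(collection$universe),
      set_sizes = as.list(stats::setNames(lengths(collection$sets), ids))
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Build GO-style gene sets from annotation records
#'
#' Constructs one gene set per ontology term from filtered annotation
#' records, either direct (a gene belongs only to the terms it is annotated
#' to) or propagated ("flattened": membership extends to every ancestor of
#' an annotated term). With a slim, membership is re-expressed on the slim
#' terms via [map_to_slim()] semantics.
#'
#' Records whose term is unknown to the ontology (after alternate-id
#' resolution) or obsolete are skipped with a warning and counted in the
#' `skipped` attribute of the result.
#'
#' @param records Annotation records ([read_gaf()] output), already passed
#'   through [filter_by_evidence()] (at minimum mode `"all"`, which removes
#'   `NOT` records; `build_go_sets` also drops any remaining `NOT` rows).
#' @param ontology An [read_obo()] ontology.
#' @param propagate Logical; extend membership to ancestor terms.
#' @param slim Optional character vector of slim term ids; when given, the
#'   returned sets are keyed by slim terms.
#' @param aspect Optional filter on the GAF aspect column
#'   (`"P"`, `"F"` or `"C"`) before building.
#' @inheritParams gene_set_collection
#' @return A [gene_set_collection()] whose sets are keyed by term id, with
#'   term names as labels and an integer attribute `skipped`.
#' @export
build_go_sets <- function(records, ontology, propagate = TRUE, slim = NULL,
                          aspect = NULL, collection_id = "go",
                          species = NA_character_,
                          category = if (propagate) "GO-propagated" else "GO-direct") {
  stopifnot(inherits(ontology, "ontology"))
  records <- records[!records$negated, , drop = FALSE]
  if (!is.null(aspect)) {
    records <- records[records$aspect %in% aspect, , drop = FALSE]
  }

  known <- c(ontology$terms$term_id, names(ontology$alt_ids))
  obsolete <- ontology$terms$term_id[ontology$terms$is_obsolete]
  term <- records$term_id
  prim <- ifelse(term %in% names(ontology$alt_ids),
                 unname(ontology$alt_ids[term]), term)
  ok <- term %in% known & !(prim %in% obsolete)
  skipped <- sum(!ok)
  if (skipped > 0) {
    warning(skipped, " record(s) skipped: term unknown to the ontology or obsolete",
            call. = FALSE)
  }
  records <- records[ok, , drop = FALSE]
  prim <- prim[ok]

  memb <- list()  # term -> genes, direct
  if (nrow(records)) {
    memb <- split(records$gene_id, prim)
  }

  if (propagate && length(memb)) {
    clo <- .ancestor_closure(ontology)
    prop <- new.env(parent = emptyenv())
    for (t in names(memb)) {
      for (tt in c(t, clo[[t]])) {
        prop[[tt]] <- c(prop[[tt]], memb[[t]])
      }
    }
    memb <- as.list(prop)
  }

  if (!is.null(slim)) {
    slim <- vapply(unique(slim), resolve_term, character(1),
                   ontology = ontology, USE.NAMES = FALSE)
    if (!propagate) {
      # re-express direct annotations on slim terms: each annotated term maps
      # upward onto the slim
      clo <- .ancestor_closure(ontology)
      src <- memb
      memb <- list()
      for (t in names(src)) {
        for (s in intersect(c(t, clo[[t]]), slim)) {
          memb[[s]] <- c(memb[[s]], src[[t]])
        }
      }
    } else {
      memb <- memb[intersect(names(memb), slim)]
    }
    if (is.na(category) || !grepl("slim", category)) {
      category <- paste0(category, "-slim")
    }
  }

  labels <- stats::setNames(ontology$terms$name, ontology$terms$term_id)
  out <- gene_set_collection(memb, collection_id = collection_id,
                             species = species, category = category,
                             set_names = labels)
  attr(out, "skipped") <- skipped
  out
}

#' Read a genotype-phenotype association table
#'
#' Tab-separated with header columns `genotype`, `gene_ids` (`|`-separated
#' gene ids implicated by the genotype), `allele_class` (e.g. `classical`,
#' `insertional`, `other`) and `phenotype_term_id`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with a list-column `gene_ids`.
#' @export
read_genotype_phenotype <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("genotype", "gene_ids", "allele_class", "phenotype_term_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("genotype-phenotype table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$gene_ids <- strsplit(df$gene_ids, "|", fixed = TRUE)
  df
}

#' Build phenotype gene sets under the single-allele rule
#'
#' Phenotypes are recorded against genotypes, which may perturb several
#' genes at once; only genotypes where the phenotype can be attributed to
#' the perturbation of exactly one gene through a single classical or
#' insertional allele contribute to set membership. When an ontology of
#' phenotype terms is supplied, membership is propagated to ancestor terms
#' as for GO.
#'
#' @param records Data frame from [read_genotype_phenotype()].
#' @param ontology Optional phenotype-vocabulary [read_obo()] ontology.
#' @inheritParams gene_set_collection
#' @return A [gene_set_collection()] with an attribute `n_excluded`, the
#'   count of records that did not qualify.
#' @export
build_phenotype_sets <- function(records, ontology = NULL,
                                 collection_id = "phenotype",
                                 species = NA_character_,
                                 category = "phenotype-single-allele") {
  qualifies <- lengths(records$gene_ids) == 1L &
    records$allele_class %in% c("classical", "insertional")
  used <- records[qualifies, , drop = FALSE]
  memb <- split(unlist(used$gene_ids, use.names = FALSE),
                used$phenotype_term_id)

  if (!is.null(ontology) && length(memb)) {
    known <- c(ontology$terms$term_id, names(ontology$alt_ids))
    unknown <- setdiff(names(memb), known)
    if (length(unknown)) {
      warning(length(unknown), " phenotype term(s) unknown to the ontology; ",
              "kept without propagation", call. = FALSE)
    }
    clo <- .ancestor_closure(ontology)
    prop <- new.env(parent = emptyenv())
    for (t in names(memb)) {
      tt <- if (t %in% known) resolve_term(ontology, t) else t
      for (a in c(tt, if (t %in% known) clo[[tt]])) {
        prop[[a]] <- c(prop[[a]], memb[[t]])
      }
    }
    memb <- as.list(prop)
  }

  labels <- if (!is.null(ontology)) {
    stats::setNames(ontology$terms$name, ontology$terms$term_id)
  } else NULL
  out <- gene_set_collection(memb, collection_id = collection_id,
                             species = species, category = category,
                             set_names = labels)
  attr(out, "n_excluded") <- sum(!qualifies)
  out
}
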