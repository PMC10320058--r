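#' Read an OBO ontology file
#'
#' Parses a flat OBO 1.2/1.4 file into a directed acyclic graph of terms.
#' Only the stanza keys needed for annotation propagation are retained:
#' `id`, `name`, `namespace`, `alt_id`, `is_a`, `relationship: part_of`,
#' `is_obsolete` and `subset`. Other relationship types (e.g. the
#' regulates family) are ignored, matching the conservative propagation
#' practice used for GO-style enrichment sets. `part_of` links are only
#' followed within a namespace, so propagation never crosses aspects.
#'
#' @param path Path to an OBO file.
#' @return An object of class `ontology`: a list with elements
#'   \describe{
#'     \item{terms}{data frame with columns `term_id`, `name`, `namespace`,
#'       `is_obsolete`.}
#'     \item{parents}{named list; for each term id, a named character vector
#'       of parent ids whose names give the relation (`is_a` or `part_of`).
#'       Obsolete terms have no parents.}
#'     \item{alt_ids}{named character vector mapping alternate ids to their
#'       primary term id.}
#'     \item{roots}{ids of non-obsolete terms with no parents.}
#'     \item{subsets}{named list mapping subset (slim) labels declared in the
#'       file to their member term ids.}
#'   }
#' @details Load fails with an informative error when a referenced parent id
#'   does not exist, when an `alt_id` collides with a primary id, or when the
#'   parent links contain a directed cycle (the offending terms are listed).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: T:1", "name: root", "namespace: demo", "",
#'   "[Term]", "id: T:2", "name: mid", "namespace: demo", "is_a: T:1", "",
#'   "[Term]", "id: T:3", "name: leaf", "namespace: demo", "is_a: T:2"
#' ), obo)
#' ont <- read_obo(obo)
#' term_ancestors(ont, "T:3")
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  term_id <- character()
  name <- character()
  namespace <- character()
  obsolete <- logical()
  parents <- list()
  alt_map <- character()
  subsets <- list()

  in_term <- FALSE
  cur <- NULL

  flush_term <- function(cur) {
    if (is.null(cur$id)) {
      stop("malformed [Term] stanza ending before line ", cur$line,
           ": missing id", call. = FALSE)
    }
    if (cur$id %in% term_id) {
      stop("duplicate term id '", cur$id, "' near line ", cur$line, call. = FALSE)
    }
    term_id <<- c(term_id, cur$id)
    name <<- c(name, cur$name %||% cur$id)
    namespace <<- c(namespace, cur$namespace %||% NA_character_)
    obsolete <<- c(obsolete, isTRUE(cur$obsolete))
    # obsolete terms contribute no propagation edges
    parents[[cur$id]] <<- if (isTRUE(cur$obsolete)) {
      stats::setNames(character(), character())
    } else {
      cur$parents
    }
    for (a in cur$alt_ids) alt_map[[a]] <<- cur$id
    for (s in cur$subsets) subsets[[s]] <<- c(subsets[[s]], cur$id)
    invisible(NULL)
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s*!.*$", "", lines[i])  # strip trailing comments
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      if (in_term) flush_term(cur)
      in_term <- identical(line, "[Term]")
      cur <- list(line = i, parents = stats::setNames(character(), character()),
                  alt_ids = character(), subsets = character())
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) == 0) {
      stop("malformed OBO line ", i, ": '", lines[i], "'", call. = FALSE)
    }
    key <- m[2]; val <- trimws(m[3])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "alt_id") cur$alt_ids <- c(cur$alt_ids, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
    else if (key == "subset") cur$subsets <- c(cur$subsets, val)
    else if (key == "is_a") {
      pid <- trimws(strsplit(val, "!", fixed = TRUE)[[1]][1])
      cur$parents <- c(cur$parents, stats::setNames(pid, "is_a"))
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2) {
        stop("malformed relationship on line ", i, ": '", lines[i], "'",
             call. = FALSE)
      }
      if (parts[1] == "part_of") {
        cur$parents <- c(cur$parents, stats::setNames(parts[2], "part_of"))
      }
    }
    # other keys (def, synonym, xref, ...) are ignored
  }
  if (in_term) flush_term(cur)

  if (length(term_id) == 0) stop("no [Term] stanzas found in ", path, call. = FALSE)

  bad_alt <- intersect(names(alt_map), term_id)
  if (length(bad_alt)) {
    stop("alt_id collides with a primary term id: ",
         paste(bad_alt, collapse = ", "), call. = FALSE)
  }

  ns <- stats::setNames(namespace, term_id)
  for (t in term_id) {
    p <- parents[[t]]
    missing <- setdiff(p, term_id)
    if (length(missing)) {
      stop("term '", t, "' references unknown parent(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    # part_of is confined to the term's own namespace
    keep <- names(p) != "part_of" | is.na(ns[p]) | is.na(ns[[t]]) | ns[p] == ns[[t]]
    parents[[t]] <- p[keep]
  }

  ont <- structure(
    list(
      terms = data.frame(term_id = term_id, name = name, namespace = namespace,
                         is_obsolete = obsolete, stringsAsFactors = FALSE),
      parents = parents,
      alt_ids = alt_map,
      roots = term_id[!obsolete & vapply(parents[term_id], length, 1L) == 0],
      subsets = subsets
    ),
    class = "ontology"
  )

  cyc <- .find_cycle(ont)
  if (!is.null(cyc)) {
    stop("ontology parent links contain a cycle: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  ont
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kahn's algorithm; returns NULL if acyclic, else the ids left in the cycle.
.find_cycle <- function(ontology) {
  ids <- ontology$terms$term_id
  indeg <- stats::setNames(integer(length(ids)), ids)  # number of parents
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) {
    for (p in unique(unname(ontology$parents[[t]]))) {
      children[[p]] <- c(children[[p]], t)
      indeg[[t]] <- indeg[[t]] + 1L
    }
  }
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(ids)) NULL else names(indeg)[indeg > 0L]
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology:", nrow(x$terms), "terms (",
      sum(x$terms$is_obsolete), "obsolete ),",
      length(x$roots), "root(s),",
      length(x$alt_ids), "alt id(s)\n")
  ns <- table(x$terms$namespace, useNA = "ifany")
  if (length(ns)) {
    cat("namespaces:", paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Resolve a term id, following alternate ids
#'
#' @param ontology An `ontology` object.
#' @param term_id A term accession, primary or alternate.
#' @return The primary term id.
#' @export
resolve_term <- function(ontology, term_id) {
  stopifnot(inherits(ontology, "ontology"))
  if (term_id %in% ontology$terms$term_id) return(term_id)
  if (term_id %in% names(ontology$alt_ids)) return(unname(ontology$alt_ids[[term_id]]))
  stop("unknown term id: ", term_id, call. = FALSE)
}

#' Ancestors of a term
#'
#' All terms reachable from `term_id` by following `is_a` and `part_of`
#' links upward, excluding the query term itself.
#'
#' @inheritParams resolve_term
#' @return Character vector of ancestor term ids (sorted, no duplicates).
#' @export
term_ancestors <- function(ontology, term_id) {
  id <- resolve_term(ontology, term_id)
  seen <- character()
  frontier <- unique(unname(ontology$parents[[id]]))
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(lapply(frontier, function(p)
      unname(ontology$parents[[p]])), use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

# Ancestor closure for every non-obsolete term, computed once by dynamic
# programming in topological order. Used by the set builders.
.ancestor_closure <- function(ontology) {
  ids <- ontology$terms$term_id
  order <- .topo_order(ontology)
  clo <- stats::setNames(vector("list", length(ids)), ids)
  for (t in order) {  # parents before children
    ps <- unique(unname(ontology$parents[[t]]))
    clo[[t]] <- sort(unique(c(ps, unlist(clo[ps], use.names = FALSE))))
  }
  clo
}

# topological order with parents first
.topo_order <- function(ontology) {
  ids <- ontology$terms$term_id
  indeg <- stats::setNames(integer(length(ids)), ids)
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) {
    for (p in unique(unname(ontology$parents[[t]]))) {
      children[[p]] <- c(children[[p]], t)
      indeg[[t]] <- indeg[[t]] + 1L
    }
  }
  queue <- sort(ids[indeg == 0L])
  out <- character()
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Read a slim subset from a one-column text file
#'
#' One term id per line; blank lines and `#` comments ignored. The slim can
#' also come from the `subset:` tags of the ontology itself (see the
#' `subsets` element of [read_obo()]'s return value).
#'
#' @param path Path to the file.
#' @param ontology Optional `ontology`; when given, member ids are resolved
#'   through alternate ids and unknown ids raise an error.
#' @return Character vector of slim member term ids.
#' @export
read_slim <- function(path, ontology = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  ids <- unique(lines)
  if (!is.null(ontology)) {
    ids <- vapply(ids, resolve_term, character(1), ontology = ontology,
                  USE.NAMES = FALSE)
  }
  ids
}

#' Map a term onto a slim subset
#'
#' Returns the slim terms among the term itself and its ancestors
#' (propagate-then-intersect semantics, so a term can map to several slim
#' terms or to none).
#'
#' @inheritParams resolve_term
#' @param slim Character vector of slim member term ids.
#' @return Character vector (possibly empty) of slim term ids.
#' @export
map_to_slim <- function(ontology, term_id, slim) {
  id <- resolve_term(ontology, term_id)
  slim <- vapply(unique(slim), resolve_term, character(1),
                 ontology = ontology, USE.NAMES = FALSE)
  sort(intersect(c(id, term_ancestors(ontology, id)), slim))
}
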