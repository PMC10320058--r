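#' Read a GAF gene-association file
#'
#' Parses GAF 2.1/2.2: 17 tab-separated columns, comment lines starting with
#' `!`. Only the columns used for set construction are kept.
#'
#' @param path Path to a GAF file.
#' @return A data frame of annotation records with columns `gene_id`
#'   (DB object id, column 2), `gene_symbol` (column 3), `qualifiers`
#'   (`|`-joined string, column 4), `negated` (logical; `TRUE` when a `NOT`
#'   qualifier is present), `term_id` (column 5), `evidence_code` (column 7)
#'   and `aspect` (column 9, one of `P`/`F`/`C`).
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop("GAF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(.empty_gaf())
  # sentinel keeps trailing empty columns, which strsplit would drop
  fields <- strsplit(paste0(lines[idx], "\t\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  nf <- lengths(fields)
  bad <- nf != 17L
  if (any(bad)) {
    stop("GAF line ", idx[which(bad)[1]], " has ", nf[which(bad)[1]],
         " columns (expected 17)", call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 17L, byrow = TRUE)
  quals <- m[, 4]
  data.frame(
    gene_id = m[, 2],
    gene_symbol = m[, 3],
    qualifiers = quals,
    negated = vapply(strsplit(quals, "|", fixed = TRUE),
                     function(q) "NOT" %in% q, logical(1)),
    term_id = m[, 5],
    evidence_code = m[, 7],
    aspect = m[, 9],
    stringsAsFactors = FALSE
  )
}

.empty_gaf <- function() {
  data.frame(gene_id = character(), gene_symbol = character(),
             qualifiers = character(), negated = logical(),
             term_id = character(), evidence_code = character(),
             aspect = character(), stringsAsFactors = FALSE)
}

#' Evidence-code groups used for annotation filtering
#'
#' `computational_codes` are annotations based only on phylogenetic, sequence
#' or structural similarity and other computational analyses;
#' `htp_codes` are the high-throughput experiment codes.
#'
#' @format Named list with character vectors `computational` and `htp`.
#' @export
evidence_code_groups <- list(
  computational = c("IEA", "IBA", "IBD", "IKR", "IRD", "ISS", "ISO", "ISA",
                    "ISM", "IGC", "RCA"),
  htp = c("HTP", "HDA", "HMP", "HGI", "HEP")
)

#' Filter annotation records by evidence code
#'
#' Filtering operates at the (gene, term) pair level: a pair is dropped only
#' when *every* record supporting it carries an excluded code, so a pair
#' supported by both a computational and an experimental code survives the
#' experimental-only filter. `NOT`-qualified records are always removed
#' first; they never contribute to set membership.
#'
#' @param records Data frame as returned by [read_gaf()].
#' @param mode One of `"all"` (drop only `NOT` records),
#'   `"experimental_only"` (drop pairs supported solely by computational
#'   codes) or `"exclude_htp_only"` (drop pairs supported solely by
#'   high-throughput codes).
#' @return The surviving records (all rows of every surviving pair).
#' @examples
#' rec <- data.frame(gene_id = c("g1", "g1", "g2"),
#'                   gene_symbol = c("g1", "g1", "g2"),
#'                   qualifiers = "", negated = FALSE,
#'                   term_id = c("T:1", "T:1", "T:1"),
#'                   evidence_code = c("IEA", "IDA", "IEA"),
#'                   aspect = "P")
#' # g1/T:1 has direct-assay support and survives; g2/T:1 is IEA-only
#' filter_by_evidence(rec, "experimental_only")$gene_id
#' @export
filter_by_evidence <- function(records,
                               mode = c("all", "experimental_only",
                                        "exclude_htp_only")) {
  mode <- match.arg(mode)
  records <- records[!records$negated, , drop = FALSE]
  if (mode == "all" || nrow(records) == 0) return(records)
  excluded <- switch(mode,
    experimental_only = evidence_code_groups$computational,
    exclude_htp_only = evidence_code_groups$htp
  )
  pair <- paste(records$gene_id, records$term_id, sep = "\r")
  drop_pair <- tapply(records$evidence_code, pair,
                      function(codes) all(codes %in% excluded))
  records[!drop_pair[pair], , drop = FALSE]
}
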