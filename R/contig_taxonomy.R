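# Contig-level taxonomy: parse assignment tables (centrifuge-style), drop
# ambiguous contigs, and resolve lineage labels at a requested rank.

RANK_ORDER <- c("superkingdom", "phylum", "class", "order", "family",
                "genus", "species")

#' Read a contig-to-taxon assignment table
#'
#' Tab-separated, at least three columns: contig id, taxon id, score. A header
#' line is detected and skipped when the third field is not numeric.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `contig_id`, `taxon_id`, `score`.
#' @export
read_taxon_assignments <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(contig_id = character(), taxon_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t", fixed = TRUE)[[1L]]
  if (length(first) < 3L) stop("assignment table needs >= 3 columns")
  has_header <- is.na(suppressWarnings(as.numeric(first[3L])))
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          colClasses = list(character = 1:2))
  dt <- dt[, 1:3, with = FALSE]
  data.table::setnames(dt, c("contig_id", "taxon_id", "score"))
  dt[, score := as.numeric(score)]
  if (any(dt$score < 0, na.rm = TRUE)) stop("negative assignment score")
  data.table::setDF(dt)
  dt
}

#' Remove contigs with ambiguous taxonomic assignments
#'
#' A contig is kept if and only if exactly one taxon attains the maximum
#' assignment score for that contig; ties are discarded entirely (no LCA
#' resolution by default). Idempotent.
#'
#' @param rows data.frame with columns `contig_id`, `taxon_id`, `score`.
#' @param lca_ties if `TRUE`, tied contigs are not dropped but assigned the
#'   lexicographically smallest tied taxon id (a crude stand-in for LCA
#'   resolution; off by default because ambiguous contigs are filtered out).
#' @return data.frame with columns `contig_id`, `taxon_id`, one row per kept
#'   contig, ordered by contig id.
#' @export
filter_ambiguous <- function(rows, lca_ties = FALSE) {
  dt <- data.table::as.data.table(rows)
  if (nrow(dt) == 0L) {
    return(data.frame(contig_id = character(), taxon_id = character(),
                      stringsAsFactors = FALSE))
  }
  dt <- dt[, .(contig_id, taxon_id = as.character(taxon_id), score)]
  top <- dt[, .SD[score == max(score)], by = contig_id]
  top <- unique(top, by = c("contig_id", "taxon_id"))
  n_top <- top[, .N, by = contig_id]
  if (lca_ties) {
    keep <- top[order(contig_id, taxon_id), .SD[1L], by = contig_id]
  } else {
    keep <- top[contig_id %in% n_top[N == 1L, contig_id]]
  }
  out <- keep[order(contig_id), .(contig_id, taxon_id)]
  data.table::setDF(out)
  out
}

#' Read a taxonomy lineage table
#'
#' Tab-separated columns: taxon id, parent id, rank, name (a flattened
#' nodes/names-style dialect). The root is any node whose parent equals its
#' own id or is empty.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `taxon_id`, `parent_id`, `rank`, `name`.
#' @export
read_taxonomy <- function(path) {
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t", fixed = TRUE)[[1L]]
  has_header <- identical(tolower(first[1L]), "taxon_id")
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 4L) {
    stop("taxonomy table needs 4 columns (taxon_id, parent_id, rank, name)")
  }
  dt <- dt[, 1:4, with = FALSE]
  data.table::setnames(dt, c("taxon_id", "parent_id", "rank", "name"))
  if (anyDuplicated(dt$taxon_id)) stop("duplicate taxon_id in taxonomy table")
  data.table::setDF(dt)
  dt
}

# Walk parent links from each taxon until a node of `rank` is found.
# Returns a data.frame (taxon_id at rank, name at rank); NA when the walk
# reaches the root without meeting the rank. Cycles raise an error.
lineage_node_at_rank <- function(taxon_ids, rank, taxonomy) {
  parent <- stats::setNames(taxonomy$parent_id, taxonomy$taxon_id)
  ranks <- stats::setNames(taxonomy$rank, taxonomy$taxon_id)
  names_ <- stats::setNames(taxonomy$name, taxonomy$taxon_id)
  uids <- unique(as.character(taxon_ids))
  unknown <- uids[!is.na(uids) & !(uids %in% names(parent))]
  if (length(unknown)) {
    stop("unknown taxon id(s): ", paste(unknown, collapse = ", "))
  }
  walk_one <- function(id) {
    if (is.na(id)) return(c(NA_character_, NA_character_))
    cur <- id
    for (step in seq_len(length(parent) + 1L)) {
      if (identical(ranks[[cur]], rank)) return(c(cur, names_[[cur]]))
      nxt <- parent[[cur]]
      if (is.na(nxt) || !nzchar(nxt) || identical(nxt, cur)) {
        return(c(NA_character_, NA_character_))
      }
      if (!(nxt %in% names(parent))) {
        stop("taxonomy table is broken: parent ", nxt, " of ", cur,
             " is not a node")
      }
      cur <- nxt
    }
    stop("cycle detected in taxonomy table at node ", id)
  }
  res <- vapply(uids, walk_one, character(2))
  idx <- match(as.character(taxon_ids), uids)
  data.frame(taxon_id = unname(res[1L, idx]), name = unname(res[2L, idx]),
             stringsAsFactors = FALSE)
}

#' Resolve the lineage name of a taxon at a requested rank
#'
#' Walks parent links upward until a node with the requested rank is reached;
#' returns `NA` if the root is reached first (the lineage lacks that rank).
#'
#' @param taxon_id character vector of taxon ids (vectorized).
#' @param rank requested rank, e.g. `"genus"` or `"species"`.
#' @param taxonomy taxonomy table from [read_taxonomy()].
#' @return character vector of names at `rank` (NA where absent).
#' @export
lineage_at_rank <- function(taxon_id, rank, taxonomy) {
  lineage_node_at_rank(taxon_id, rank, taxonomy)$name
}

#' Resolve contig taxa from an assignment table
#'
#' Applies the ambiguity filter, then (optionally) retains contigs with no
#' assignment at all as unclassified (`taxon_id = NA`) so that their read
#' mass still contributes to per-sample totals.
#'
#' @param assignments data.frame from [read_taxon_assignments()].
#' @param contig_ids all contig ids in the sample; required to reinstate
#'   unassigned contigs. If `NULL`, only assigned contigs are returned.
#' @param drop_unassigned drop contigs that have no assignment row.
#' @return data.frame with columns `contig_id`, `taxon_id` (NA = unclassified).
#'   Ambiguously assigned contigs are absent.
#' @export
assign_contig_taxa <- function(assignments, contig_ids = NULL,
                               drop_unassigned = FALSE) {
  kept <- filter_ambiguous(assignments)
  if (!is.null(contig_ids) && !drop_unassigned) {
    seen <- unique(as.character(assignments$contig_id))
    missing <- setdiff(contig_ids, seen)
    if (length(missing)) {
      kept <- rbind(kept, data.frame(contig_id = missing,
                                     taxon_id = NA_character_,
                                     stringsAsFactors = FALSE))
    }
    kept <- kept[order(kept$contig_id), , drop = FALSE]
    rownames(kept) <- NULL
  }
  kept
}
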