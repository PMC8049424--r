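# Tabularization: merge per-sample profiles into a samples x joint-features
# matrix and aggregate profiles across taxonomic ranks.

#' Merge per-sample profiles into a feature table
#'
#' Builds the union of feature keys (`"TaxonLabel|GeneId"`) over all
#' profiles; a (sample, feature) pair absent from a profile is a true zero
#' (the gene was not observed in that sample). Column order follows the
#' input order; rows are sorted by key.
#'
#' @param profiles named list of profile data.frames ([profile_sample()] or
#'   [read_profile_tsv()]); names are the sample ids.
#' @param stat which statistic fills the matrix: `"mean_depth"`, `"fpkm"`,
#'   `"depth_per_genome"` or `"fragment_count"`.
#' @return numeric matrix, rows = feature keys, columns = samples.
#' @export
merge_profiles <- function(profiles, stat = "mean_depth") {
  if (length(profiles) == 0L) {
    return(matrix(numeric(), nrow = 0L, ncol = 0L))
  }
  ids <- names(profiles)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("profiles must be a named list (names = sample ids)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "))
  }
  keyed <- lapply(profiles, function(p) {
    if (!stat %in% names(p)) stop("profile lacks statistic '", stat, "'")
    data.frame(key = feature_key(p$taxon_label, p$gene_id),
               value = as.numeric(p[[stat]]), stringsAsFactors = FALSE)
  })
  keys <- sort(unique(unlist(lapply(keyed, `[[`, "key"))))
  mat <- matrix(0, nrow = length(keys), ncol = length(ids),
                dimnames = list(keys, ids))
  for (j in seq_along(keyed)) {
    k <- keyed[[j]]
    v <- k$value
    v[is.na(v)] <- 0
    mat[k$key, j] <- v
  }
  mat
}

#' Aggregate a joint profile to a higher taxonomic rank
#'
#' Relabels features at `to_rank` via the lineage walk and pools them:
#' fragment counts, aligned bases and region lengths are summed (total
#' fragment count is conserved); mean depth follows the profile's
#' aggregation mode (`"sum"`: per-feature mean depths add, `"pool"`:
#' recomputed from pooled aligned bases over pooled region length); FPKM and
#' depth-per-genome are recomputed from the pooled quantities. Features whose
#' lineage lacks `to_rank` are bucketed under `"unclassified"`.
#'
#' @param profile a profile from [profile_sample()].
#' @param to_rank target rank; must not be below the profile's rank.
#' @param taxonomy taxonomy table from [read_taxonomy()].
#' @return a profile data.frame at `to_rank`, same shape and attributes.
#' @export
aggregate_rank <- function(profile, to_rank, taxonomy) {
  from_rank <- attr(profile, "rank")
  mode <- attr(profile, "mode") %||% "sum"
  total_fragments <- attr(profile, "total_fragments")
  gs <- attr(profile, "genome_stats")
  if (!is.null(from_rank)) {
    fi <- match(from_rank, RANK_ORDER)
    ti <- match(to_rank, RANK_ORDER)
    if (!is.na(fi) && !is.na(ti)) {
      if (ti > fi) stop("to_rank '", to_rank, "' is below the profile rank '",
                        from_rank, "'")
      if (ti == fi) return(profile)
    }
  }
  dt <- data.table::as.data.table(profile)
  node <- lineage_node_at_rank(dt$taxon_id, to_rank, taxonomy)
  dt[, `:=`(new_id = node$taxon_id,
            new_label = ifelse(is.na(node$name), UNCLASSIFIED, node$name))]
  out <- dt[, .(
    fragment_count = sum(fragment_count),
    aligned_bases = sum(aligned_bases),
    region_length = sum(region_length),
    mean_depth = if (mode == "sum") sum(mean_depth)
                 else sum(aligned_bases) / sum(region_length)
  ), by = .(taxon_id = new_id, taxon_label = new_label, gene_id)]
  if (!is.null(total_fragments) && total_fragments > 0) {
    out[, fpkm := fpkm(fragment_count, region_length, total_fragments)]
  } else {
    out[, fpkm := NA_real_]
  }
  if (!is.null(gs)) {
    gdt <- data.table::as.data.table(gs)
    gnode <- lineage_node_at_rank(gdt$taxon_id, to_rank, taxonomy)
    gdt[, `:=`(taxon_id = gnode$taxon_id,
               taxon_label = ifelse(is.na(gnode$name), UNCLASSIFIED,
                                    gnode$name))]
    gagg <- gdt[, .(genome_length = sum(genome_length),
                    genome_aligned_bases = sum(genome_aligned_bases)),
                by = .(taxon_id, taxon_label)]
    gagg[, genome_depth := genome_aligned_bases / genome_length]
    out <- merge(out, gagg[, .(taxon_label, genome_depth)],
                 by = "taxon_label", all.x = TRUE)
    out[, depth_per_genome := depth_per_genome(mean_depth, genome_depth)]
    out[, genome_depth := NULL]
    gs_out <- data.table::setDF(gagg)
  } else {
    out[, depth_per_genome := NA_real_]
    gs_out <- NULL
  }
  data.table::setorder(out, taxon_label, gene_id)
  data.table::setcolorder(out, c("taxon_id", "taxon_label", "gene_id"))
  data.table::setDF(out)
  structure(out, rank = to_rank, mode = mode,
            total_fragments = total_fragments, genome_stats = gs_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
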