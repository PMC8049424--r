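# Core joint-profiling algorithm: combine contig taxonomy, gene regions and
# read alignments into per-sample (taxon, gene) abundances with three
# normalizations: mean depth, FPKM, depth per genome.

UNCLASSIFIED <- "unclassified"

#' Count fragments and aligned bases over gene regions
#'
#' A fragment (template) counts once for a region when any of its read
#' intervals overlaps the region by at least one base; `aligned_bases` sums
#' the per-base overlap of all its intervals clipped to the region. A
#' fragment overlapping several regions counts for each of them.
#'
#' @param fragments data.frame from [read_sam_fragments()].
#' @param regions data.frame of gene regions ([derive_gene_regions()]); any
#'   data.frame with `contig_id`, `start`, `end` works.
#' @return `regions` with added `fragment_count` and `aligned_bases` columns.
#' @export
region_depth <- function(fragments, regions) {
  out <- data.table::as.data.table(regions)
  out[, `:=`(fragment_count = 0L, aligned_bases = 0)]
  if (nrow(out) == 0L || nrow(fragments) == 0L) {
    data.table::setDF(out)
    return(out)
  }
  fr <- data.table::as.data.table(fragments)[, .(fragment_id, contig_id, start, end)]
  rg <- out[, .(contig_id, start, end)]
  rg[, region_idx := .I]
  data.table::setkey(fr, contig_id, start, end)
  ov <- data.table::foverlaps(rg, fr, type = "any", nomatch = NULL)
  if (nrow(ov) > 0L) {
    # i.start/i.end are the region's bounds, start/end the fragment read's
    ov[, width := pmin(end, i.end) - pmax(start, i.start) + 1L]
    stats <- ov[, .(fragment_count = data.table::uniqueN(fragment_id),
                    aligned_bases = sum(as.numeric(width))), by = region_idx]
    out[stats$region_idx, `:=`(fragment_count = stats$fragment_count,
                               aligned_bases = stats$aligned_bases)]
  }
  data.table::setDF(out)
  out
}

#' Mean depth of a region
#'
#' Aligned bases divided by region length: the average per-base read coverage
#' of the region.
#'
#' @param aligned_bases total bases of read intervals clipped to the region.
#' @param region_length region length in bp (> 0).
#' @return mean depth (vectorized).
#' @export
mean_depth <- function(aligned_bases, region_length) {
  if (any(region_length <= 0)) stop("region_length must be > 0")
  aligned_bases / region_length
}

#' Fragments per kilobase per million mapped fragments
#'
#' `fragment_count * 1e9 / (region_length_bp * total_mapped_fragments)`.
#'
#' @param fragment_count fragments overlapping the region.
#' @param region_length_bp region length in bp.
#' @param total_mapped_fragments distinct mapped fragments in the sample (> 0).
#' @return FPKM (vectorized).
#' @export
fpkm <- function(fragment_count, region_length_bp, total_mapped_fragments) {
  if (any(total_mapped_fragments <= 0)) {
    stop("total_mapped_fragments must be > 0")
  }
  fragment_count * 1e9 / (region_length_bp * total_mapped_fragments)
}

#' Depth per genome (gene copies per genome)
#'
#' A gene's mean depth divided by the genome-wide mean depth of its taxon
#' (total aligned bases on the taxon's contigs over their total length).
#' Under uniform coverage this estimates the gene's copy number per genome.
#'
#' @param gene_mean_depth mean depth of the gene feature.
#' @param taxon_genome_mean_depth genome-wide mean depth of the taxon.
#' @return depth per genome; `NA` where the genome depth is zero (undefined).
#' @export
depth_per_genome <- function(gene_mean_depth, taxon_genome_mean_depth) {
  ifelse(taxon_genome_mean_depth > 0,
         gene_mean_depth / taxon_genome_mean_depth, NA_real_)
}

#' Profile one sample into joint (taxon, gene) features
#'
#' Regions on contigs removed by the ambiguity filter (absent from
#' `contig_taxa`) are dropped; remaining regions are labelled at `rank` via
#' the taxonomy (contigs whose lineage lacks the rank, or with `NA` taxon,
#' become `"unclassified"`) and their depth statistics aggregated per
#' (taxon label, gene id).
#'
#' Aggregation over several regions of the same feature (gene copies) has two
#' modes. `"sum"` (default) adds the per-region mean depths, so a two-copy
#' gene at 10x coverage reports mean depth 20 and depth-per-genome 2 -- the
#' additive abundance that matches a planted-copy-number truth. `"pool"`
#' divides the pooled aligned bases by the pooled region length, reporting
#' the average coverage across copies instead.
#'
#' @param contigs contig sequences (data.frame with `id`, `seq`) or lengths
#'   (data.frame with `id`, `length`).
#' @param contig_taxa data.frame from [assign_contig_taxa()].
#' @param gene_regions data.frame from [derive_gene_regions()].
#' @param fragments data.frame from [read_sam_fragments()].
#' @param taxonomy taxonomy table from [read_taxonomy()].
#' @param rank aggregation rank (default `"species"`).
#' @param mode multi-region aggregation, `"sum"` or `"pool"` (see above).
#' @param drop_zeros drop features with zero fragments.
#' @param total_fragments override the FPKM denominator; default = number of
#'   distinct mapped fragment ids in `fragments`.
#' @return data.frame with one row per (taxon label, gene id), columns
#'   `taxon_id` (lineage node at `rank`; NA for unclassified), `taxon_label`,
#'   `gene_id`, `fragment_count`, `aligned_bases`, `region_length`,
#'   `mean_depth`, `fpkm`, `depth_per_genome`, ordered by taxon then gene.
#'   Attributes: `rank`, `mode`, `total_fragments`, `genome_stats`.
#' @export
profile_sample <- function(contigs, contig_taxa, gene_regions, fragments,
                           taxonomy, rank = "species",
                           mode = c("sum", "pool"), drop_zeros = FALSE,
                           total_fragments = NULL) {
  mode <- match.arg(mode)
  clen <- if ("length" %in% names(contigs)) {
    stats::setNames(as.numeric(contigs$length), contigs$id)
  } else {
    stats::setNames(nchar(contigs$seq), contigs$id)
  }
  for (what in list(c("gene regions", "gene_regions"),
                    c("fragments", "fragments"),
                    c("contig taxa", "contig_taxa"))) {
    df <- get(what[2L])
    bad <- setdiff(unique(df$contig_id), names(clen))
    if (length(bad)) {
      stop(what[1L], " reference unknown contig id(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  frags <- data.table::as.data.table(fragments)
  if (is.null(total_fragments)) {
    total_fragments <- data.table::uniqueN(frags$fragment_id)
  }

  # label each retained contig at the requested rank
  ct <- data.table::as.data.table(contig_taxa)
  node <- lineage_node_at_rank(ct$taxon_id, rank, taxonomy)
  ct[, `:=`(rank_id = node$taxon_id,
            rank_label = ifelse(is.na(node$name), UNCLASSIFIED, node$name))]

  regions <- data.table::as.data.table(gene_regions)
  regions <- regions[contig_id %in% ct$contig_id]  # ambiguous contigs dropped
  regions <- region_depth(frags, regions)
  regions <- data.table::as.data.table(regions)
  regions[, region_length := end - start + 1L]
  regions <- merge(regions, ct[, .(contig_id, rank_id, rank_label)],
                   by = "contig_id")

  prof <- regions[, .(
    fragment_count = sum(fragment_count),
    aligned_bases = sum(aligned_bases),
    region_length = sum(as.numeric(region_length)),
    mean_depth = if (mode == "sum") sum(aligned_bases / region_length)
                 else sum(aligned_bases) / sum(as.numeric(region_length))
  ), by = .(taxon_id = rank_id, taxon_label = rank_label, gene_id)]

  # genome-wide depth per taxon label over its retained contigs
  frags_lab <- merge(frags, ct[, .(contig_id, rank_id, rank_label)],
                     by = "contig_id")
  gab <- frags_lab[, .(genome_aligned_bases =
                         sum(as.numeric(end - start + 1L))),
                   by = .(taxon_id = rank_id, taxon_label = rank_label)]
  glen <- ct[, .(genome_length = sum(clen[contig_id])),
             by = .(taxon_id = rank_id, taxon_label = rank_label)]
  gs <- merge(glen, gab, by = c("taxon_id", "taxon_label"), all.x = TRUE)
  gs[is.na(genome_aligned_bases), genome_aligned_bases := 0]
  gs[, genome_depth := genome_aligned_bases / genome_length]

  prof <- merge(prof, gs[, .(taxon_label, genome_depth)],
                by = "taxon_label", all.x = TRUE)
  if (total_fragments > 0) {
    prof[, fpkm := fpkm(fragment_count, region_length, total_fragments)]
  } else {
    prof[, fpkm := NA_real_]
  }
  prof[, depth_per_genome := depth_per_genome(mean_depth, genome_depth)]
  prof[, genome_depth := NULL]
  if (drop_zeros) prof <- prof[fragment_count > 0L]
  data.table::setorder(prof, taxon_label, gene_id)
  data.table::setcolorder(prof, c("taxon_id", "taxon_label", "gene_id"))
  data.table::setDF(prof)
  data.table::setDF(gs)
  structure(prof, rank = rank, mode = mode,
            total_fragments = total_fragments, genome_stats = gs)
}

#' Run the full joint-profiling pipeline from files
#'
#' Reads contigs, taxonomic assignments (ambiguity-filtered), a taxonomy
#' table, protein alignments (coverage-filtered) and a SAM file, detects
#' ORFs, derives gene regions and profiles the sample.
#'
#' @param contigs_path FASTA of contigs.
#' @param taxa_path contig-to-taxon assignment TSV.
#' @param taxonomy_path taxonomy lineage TSV.
#' @param proteins_path tabular protein alignments (12/13 columns).
#' @param sam_path SAM of reads aligned to the contigs.
#' @param gene_map_path optional subject-to-gene TSV.
#' @param subject_lengths optional subject-length table for 12-column input.
#' @param rank aggregation rank.
#' @param min_coverage minimum subject coverage for protein alignments.
#' @param min_mapq minimum read mapping quality.
#' @param min_codons minimum ORF length in codons.
#' @param mode multi-region aggregation mode (see [profile_sample()]).
#' @param drop_zeros drop zero-fragment features.
#' @return the profile data.frame from [profile_sample()].
#' @export
profile_metagenome <- function(contigs_path, taxa_path, taxonomy_path,
                               proteins_path, sam_path, gene_map_path = NULL,
                               subject_lengths = NULL, rank = "species",
                               min_coverage = 0.8, min_mapq = 0L,
                               min_codons = 30L, mode = "sum",
                               drop_zeros = FALSE) {
  contigs <- read_fasta(contigs_path)
  taxonomy <- read_taxonomy(taxonomy_path)
  assignments <- read_taxon_assignments(taxa_path)
  contig_taxa <- assign_contig_taxa(assignments, contigs$id)
  orfs <- find_orfs(contigs, min_codons = min_codons, translate = FALSE)
  aligns <- read_protein_alignments(proteins_path, subject_lengths)
  aligns <- filter_by_coverage(aligns, min_coverage)
  gene_map <- if (!is.null(gene_map_path)) read_gene_map(gene_map_path)
  regions <- derive_gene_regions(orfs, aligns, gene_map)
  fragments <- read_sam_fragments(sam_path, min_mapq = min_mapq)
  profile_sample(contigs, contig_taxa, regions, fragments, taxonomy,
                 rank = rank, mode = mode, drop_zeros = drop_zeros)
}
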