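# Synthetic community generator: plants gene cassettes at known copy number
# in random genome backgrounds, simulates error-free paired fragments at a
# target coverage, and emits every pipeline input format together with the
# exact ground truth (true abundance = coverage x copy number). Replaces
# assembler + aligners for testing: fragments are emitted directly as SAM
# records carrying their true coordinates.

CASSETTE_CODONS <- 300L  # 900 bp: start codon + 298 internal codons + stop

#' Specification of a synthetic community
#'
#' @param n_species number of species (one genome each; species are grouped
#'   two-per-genus so rank aggregation is exercised).
#' @param genome_length genome length in bp (one contig per genome).
#' @param genes_per_genome number of distinct planted genes per genome.
#' @param copy_min,copy_max inclusive range of gene copy numbers.
#' @param coverage target fold coverage of read bases (default 10).
#' @param read_length read length in bp (default 100).
#' @param fragment_mean,fragment_sd fragment size distribution, bp
#'   (default 200 +/- 50); lengths are truncated to
#'   `[read_length, 3 * fragment_mean]`.
#' @param error_rate per-base substitution rate applied to read sequences
#'   (positions are never perturbed; default 0).
#' @param seed RNG seed; the whole community and its reads are reproducible
#'   from it.
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_species = 20L, genome_length = 300000L,
                           genes_per_genome = 50L, copy_min = 1L,
                           copy_max = 5L, coverage = 10, read_length = 100L,
                           fragment_mean = 200L, fragment_sd = 50L,
                           error_rate = 0, seed = 42L) {
  stopifnot(n_species >= 1L, genes_per_genome >= 1L, copy_min >= 1L,
            copy_max >= copy_min, coverage >= 0, read_length >= 1L,
            fragment_mean >= read_length, fragment_sd >= 0,
            error_rate >= 0, error_rate <= 1)
  structure(list(n_species = as.integer(n_species),
                 genome_length = as.integer(genome_length),
                 genes_per_genome = as.integer(genes_per_genome),
                 copy_min = as.integer(copy_min),
                 copy_max = as.integer(copy_max),
                 coverage = coverage,
                 read_length = as.integer(read_length),
                 fragment_mean = as.integer(fragment_mean),
                 fragment_sd = as.numeric(fragment_sd),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "community_spec")
}

random_cassette <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, CASSETTE_CODONS - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

#' Generate a synthetic community with planted gene copy numbers
#'
#' Each genome is a random ACGT background into which 900-bp gene cassettes
#' (start codon, 298 stop-free sense codons, stop codon) are inserted at
#' disjoint positions, on a random strand, with a copy number drawn uniformly
#' from `[copy_min, copy_max]` per (species, gene). Byte-identical output for
#' a fixed seed.
#'
#' @param spec a [community_spec()].
#' @return a `synthetic_community` list with elements `spec`, `contigs`
#'   (data.frame `id`, `taxon_id`, `seq`; one contig per genome), `genes`
#'   (planted cassette coordinates: `contig_id`, `gene_id`, `start`, `end`,
#'   `strand`), `taxonomy` (lineage table), `truth` (`taxon_id`,
#'   `taxon_name`, `gene_id`, `copy_number`,
#'   `true_abundance = coverage * copy_number`).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n <- spec$n_species
  G <- spec$genes_per_genome
  gene_ids <- sprintf("K%05d", seq_len(G))
  n_gen <- ceiling(n / 2)
  genus_ids <- sprintf("g%02d", seq_len(n_gen))
  genus_names <- sprintf("Genus_%02d", seq_len(n_gen))
  sp_genus <- rep(seq_len(n_gen), each = 2L)[seq_len(n)]
  sp_ids <- sprintf("t%02d", seq_len(n))
  sp_names <- sprintf("%s species_%d", genus_names[sp_genus],
                      stats::ave(sp_genus, sp_genus, FUN = seq_along))
  taxonomy <- data.frame(
    taxon_id = c("1", "2", genus_ids, sp_ids),
    parent_id = c("1", "1", rep("2", n_gen), genus_ids[sp_genus]),
    rank = c("no rank", "superkingdom", rep("genus", n_gen),
             rep("species", n)),
    name = c("root", "Bacteria", genus_names, sp_names),
    stringsAsFactors = FALSE)

  bases <- c("A", "C", "G", "T")
  margin <- 1000L
  contigs <- vector("list", n)
  genes <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    copies <- if (spec$copy_min == spec$copy_max) {
      rep(spec$copy_min, G)
    } else {
      sample(seq(spec$copy_min, spec$copy_max), G, replace = TRUE)
    }
    cass <- vapply(seq_len(G), function(g) random_cassette(), character(1))
    n_pl <- sum(copies)
    clen <- 3L * CASSETTE_CODONS
    bg_len <- spec$genome_length - clen * n_pl
    n_slots <- bg_len - 2L * margin
    if (bg_len < 2L * margin || n_slots < n_pl) {
      stop("genome_length ", spec$genome_length, " too short to host ",
           n_pl, " gene cassettes")
    }
    cuts <- sort(sample(seq(margin, bg_len - margin), n_pl, replace = FALSE))
    inst <- sample(rep(seq_len(G), copies))
    strands <- sample(c("+", "-"), n_pl, replace = TRUE)
    bg <- paste(sample(bases, bg_len, replace = TRUE), collapse = "")
    pieces <- character(2L * n_pl + 1L)
    starts <- integer(n_pl)
    prev <- 0L
    for (k in seq_len(n_pl)) {
      pieces[2L * k - 1L] <- substr(bg, prev + 1L, cuts[k])
      seq_k <- cass[inst[k]]
      if (strands[k] == "-") seq_k <- revcomp(seq_k)
      pieces[2L * k] <- seq_k
      starts[k] <- cuts[k] + clen * (k - 1L) + 1L
      prev <- cuts[k]
    }
    pieces[2L * n_pl + 1L] <- substr(bg, prev + 1L, bg_len)
    contig_id <- paste0("contig_", sp_ids[i])
    contigs[[i]] <- data.frame(id = contig_id, taxon_id = sp_ids[i],
                               seq = paste(pieces, collapse = ""),
                               stringsAsFactors = FALSE)
    genes[[i]] <- data.frame(contig_id = contig_id,
                             gene_id = gene_ids[inst],
                             start = starts, end = starts + clen - 1L,
                             strand = strands, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(taxon_id = sp_ids[i], taxon_name = sp_names[i],
                             gene_id = gene_ids, copy_number = copies,
                             true_abundance = spec$coverage * copies,
                             stringsAsFactors = FALSE)
  }
  structure(list(spec = spec,
                 contigs = do.call(rbind, contigs),
                 genes = do.call(rbind, genes),
                 taxonomy = taxonomy,
                 truth = do.call(rbind, truth)),
            class = "synthetic_community")
}

mutate_bases <- function(seqs, error_rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(ch)) < error_rate)
    if (length(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired sequencing fragments as pre-aligned SAM records
#'
#' Fragment starts are uniform over each genome; fragment lengths are
#' Normal(`fragment_mean`, `fragment_sd`) truncated to
#' `[read_length, 3 * fragment_mean]`. The two mates are `read_length`
#' intervals at the fragment ends and are emitted as properly paired SAM
#' records carrying their true positions, so no aligner is involved and the
#' expected per-base depth equals `coverage`. Substitution errors (when
#' `error_rate > 0` and `include_seq = TRUE`) alter read sequences but never
#' positions.
#'
#' @param community a [generate_community()] result.
#' @param seed RNG seed (default: the community seed + 1, so a pipeline run
#'   from one spec is fully reproducible).
#' @param include_seq emit actual read sequences instead of `*` (required
#'   for a nonzero `error_rate` to be visible; positions are unaffected).
#' @return a `sim_fragments` list: `records` (data.frame of SAM columns) and
#'   `sq` (contig name/length table for the header).
#' @export
simulate_fragments <- function(community, seed = NULL, include_seq = FALSE) {
  stopifnot(inherits(community, "synthetic_community"))
  spec <- community$spec
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  R <- spec$read_length
  per_contig <- vector("list", nrow(community$contigs))
  for (i in seq_len(nrow(community$contigs))) {
    contig <- community$contigs$id[i]
    s <- community$contigs$seq[i]
    L <- nchar(s)
    n_frag <- round(spec$coverage * L / (2 * R))
    if (n_frag < 1L) next
    len <- pmin(pmax(round(rnorm(n_frag, spec$fragment_mean,
                                 spec$fragment_sd)), R),
                min(3L * spec$fragment_mean, L))
    start <- 1L + floor(runif(n_frag) * (L - len + 1))
    qname <- sprintf("%s_f%07d", community$contigs$taxon_id[i],
                     seq_len(n_frag))
    m1_pos <- as.integer(start)
    m2_pos <- as.integer(start + len - R)
    seq1 <- seq2 <- "*"
    if (include_seq) {
      seq1 <- substring(s, m1_pos, m1_pos + R - 1L)
      seq2 <- revcomp(substring(s, m2_pos, m2_pos + R - 1L))
      if (spec$error_rate > 0) {
        seq1 <- mutate_bases(seq1, spec$error_rate)
        seq2 <- mutate_bases(seq2, spec$error_rate)
      }
    }
    per_contig[[i]] <- data.table::data.table(
      qname = rep(qname, 2L),
      flag = rep(c(99L, 147L), each = n_frag),
      rname = contig,
      pos = c(m1_pos, m2_pos),
      mapq = 60L,
      cigar = paste0(R, "M"),
      rnext = "=",
      pnext = c(m2_pos, m1_pos),
      tlen = c(as.integer(len), -as.integer(len)),
      seq = c(seq1, seq2),
      qual = "*")
  }
  records <- data.table::rbindlist(per_contig)
  if (nrow(records)) data.table::setorder(records, rname, pos, qname, flag)
  data.table::setDF(records)
  structure(list(records = records,
                 sq = data.frame(id = community$contigs$id,
                                 length = nchar(community$contigs$seq),
                                 stringsAsFactors = FALSE)),
            class = "sim_fragments")
}

#' Write simulated fragments as a SAM text file
#'
#' @param sim a [simulate_fragments()] result.
#' @param path output path.
#' @export
write_sam <- function(sim, path) {
  stopifnot(inherits(sim, "sim_fragments"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", sim$sq$id, sim$sq$length))
  writeLines(hdr, path)
  if (nrow(sim$records)) {
    data.table::fwrite(sim$records, path, sep = "\t", append = TRUE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Emit synthetic annotation inputs (assignments, protein alignments)
#'
#' Stands in for the outputs of a taxonomic classifier and a translated
#' protein search. Each contig is assigned its true taxon with score 100
#' (optionally a fraction of contigs receive a second tied assignment, to
#' exercise the ambiguity filter). For every planted cassette, the matching
#' ORF is located and a full-coverage, 100%-identity alignment row is
#' synthesized against subject `P_<gene>`; the accompanying gene map sends
#' `P_<gene>` back to the gene id.
#'
#' @param community a [generate_community()] result.
#' @param ambiguous_fraction fraction of contigs to make ambiguous (tied
#'   top-score duplicate assignment to another taxon).
#' @param seed RNG seed (default: community seed + 2).
#' @param min_codons ORF caller threshold used to locate cassette ORFs.
#' @return list with `assignments` (contig_id, taxon_id, score),
#'   `alignments` (13-column protein alignment data.frame) and `gene_map`.
#' @export
emit_annotation_inputs <- function(community, ambiguous_fraction = 0,
                                   seed = NULL, min_codons = 30L) {
  stopifnot(inherits(community, "synthetic_community"))
  spec <- community$spec
  if (is.null(seed)) seed <- spec$seed + 2L
  set.seed(seed)
  contigs <- community$contigs
  assignments <- data.frame(contig_id = contigs$id,
                            taxon_id = contigs$taxon_id,
                            score = 100, stringsAsFactors = FALSE)
  n_amb <- round(ambiguous_fraction * nrow(contigs))
  if (n_amb > 0L) {
    if (nrow(contigs) < 2L) stop("need >= 2 taxa to create ambiguity")
    pick <- sort(sample(seq_len(nrow(contigs)), n_amb))
    other <- contigs$taxon_id[(pick %% nrow(contigs)) + 1L]
    assignments <- rbind(assignments,
                         data.frame(contig_id = contigs$id[pick],
                                    taxon_id = other, score = 100,
                                    stringsAsFactors = FALSE))
    assignments <- assignments[order(assignments$contig_id,
                                     assignments$taxon_id), , drop = FALSE]
    rownames(assignments) <- NULL
  }

  aa_len <- CASSETTE_CODONS - 1L  # start + internal codons, stop untranslated
  orfs <- find_orfs(contigs, min_codons = min_codons, translate = FALSE)
  odt <- data.table::as.data.table(orfs)
  gdt <- data.table::as.data.table(community$genes)
  plus <- merge(gdt[strand == "+"],
                odt[strand == "+", .(contig_id, orf_id, ostart = start,
                                     oend = end)],
                by.x = c("contig_id", "end"), by.y = c("contig_id", "oend"))
  minus <- merge(gdt[strand == "-"],
                 odt[strand == "-", .(contig_id, orf_id, ostart = start,
                                      oend = end)],
                 by.x = c("contig_id", "start"),
                 by.y = c("contig_id", "ostart"))
  if (nrow(plus) + nrow(minus) != nrow(gdt)) {
    stop("internal error: ", nrow(gdt) - nrow(plus) - nrow(minus),
         " planted cassette(s) have no matching ORF")
  }
  off_plus <- (plus$start - plus$ostart) %/% 3L
  off_minus <- (minus$oend - minus$end) %/% 3L
  if (any((plus$start - plus$ostart) %% 3L != 0L) ||
      any((minus$oend - minus$end) %% 3L != 0L)) {
    stop("internal error: cassette/ORF frame mismatch")
  }
  mk <- function(m, off) {
    if (nrow(m) == 0L) return(NULL)
    data.table::data.table(
      query_id = m$orf_id, subject_id = paste0("P_", m$gene_id),
      pct_identity = 100, align_len = aa_len, mismatches = 0L,
      gap_opens = 0L, qstart = off + 1L, qend = off + aa_len,
      sstart = 1L, send = aa_len, evalue = 0,
      bitscore = round(1.9 * aa_len, 1), subject_len = aa_len)
  }
  alignments <- data.table::rbindlist(list(mk(plus, off_plus),
                                           mk(minus, off_minus)))
  data.table::setorder(alignments, query_id, subject_id)
  data.table::setDF(alignments)
  gene_ids <- sort(unique(community$genes$gene_id))
  list(assignments = assignments,
       alignments = alignments,
       gene_map = data.frame(subject_id = paste0("P_", gene_ids),
                             gene_id = gene_ids, stringsAsFactors = FALSE))
}

#' Generate a community and write every pipeline input plus the truth table
#'
#' Writes `contigs.fasta`, `reads.sam`, `taxa.tsv`, `taxonomy.tsv`,
#' `proteins.tsv` (13-column alignments), `gene_map.tsv` and `truth.tsv`
#' into `dir`.
#'
#' @param spec a [community_spec()].
#' @param dir output directory (created if needed).
#' @param ambiguous_fraction passed to [emit_annotation_inputs()].
#' @param include_seq passed to [simulate_fragments()].
#' @return invisibly, a list with the `community`, the `fragments` object
#'   and a named list of file `paths`.
#' @export
simulate_metagenome <- function(spec, dir, ambiguous_fraction = 0,
                                include_seq = FALSE) {
  community <- generate_community(spec)
  fragments <- simulate_fragments(community, include_seq = include_seq)
  ann <- emit_annotation_inputs(community,
                                ambiguous_fraction = ambiguous_fraction)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    contigs = file.path(dir, "contigs.fasta"),
    sam = file.path(dir, "reads.sam"),
    taxa = file.path(dir, "taxa.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    proteins = file.path(dir, "proteins.tsv"),
    gene_map = file.path(dir, "gene_map.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_fasta(community$contigs, paths$contigs)
  write_sam(fragments, paths$sam)
  data.table::fwrite(ann$assignments, paths$taxa, sep = "\t", quote = FALSE)
  data.table::fwrite(community$taxonomy, paths$taxonomy, sep = "\t",
                     quote = FALSE)
  data.table::fwrite(ann$alignments, paths$proteins, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  data.table::fwrite(ann$gene_map, paths$gene_map, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  data.table::fwrite(community$truth, paths$truth, sep = "\t", quote = FALSE)
  invisible(list(community = community, fragments = fragments,
                 annotation = ann, paths = paths))
}
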