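# ORF detection, translation, protein-alignment coverage filtering, and
# projection of accepted alignments back to nucleotide gene regions.

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Translate a nucleotide sequence (bacterial code, table 11)
#'
#' Codons containing an ambiguous base (`N`) translate to `X`. For the minus
#' strand the sequence is reverse-complemented before translation.
#'
#' @param nt_seq nucleotide string, length divisible by 3.
#' @param strand `"+"` or `"-"`.
#' @return amino-acid string.
#' @export
translate_dna <- function(nt_seq, strand = "+") {
  if (nchar(nt_seq) %% 3L != 0L) {
    stop("sequence length (", nchar(nt_seq), ") is not divisible by 3")
  }
  if (nchar(nt_seq) == 0L) return("")
  if (strand == "-") nt_seq <- revcomp(nt_seq)
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt_seq),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

# Six-frame ORF scan of one plus-strand oriented string. Returns codon-index
# coordinates per frame; caller maps to nucleotides and strands.
scan_frames_one_strand <- function(s, min_codons) {
  L <- nchar(s)
  out <- vector("list", 3L)
  for (off in 0:2) {
    n_codons <- (L - off) %/% 3L
    if (n_codons < 1L) next
    p <- off + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, p, p + 2L)
    si <- which(codons %in% STOP_CODONS)
    ti <- which(codons %in% START_CODONS)
    cs <- integer(0); ce <- integer(0); has_stop <- logical(0); partial <- logical(0)
    if (length(si)) {
      prev <- c(0L, si[-length(si)])
      pos <- findInterval(prev, ti) + 1L
      cand <- ifelse(pos <= length(ti), ti[pos], NA_integer_)
      ok <- !is.na(cand) & cand < si
      n_coding <- ifelse(ok, si - cand, NA_integer_)
      keep <- ok & n_coding >= min_codons
      cs <- cand[keep]; ce <- si[keep]
      has_stop <- rep(TRUE, sum(keep)); partial <- rep(FALSE, sum(keep))
      # 5'-truncated: first stop-bounded segment starts at the frame edge and
      # has no start codon before its stop.
      if (!ok[1L] && (si[1L] - 1L) >= min_codons) {
        cs <- c(1L, cs); ce <- c(si[1L], ce)
        has_stop <- c(TRUE, has_stop); partial <- c(TRUE, partial)
      }
      last_stop <- si[length(si)]
    } else {
      last_stop <- 0L
    }
    # trailing segment (no terminating stop): 3'-truncated
    if (last_stop < n_codons) {
      pos <- findInterval(last_stop, ti) + 1L
      cand <- if (pos <= length(ti)) ti[pos] else NA_integer_
      if (!is.na(cand) && (n_codons - cand + 1L) >= min_codons) {
        cs <- c(cs, cand); ce <- c(ce, n_codons)
        has_stop <- c(has_stop, FALSE); partial <- c(partial, TRUE)
      }
    }
    if (length(cs)) {
      out[[off + 1L]] <- data.table::data.table(
        off = off, cs = cs, ce = ce, has_stop = has_stop, partial = partial)
    }
  }
  data.table::rbindlist(out)
}

#' Detect open reading frames on contigs
#'
#' Scans all six frames. An ORF runs from a start codon (`ATG`, `GTG`, `TTG`)
#' to the next in-frame stop (`TAA`, `TAG`, `TGA`); only the maximal ORF per
#' stop-bounded segment (the first start codon) is reported, when it has at
#' least `min_codons` coding codons (the stop codon does not count).
#' Truncated ORFs at contig edges (missing start and/or stop) are also
#' emitted and flagged `partial`. Minus-strand ORFs are reported in forward
#' contig coordinates; intervals include the stop codon when present.
#'
#' @param seqs contig sequences: a data.frame with columns `id` and `seq`
#'   (as returned by [read_fasta()]) or a named character vector.
#' @param min_codons minimum number of coding codons (default 30).
#' @param translate compute `aa_seq` (set `FALSE` to skip for speed).
#' @return data.frame with columns `orf_id`, `contig_id`, `start`, `end`
#'   (1-based inclusive, forward axis), `strand`, `partial`, `has_stop`,
#'   `aa_seq`.
#' @export
find_orfs <- function(seqs, min_codons = 30L, translate = TRUE) {
  stopifnot(min_codons >= 1L)
  if (is.character(seqs)) {
    seqs <- data.frame(id = names(seqs), seq = unname(seqs),
                       stringsAsFactors = FALSE)
  }
  res <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    s_fwd <- toupper(seqs$seq[i])
    L <- nchar(s_fwd)
    per_strand <- list()
    for (std in c("+", "-")) {
      s <- if (std == "+") s_fwd else revcomp(s_fwd)
      hits <- scan_frames_one_strand(s, min_codons)
      if (nrow(hits) == 0L) next
      nt_start <- hits$off + (hits$cs - 1L) * 3L + 1L
      nt_end <- hits$off + hits$ce * 3L
      if (std == "+") {
        fs <- nt_start; fe <- nt_end
      } else {
        fs <- L - nt_end + 1L; fe <- L - nt_start + 1L
      }
      aa <- NA_character_
      if (translate) {
        cod_end <- ifelse(hits$has_stop, nt_end - 3L, nt_end)
        nt <- substring(s, nt_start, cod_end)
        aa <- character(length(nt))
        nz <- nzchar(nt)
        if (any(nz)) {
          aa[nz] <- as.character(Biostrings::translate(
            Biostrings::DNAStringSet(nt[nz]),
            genetic.code = Biostrings::getGeneticCode("11"),
            if.fuzzy.codon = "X", no.init.codon = TRUE))
        }
      }
      per_strand[[std]] <- data.table::data.table(
        contig_id = seqs$id[i], start = fs, end = fe, strand = std,
        partial = hits$partial, has_stop = hits$has_stop, aa_seq = aa)
    }
    res[[i]] <- data.table::rbindlist(per_strand)
  }
  orfs <- data.table::rbindlist(res)
  if (nrow(orfs) == 0L) {
    return(data.frame(orf_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      partial = logical(), has_stop = logical(),
                      aa_seq = character(), stringsAsFactors = FALSE))
  }
  data.table::setorder(orfs, contig_id, start, end, strand)
  orfs[, orf_id := paste0(contig_id, "_", seq_len(.N)), by = contig_id]
  data.table::setcolorder(orfs, "orf_id")
  data.table::setDF(orfs)
  orfs
}

#' Filter protein alignments by subject coverage
#'
#' Subject coverage is the fraction of the database protein spanned by the
#' alignment, `(send - sstart + 1) / subject_len`; alignments below
#' `min_coverage` are dropped. Guards against fragmentary hits.
#'
#' @param aligns data.frame from [read_protein_alignments()].
#' @param min_coverage minimum subject coverage (default 0.8; alignments with
#'   coverage exactly equal to the threshold are kept).
#' @return the filtered data.frame with an added `coverage` column.
#' @export
filter_by_coverage <- function(aligns, min_coverage = 0.8) {
  if (!("subject_len" %in% names(aligns)) || anyNA(aligns$subject_len)) {
    stop("subject_len must be known for every alignment")
  }
  cov <- (aligns$send - aligns$sstart + 1) / aligns$subject_len
  out <- aligns[cov >= min_coverage, , drop = FALSE]
  out$coverage <- cov[cov >= min_coverage]
  rownames(out) <- NULL
  out
}

#' Derive nucleotide gene regions from ORFs and filtered protein alignments
#'
#' Per ORF only the best alignment is kept (maximum bitscore, ties broken by
#' percent identity then lexicographic subject id); its aligned query
#' sub-interval `[qstart, qend]` (amino acids) is projected onto the contig
#' respecting strand, yielding one gene region per surviving ORF.
#'
#' @param orfs data.frame from [find_orfs()].
#' @param aligns filtered alignments ([filter_by_coverage()]); `query_id`
#'   must match `orf_id`.
#' @param gene_map optional named character vector mapping subject id to gene
#'   id (see [read_gene_map()]); when `NULL`, subject ids are the gene ids.
#' @return data.frame with columns `contig_id`, `orf_id`, `gene_id`, `start`,
#'   `end` (1-based inclusive), `strand`, `bitscore`, `identity`, `coverage`.
#' @export
derive_gene_regions <- function(orfs, aligns, gene_map = NULL) {
  empty <- data.frame(contig_id = character(), orf_id = character(),
                      gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      bitscore = numeric(), identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (nrow(aligns) == 0L) return(empty)
  dangling <- setdiff(unique(aligns$query_id), orfs$orf_id)
  if (length(dangling)) {
    stop("alignment query id(s) with no matching ORF: ",
         paste(utils::head(dangling, 5L), collapse = ", "))
  }
  dt <- data.table::as.data.table(aligns)
  data.table::setorder(dt, query_id, -bitscore, -pct_identity, subject_id)
  best <- dt[, .SD[1L], by = query_id]
  o <- data.table::as.data.table(orfs)[, .(orf_id, contig_id, start, end, strand)]
  m <- merge(best, o, by.x = "query_id", by.y = "orf_id")
  gid <- as.character(m$subject_id)
  if (!is.null(gene_map)) {
    mapped <- gene_map[gid]
    if (anyNA(mapped)) {
      stop("gene map lacks subject id(s): ",
           paste(unique(gid[is.na(mapped)]), collapse = ", "))
    }
    gid <- unname(mapped)
  }
  plus <- m$strand == "+"
  rs <- ifelse(plus, m$start + (m$qstart - 1L) * 3L,
               m$end - m$qend * 3L + 1L)
  re <- ifelse(plus, m$start + m$qend * 3L - 1L,
               m$end - (m$qstart - 1L) * 3L)
  cov <- if ("coverage" %in% names(m)) m$coverage else
    (m$send - m$sstart + 1) / m$subject_len
  out <- data.table::data.table(
    contig_id = m$contig_id, orf_id = m$query_id, gene_id = gid,
    start = as.integer(rs), end = as.integer(re), strand = m$strand,
    bitscore = m$bitscore, identity = m$pct_identity, coverage = cov)
  data.table::setorder(out, contig_id, start, end, gene_id)
  data.table::setDF(out)
  out
}
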