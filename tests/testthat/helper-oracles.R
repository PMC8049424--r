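# Independent reference implementations used as test oracles. These are
# deliberately naive (per-element loops, no shared code with the package
# internals) so that agreement is meaningful.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Reference-consumed width of one CIGAR, walked character by character.
oracle_cigar_width <- function(cigar) {
  chars <- strsplit(cigar, "")[[1]]
  num <- ""
  width <- 0L
  for (ch in chars) {
    if (grepl("[0-9]", ch)) {
      num <- paste0(num, ch)
    } else {
      if (ch %in% c("M", "D", "N", "=", "X")) width <- width + as.integer(num)
      num <- ""
    }
  }
  width
}

# Naive six-frame ORF scanner: per-codon loop, mirrors the documented rules
# (first start per stop-bounded segment; 5'-truncated needs a terminating
# stop, 3'-truncated needs a start codon; stop codon included in the span).
oracle_orf_scan <- function(seq, min_codons) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3
      if (n_codons < 1) next
      seg_edge <- TRUE   # current segment begins at the frame edge
      first_start <- NA
      for (k in seq_len(n_codons)) {
        codon <- substr(s, off + 3 * (k - 1) + 1, off + 3 * k)
        if (is.na(first_start) && codon %in% starts) first_start <- k
        if (codon %in% stops) {
          cs <- if (!is.na(first_start)) first_start
                else if (seg_edge) 1 else NA
          if (!is.na(cs) && (k - cs) >= min_codons) {
            out[[length(out) + 1]] <- data.frame(
              lo = off + 3 * (cs - 1) + 1, hi = off + 3 * k,
              strand = strand, partial = is.na(first_start),
              has_stop = TRUE)
          }
          seg_edge <- FALSE
          first_start <- NA
        }
      }
      if (!is.na(first_start) && (n_codons - first_start + 1) >= min_codons) {
        out[[length(out) + 1]] <- data.frame(
          lo = off + 3 * (first_start - 1) + 1, hi = off + 3 * n_codons,
          strand = strand, partial = TRUE, has_stop = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), partial = logical(),
                      has_stop = logical()))
  }
  df <- do.call(rbind, out)
  flip <- df$strand == "-"
  start <- ifelse(flip, L - df$hi + 1, df$lo)
  end <- ifelse(flip, L - df$lo + 1, df$hi)
  res <- data.frame(start = start, end = end, strand = df$strand,
                    partial = df$partial, has_stop = df$has_stop)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# Assemble a SAM text file from header/record fragments.
write_sam_text <- function(path, sq = c(c1 = 1000L), records = character()) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos, mapq, cigar) {
  paste(qname, flag, rname, pos, mapq, cigar, "=", 0, 0, "*", "*",
        sep = "\t")
}

# Small fixed taxonomy: two genera under Bacteria, three species.
toy_taxonomy <- function() {
  data.frame(
    taxon_id = c("1", "2", "g1", "g2", "s1", "s2", "s3"),
    parent_id = c("1", "1", "2", "2", "g1", "g1", "g2"),
    rank = c("no rank", "superkingdom", "genus", "genus",
             "species", "species", "species"),
    name = c("root", "Bacteria", "Eubacterium", "Streptococcus",
             "Eubacterium rectale", "Eubacterium siraeum",
             "Streptococcus mitis"),
    stringsAsFactors = FALSE)
}

# One-contig helper objects for profiling tests.
toy_contigs <- function(ids, lengths) {
  data.frame(id = ids, length = lengths, stringsAsFactors = FALSE)
}

toy_fragments <- function(fragment_id, contig_id, start, end) {
  data.frame(fragment_id = fragment_id, contig_id = contig_id,
             start = start, end = end,
             mapq = rep(60L, length(fragment_id)), stringsAsFactors = FALSE)
}

toy_regions <- function(contig_id, gene_id, start, end, strand = "+") {
  data.frame(contig_id = contig_id, orf_id = paste0(contig_id, "_x"),
             gene_id = gene_id, start = start, end = end, strand = strand,
             bitscore = 100, identity = 100, coverage = 1,
             stringsAsFactors = FALSE)
}

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_species = 3L, genome_length = 30000L,
                   genes_per_genome = 4L, copy_min = 1L, copy_max = 3L,
                   coverage = 10, seed = 42L)
  do.call(community_spec, utils::modifyList(defaults, args))
}
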