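# Readers and writers for the external formats the pipeline touches.
# Internal coordinate convention: 1-based, inclusive on both ends (IRanges
# style). SAM POS is already 1-based; tabular protein alignment coordinates
# (1-based inclusive amino acids) are kept as-is and converted to nucleotide
# intervals only when gene regions are derived.

#' Read a (multi-)FASTA file of contigs
#'
#' Sequences are uppercased and any character outside `A`, `C`, `G`, `T`, `N`
#' is replaced by `N`. The record id is the first whitespace-delimited token
#' of the header; the remainder is kept as the description.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return a data.frame with columns `id`, `desc`, `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonempty[1L]]), ">")) {
    stop("malformed FASTA: sequence data before first header at line ",
         nonempty[1L])
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(id))) stop("malformed FASTA: empty record id")
  seq <- toupper(as.character(set))
  seq <- gsub("[^ACGTN]", "N", seq)
  data.frame(id = unname(id), desc = unname(desc), seq = unname(seq),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequence records as FASTA
#'
#' @param records data.frame with columns `id`, `seq` and optionally `desc`.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc
          else rep("", nrow(records))
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Reference-consumed width of a CIGAR string: M, D, N, =, X consume reference.
cigar_reference_width <- function(cigar) {
  out <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    ucig <- unique(cigar[ok])
    w <- vapply(ucig, function(cg) {
      ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
      if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg)) {
        stop("malformed CIGAR string: ", cg)
      }
      len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
      op <- substring(ops, nchar(ops), nchar(ops))
      sum(len[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
    out[ok] <- w[match(cigar[ok], ucig)]
  }
  out[!ok] <- NA_integer_
  out
}

#' Read aligned read intervals from a SAM file
#'
#' Parses the mandatory SAM columns and converts each mapped record into the
#' reference interval it consumes (CIGAR operations `M`, `D`, `N`, `=`, `X`).
#' Unmapped (0x4), secondary (0x100) and supplementary (0x800) records are
#' excluded, as are records below `min_mapq`. The two mates of a template
#' appear as two rows sharing `fragment_id`; downstream counting deduplicates
#' by `fragment_id` so abundances are fragment-level.
#'
#' @param path path to a SAM text file with `@SQ` headers.
#' @param min_mapq minimum mapping quality to keep a record.
#' @return data.frame with columns `fragment_id`, `contig_id`, `start`, `end`
#'   (1-based inclusive), `mapq`.
#' @export
read_sam_fragments <- function(path, min_mapq = 0L) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[is_hdr & startsWith(lines, "@SQ")]
  sq_name <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  sq_len <- suppressWarnings(as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)))
  body <- lines[!is_hdr & nzchar(lines)]
  empty <- data.frame(fragment_id = character(), contig_id = character(),
                      start = integer(), end = integer(), mapq = integer(),
                      stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:6)
  dt <- data.table::data.table(
    fragment_id = f[[1L]],
    flag = suppressWarnings(as.integer(f[[2L]])),
    contig_id = f[[3L]],
    pos = suppressWarnings(as.integer(f[[4L]])),
    mapq = suppressWarnings(as.integer(f[[5L]])),
    cigar = f[[6L]]
  )
  if (anyNA(dt$flag) || anyNA(dt$pos)) {
    stop("malformed SAM record at line ",
         which(!is_hdr)[which(is.na(dt$flag) | is.na(dt$pos))[1L]])
  }
  drop <- bitwAnd(dt$flag, 0x4L) != 0L |
    bitwAnd(dt$flag, 0x100L) != 0L |
    bitwAnd(dt$flag, 0x800L) != 0L |
    dt$contig_id == "*" | dt$cigar == "*" |
    dt$mapq < min_mapq
  dt <- dt[!drop]
  if (nrow(dt) == 0L) return(empty)
  rw <- cigar_reference_width(dt$cigar)
  dt[, `:=`(start = pos, end = pos + rw - 1L)]
  if (length(sq_name)) {
    lim <- sq_len[match(dt$contig_id, sq_name)]
    bad <- which(!is.na(lim) & dt$end > lim)
    if (length(bad)) {
      stop("CIGAR extends beyond contig length for record(s): ",
           paste(utils::head(dt$fragment_id[bad], 5L), collapse = ", "))
    }
  }
  out <- dt[, .(fragment_id, contig_id, start, end, mapq)]
  data.table::setDF(out)
  out
}

#' Read tabular protein alignments (12/13-column, outfmt-6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore, plus an optional 13th column `slen` (subject protein
#' length in amino acids). The subject length is required by the coverage
#' filter; when the file has only 12 columns it must be supplied through
#' `subject_lengths`.
#'
#' @param path path to the alignment table.
#' @param subject_lengths optional named numeric vector, or two-column
#'   data.frame (`subject_id`, `subject_len`), of subject protein lengths.
#' @return data.frame of alignments with amino-acid coordinates (1-based
#'   inclusive) and a `subject_len` column.
#' @export
read_protein_alignments <- function(path, subject_lengths = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  cols <- c("query_id", "subject_id", "pct_identity", "align_len",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  if (file.size(path) == 0L || length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    out <- data.frame(matrix(nrow = 0L, ncol = 13L))
    names(out) <- c(cols, "subject_len")
    return(out)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1:2))
  if (ncol(dt) < 12L) {
    stop("protein alignment table needs >= 12 tab-separated columns, got ",
         ncol(dt))
  }
  bad <- which(is.na(dt[[12L]]) | is.na(dt[[7L]]))
  if (length(bad)) stop("malformed protein alignment row ", bad[1L])
  has_slen <- ncol(dt) >= 13L && !all(is.na(dt[[13L]]))
  dt <- dt[, 1:(if (has_slen) 13L else 12L), with = FALSE]
  data.table::setnames(dt, c(cols, if (has_slen) "subject_len"))
  if (!has_slen) {
    if (is.null(subject_lengths)) {
      stop("subject protein lengths are required: supply a 13th `slen` ",
           "column or a subject_lengths table")
    }
    if (is.data.frame(subject_lengths)) {
      subject_lengths <- stats::setNames(as.numeric(subject_lengths[[2L]]),
                                         as.character(subject_lengths[[1L]]))
    }
    dt[, subject_len := as.numeric(subject_lengths[subject_id])]
    if (anyNA(dt$subject_len)) {
      stop("no subject length for: ",
           paste(unique(dt$subject_id[is.na(dt$subject_len)]), collapse = ", "))
    }
  }
  stopifnot(all(dt$qstart <= dt$qend), all(dt$sstart <= dt$send))
  if (any(dt$subject_len < dt$send)) {
    stop("subject_len smaller than alignment end for: ",
         paste(unique(dt$subject_id[dt$subject_len < dt$send]), collapse = ", "))
  }
  data.table::setDF(dt)
  dt
}

#' Read an optional subject-to-gene mapping table
#'
#' Two tab-separated columns: subject (protein) id, gene id. When absent, the
#' alignment subject id is used directly as the gene id.
#'
#' @param path path to the two-column TSV.
#' @return named character vector mapping subject id to gene id.
#' @export
read_gene_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("gene map needs two columns (subject_id, gene_id)")
  stats::setNames(dt[[2L]], dt[[1L]])
}

#' Read a sample label table
#'
#' Two tab-separated columns (header optional): sample id, group/outcome.
#'
#' @param path path to the TSV.
#' @return named character vector: sample id -> label.
#' @export
read_sample_labels <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("label table needs two columns (sample_id, label)")
  if (nrow(dt) > 0L && tolower(dt[[1L]][1L]) %in% c("sample", "sample_id")) {
    dt <- dt[-1L]
  }
  stats::setNames(dt[[2L]], dt[[1L]])
}

# --- feature table TSV ------------------------------------------------------

feature_key <- function(taxon_label, gene_id) {
  if (any(grepl("|", gene_id, fixed = TRUE))) {
    stop("gene ids may not contain '|'")
  }
  paste(taxon_label, gene_id, sep = "|")
}

# Split "Taxon|Gene" at the LAST '|' (taxon names may themselves contain '|').
split_feature_key <- function(key) {
  pos <- regexpr("\\|[^|]*$", key)
  bad <- which(pos < 0L)
  if (length(bad)) stop("malformed feature key: ", key[bad[1L]])
  data.frame(taxon_label = substr(key, 1L, pos - 1L),
             gene_id = substr(key, pos + 1L, nchar(key)),
             stringsAsFactors = FALSE)
}

#' Write a feature table as TSV
#'
#' First column `feature` holds the `"TaxonLabel|GeneId"` key; the remaining
#' columns are one per sample. Values are written with enough precision that
#' a read/write round trip is lossless to at least 6 significant digits.
#'
#' @param table numeric matrix; rownames are feature keys, colnames samples.
#' @param path output path.
#' @export
write_feature_tsv <- function(table, path) {
  stopifnot(is.matrix(table))
  keys <- rownames(table)
  if (is.null(keys)) keys <- character(nrow(table))
  dt <- data.table::data.table(feature = keys)
  if (ncol(table) > 0L) dt <- cbind(dt, data.table::as.data.table(table))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a feature table TSV
#'
#' @param path path written by [write_feature_tsv()] (or equivalent).
#' @return numeric matrix with feature-key rownames and sample colnames.
#' @export
read_feature_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (ncol(dt) < 1L) stop("feature table must have a feature-key column")
  keys <- as.character(dt[[1L]])
  if (anyDuplicated(keys)) {
    stop("duplicate feature key(s) in ", path, ": ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  mat <- as.matrix(dt[, -1L, with = FALSE])
  if (length(mat)) mode(mat) <- "numeric"
  rownames(mat) <- keys
  mat
}

#' Write a per-sample joint profile as TSV
#'
#' @param profile a profile data.frame from [profile_sample()].
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  data.table::fwrite(data.table::as.data.table(profile), path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-sample joint profile TSV
#'
#' @param path path written by [write_profile_tsv()].
#' @return data.frame with the profile columns.
#' @export
read_profile_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = "gene_id"))
  need <- c("taxon_label", "gene_id")
  if (!all(need %in% names(dt))) {
    stop("not a profile table (missing taxon_label/gene_id): ", path)
  }
  data.table::setDF(dt)
  dt
}
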