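# ORF detection, translation, coverage filtering, gene-region projection.

test_that("find_orfs detects a minimal complete ORF with its stop codon", {
  orfs <- find_orfs(c(c1 = "ATGAAATAA"), min_codons = 2L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$start, 1L)   # spans start codon through stop codon
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$aa_seq, "MK")
  expect_false(orfs$partial)
})

test_that("sequences shorter than the codon threshold yield no ORFs", {
  expect_equal(nrow(find_orfs(c(c1 = "ATGTAA"), min_codons = 30L)), 0L)
  expect_equal(nrow(find_orfs(c(c1 = ""), min_codons = 1L)), 0L)
})

test_that("find_orfs matches a brute-force six-frame oracle on random 1-kb", {
  withr::local_seed(101)
  for (rep in 1:50) {
    s <- random_dna(1000)
    got <- find_orfs(c(ctg = s), min_codons = 10L, translate = FALSE)
    got <- got[order(got$start, got$end, got$strand),
               c("start", "end", "strand", "partial", "has_stop")]
    rownames(got) <- NULL
    want <- oracle_orf_scan(s, min_codons = 10L)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("ORF calls are strand-symmetric under reverse complement", {
  withr::local_seed(5)
  for (rep in 1:10) {
    s <- random_dna(600)
    L <- nchar(s)
    fwd <- find_orfs(c(c1 = s), min_codons = 15L, translate = FALSE)
    rev <- find_orfs(c(c1 = oracle_revcomp(s)), min_codons = 15L,
                     translate = FALSE)
    mirrored <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L,
                           strand = ifelse(rev$strand == "+", "-", "+"))
    mirrored <- mirrored[order(mirrored$start, mirrored$end,
                               mirrored$strand), ]
    fwd <- fwd[order(fwd$start, fwd$end, fwd$strand), ]
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$end, mirrored$end)
    expect_equal(fwd$strand, mirrored$strand)
  }
})

test_that("translation uses the bacterial code and masks fuzzy codons", {
  expect_equal(translate_dna("ATG"), "M")
  expect_equal(translate_dna("CAT", strand = "-"), "M")  # revcomp is ATG
  expect_equal(translate_dna("ATGANA"), "MX")
  expect_error(translate_dna("ATGA"), "divisible by 3")
  expect_equal(translate_dna(""), "")
})

test_that("translation agrees with an independent codon-table oracle", {
  withr::local_seed(17)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    s <- random_dna(3 * n)
    want <- paste(seqinr::translate(strsplit(tolower(s), "")[[1]],
                                    numcode = 11), collapse = "")
    expect_equal(translate_dna(s), want)
  }
})

test_that("coverage filter keeps exactly the threshold and above", {
  mk <- function(send) data.frame(
    query_id = "o1", subject_id = "P1", pct_identity = 100, align_len = send,
    mismatches = 0, gap_opens = 0, qstart = 1, qend = send, sstart = 1,
    send = send, evalue = 0, bitscore = 100, subject_len = 100,
    stringsAsFactors = FALSE)
  expect_equal(nrow(filter_by_coverage(mk(80), 0.8)), 1L)   # 80/100 kept
  expect_equal(nrow(filter_by_coverage(mk(79), 0.8)), 0L)   # 79/100 dropped
  al <- rbind(mk(50), mk(90))
  expect_equal(nrow(filter_by_coverage(al, 0)), 2L)
  al_nolen <- al; al_nolen$subject_len <- NA
  expect_error(filter_by_coverage(al_nolen), "subject_len")
})

test_that("raising min_coverage never increases the region count", {
  withr::local_seed(3)
  orfs <- find_orfs(c(c1 = random_dna(3000)), min_codons = 10L,
                    translate = FALSE)
  al <- data.frame(
    query_id = sample(orfs$orf_id, 30, replace = TRUE),
    subject_id = paste0("P", 1:30), pct_identity = runif(30, 50, 100),
    align_len = 50, mismatches = 0, gap_opens = 0,
    qstart = 1, qend = 10, sstart = sample(1:5, 30, TRUE),
    send = sample(5:100, 30, TRUE), evalue = 0,
    bitscore = runif(30, 50, 300), subject_len = 100,
    stringsAsFactors = FALSE)
  al <- al[al$sstart <= al$send, ]
  counts <- vapply(seq(0, 1, by = 0.1), function(mc) {
    nrow(derive_gene_regions(orfs, filter_by_coverage(al, mc)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gene regions project alignment coordinates onto the contig", {
  orfs <- data.frame(orf_id = c("o_plus", "o_minus"),
                     contig_id = "c1", start = c(1L, 401L),
                     end = c(300L, 700L), strand = c("+", "-"),
                     partial = TRUE, has_stop = FALSE, aa_seq = NA,
                     stringsAsFactors = FALSE)
  mk <- function(orf, qs, qe) data.frame(
    query_id = orf, subject_id = "P1", pct_identity = 100, align_len = qe - qs + 1,
    mismatches = 0, gap_opens = 0, qstart = qs, qend = qe, sstart = 1,
    send = 100, evalue = 0, bitscore = 200, subject_len = 100,
    stringsAsFactors = FALSE)
  # full 100-aa alignment on a 100-codon ORF covers it entirely
  r1 <- derive_gene_regions(orfs, mk("o_plus", 1, 100))
  expect_equal(c(r1$start, r1$end), c(1L, 300L))
  # partial alignment starting at aa 11 trims 30 nt off the 5' side
  r2 <- derive_gene_regions(orfs, mk("o_plus", 11, 100))
  expect_equal(c(r2$start, r2$end), c(31L, 300L))
  # minus strand: aa offset counts from the ORF's right edge
  r3 <- derive_gene_regions(orfs, mk("o_minus", 11, 100))
  expect_equal(c(r3$start, r3$end), c(401L, 670L))
  expect_equal(r3$strand, "-")
})

test_that("the best alignment per ORF wins, with documented tie-breaks", {
  orfs <- data.frame(orf_id = "o1", contig_id = "c1", start = 1L, end = 300L,
                     strand = "+", partial = FALSE, has_stop = TRUE,
                     aa_seq = NA, stringsAsFactors = FALSE)
  al <- data.frame(
    query_id = "o1", subject_id = c("P_low", "P_high", "P_tie"),
    pct_identity = c(90, 95, 99), align_len = 100, mismatches = 0,
    gap_opens = 0, qstart = 1, qend = 99, sstart = 1, send = 99, evalue = 0,
    bitscore = c(150, 200, 200), subject_len = 100, stringsAsFactors = FALSE)
  r <- derive_gene_regions(orfs, al)
  expect_equal(nrow(r), 1L)
  expect_equal(r$gene_id, "P_tie")  # bitscore tie -> higher identity
  al$pct_identity <- 95
  expect_equal(derive_gene_regions(orfs, al)$gene_id, "P_high")
  # gene map renames subjects; dangling query ids are an error
  gm <- c(P_low = "K1", P_high = "K2", P_tie = "K3")
  expect_equal(derive_gene_regions(orfs, al, gm)$gene_id, "K2")
  al$query_id <- "ghost"
  expect_error(derive_gene_regions(orfs, al), "ghost")
  expect_equal(nrow(derive_gene_regions(orfs, al[0, ])), 0L)
})

test_that("every derived region lies inside its source ORF", {
  withr::local_seed(29)
  orfs <- find_orfs(c(c1 = random_dna(5000)), min_codons = 12L,
                    translate = FALSE)
  aa_len <- (orfs$end - orfs$start + 1L) %/% 3L
  picks <- sample(nrow(orfs), min(25, nrow(orfs)))
  al <- do.call(rbind, lapply(picks, function(i) {
    qs <- sample(seq_len(aa_len[i]), 1)
    qe <- sample(qs:aa_len[i], 1)
    data.frame(query_id = orfs$orf_id[i], subject_id = "P1",
               pct_identity = 100, align_len = qe - qs + 1, mismatches = 0,
               gap_opens = 0, qstart = qs, qend = qe, sstart = 1,
               send = qe - qs + 1, evalue = 0, bitscore = 100,
               subject_len = qe - qs + 1, stringsAsFactors = FALSE)
  }))
  regions <- derive_gene_regions(orfs, al)
  m <- match(regions$orf_id, orfs$orf_id)
  expect_true(all(regions$start >= orfs$start[m]))
  expect_true(all(regions$end <= orfs$end[m]))
  expect_true(all((regions$end - regions$start + 1L) %% 3L == 0L))
})
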