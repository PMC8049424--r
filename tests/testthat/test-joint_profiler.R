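# Fragment counting over gene regions and the joint-profiling statistics.

test_that("region_depth counts overlapping fragments and clipped bases", {
  rg <- toy_regions("c1", "K1", 1L, 300L)
  expect_equal(region_depth(toy_fragments(character(), character(),
                                          integer(), integer()), rg)$fragment_count, 0L)
  # three 100-base fragments tiling the region exactly
  fr <- toy_fragments(paste0("f", 1:3), "c1", c(1L, 101L, 201L),
                      c(100L, 200L, 300L))
  d <- region_depth(fr, rg)
  expect_equal(d$fragment_count, 3L)
  expect_equal(d$aligned_bases, 300)
  expect_equal(mean_depth(d$aligned_bases, 300), 1.0)
})

test_that("mates share a fragment id: one count, summed bases", {
  rg <- toy_regions("c1", "K1", 101L, 400L)
  fr <- toy_fragments(c("f1", "f1"), "c1", c(1L, 151L), c(120L, 250L))
  d <- region_depth(fr, rg)
  expect_equal(d$fragment_count, 1L)           # same template
  expect_equal(d$aligned_bases, 20 + 100)      # each mate clipped to region
  # a fragment overlapping two regions counts for both
  rg2 <- rbind(rg, toy_regions("c1", "K2", 351L, 600L))
  fr2 <- toy_fragments("f2", "c1", 301L, 400L)
  d2 <- region_depth(fr2, rg2)
  expect_equal(d2$fragment_count, c(1L, 1L))
  expect_equal(d2$aligned_bases, c(100, 50))  # [301,400] vs [101,400], [351,600]
})

test_that("normalization formulas behave as documented", {
  expect_equal(mean_depth(0, 500), 0)
  expect_equal(mean_depth(3000, 300), 10)
  expect_error(mean_depth(10, 0), "> 0")
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(20, 1000, 2e6), fpkm(10, 1000, 1e6))  # scale invariance
  expect_error(fpkm(1, 1000, 0), "> 0")
  expect_equal(depth_per_genome(10, 10), 1)
  expect_equal(depth_per_genome(0, 10), 0)
  expect_true(is.na(depth_per_genome(5, 0)))
})

# The joint-profiling toy scene: one gene, two copies on the contig of
# species A, one copy on the contig of species B; one read per copy.
fig_toy <- function() {
  contigs <- toy_contigs(c("cA", "cB"), c(2000L, 2000L))
  ct <- data.frame(contig_id = c("cA", "cB"), taxon_id = c("s1", "s3"),
                   stringsAsFactors = FALSE)
  regions <- rbind(toy_regions("cA", "K1", 101L, 400L),
                   toy_regions("cA", "K1", 901L, 1200L),
                   toy_regions("cB", "K1", 501L, 800L))
  fr <- rbind(toy_fragments(c("a1", "a2"), "cA", c(150L, 950L),
                            c(249L, 1049L)),
              toy_fragments("b1", "cB", 600L, 699L))
  list(contigs = contigs, ct = ct, regions = regions, fr = fr)
}

test_that("joint profiling attributes gene copies to their species", {
  toy <- fig_toy()
  prof <- profile_sample(toy$contigs, toy$ct, toy$regions, toy$fr,
                         toy_taxonomy(), rank = "species")
  expect_equal(prof$taxon_label,
               c("Eubacterium rectale", "Streptococcus mitis"))
  expect_equal(prof$fragment_count, c(2L, 1L))
  expect_equal(prof$gene_id, c("K1", "K1"))
})

test_that("multi-region aggregation: additive by default, pooling optional", {
  contigs <- toy_contigs("cA", 3000L)
  ct <- data.frame(contig_id = "cA", taxon_id = "s1",
                   stringsAsFactors = FALSE)
  regions <- rbind(toy_regions("cA", "K1", 1L, 300L),
                   toy_regions("cA", "K1", 1001L, 1300L))
  fr <- toy_fragments(paste0("f", 1:6), "cA",
                      c(1L, 101L, 201L, 1001L, 1101L, 1201L),
                      c(100L, 200L, 300L, 1100L, 1200L, 1300L))
  p_sum <- profile_sample(contigs, ct, regions, fr, toy_taxonomy())
  expect_equal(p_sum$fragment_count, 6L)
  expect_equal(p_sum$mean_depth, 2.0)          # 1x depth per copy, 2 copies
  p_pool <- profile_sample(contigs, ct, regions, fr, toy_taxonomy(),
                           mode = "pool")
  expect_equal(p_pool$fragment_count, 6L)
  expect_equal(p_pool$mean_depth, 1.0)         # 600 bases over 600 bp
  expect_equal(p_pool$region_length, 600)
})

test_that("regions on ambiguity-filtered contigs are dropped, unassigned kept", {
  toy <- fig_toy()
  ct <- rbind(toy$ct[1, ],                      # cB absent = filtered out
              data.frame(contig_id = "cB", taxon_id = NA_character_))[1, ]
  prof <- profile_sample(toy$contigs, ct, toy$regions, toy$fr,
                         toy_taxonomy(), rank = "species")
  expect_equal(prof$taxon_label, "Eubacterium rectale")
  # NA taxon -> unclassified bucket, regions retained
  ct2 <- data.frame(contig_id = c("cA", "cB"),
                    taxon_id = c("s1", NA_character_),
                    stringsAsFactors = FALSE)
  prof2 <- profile_sample(toy$contigs, ct2, toy$regions, toy$fr,
                          toy_taxonomy(), rank = "species")
  expect_setequal(prof2$taxon_label, c("Eubacterium rectale", "unclassified"))
})

test_that("profiles are invariant to input row order", {
  toy <- fig_toy()
  ref <- profile_sample(toy$contigs, toy$ct, toy$regions, toy$fr,
                        toy_taxonomy())
  perm <- profile_sample(toy$contigs[2:1, ], toy$ct[2:1, ],
                         toy$regions[c(3, 1, 2), ], toy$fr[c(2, 3, 1), ],
                         toy_taxonomy())
  expect_equal(ref, perm, ignore_attr = TRUE)
})

test_that("zero-fragment features are emitted unless dropped", {
  toy <- fig_toy()
  prof <- profile_sample(toy$contigs, toy$ct, toy$regions, toy$fr[0, ],
                         toy_taxonomy())
  expect_equal(nrow(prof), 2L)
  expect_true(all(prof$fragment_count == 0L))
  expect_true(all(prof$mean_depth == 0))
  prof2 <- profile_sample(toy$contigs, toy$ct, toy$regions, toy$fr[0, ],
                          toy_taxonomy(), drop_zeros = TRUE)
  expect_equal(nrow(prof2), 0L)
})

test_that("dangling contig references are a consistency error", {
  toy <- fig_toy()
  bad <- toy$regions
  bad$contig_id[1] <- "ghost"
  expect_error(profile_sample(toy$contigs, toy$ct, bad, toy$fr,
                              toy_taxonomy()), "ghost")
})

test_that("with non-overlapping regions fragment counts are conserved", {
  withr::local_seed(41)
  contigs <- toy_contigs("c1", 10000L)
  ct <- data.frame(contig_id = "c1", taxon_id = "s1",
                   stringsAsFactors = FALSE)
  starts <- seq(1L, 9000L, by = 1000L)
  regions <- do.call(rbind, lapply(seq_along(starts), function(i) {
    toy_regions("c1", paste0("K", i), starts[i], starts[i] + 499L)
  }))
  fs <- sample(1:9900, 200)
  fr <- toy_fragments(paste0("f", 1:200), "c1", fs, fs + 99L)
  prof <- profile_sample(contigs, ct, regions, fr, toy_taxonomy())
  expect_lte(sum(prof$fragment_count), 200L)
})
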