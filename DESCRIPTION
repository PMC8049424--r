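Package: jointprofiler
Title: Joint Taxonomic and Functional Profiling of Assembled Metagenomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies taxon-specific gene abundances ("joint features") in
    shotgun metagenomes. Assembled contigs carry both a taxonomic assignment
    and gene regions derived from open reading frames and protein alignments;
    read alignments to the contigs are converted into per-(taxon, gene)
    abundance statistics (mean depth, FPKM, depth per genome). Downstream
    modules tabularize profiles across samples, compare groups by fold change
    and rank-sum tests with Benjamini-Hochberg correction, rank features by
    random-forest variable importance under leave-one-out cross-validation,
    and render HTML heatmaps. A synthetic-metagenome generator plants gene
    cassettes at known copy number and emits every input format together with
    the exact ground truth, so the whole pipeline is testable without any
    external aligner, assembler, or reference database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    grDevices,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
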