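# jointprofiler

Joint taxonomic and functional profiling of shotgun metagenomes from
assembled contigs.

Microbiome studies usually profile metagenome reads into *taxa* ("who is
there") or into *gene families* ("what can they do") separately. The unit of
analysis in this package is the **joint feature** — a (taxon, gene) pair such
as `Eubacterium|K00826` — whose abundance tells you *who carries what*. Such
features are biologically richer than either marginal profile: the same gene
carried by different organisms can have very different clinical meaning, and
taxon-specific gene abundances make competitive biomarkers for outcome
prediction.

Short reads cannot be assigned to taxon-specific genes directly, so the
algorithm routes everything through de novo assembled contigs:

1. contigs get taxonomic assignments; contigs whose top score is tied across
   several taxa are **filtered out as ambiguous**;
2. open reading frames are called in six frames (translation table 11),
   translated and matched against a protein database; alignments must cover
   ≥ 0.8 of the subject protein, and the best hit per ORF defines a **gene
   region** on the contig;
3. reads aligned to the contigs are counted per gene region at the fragment
   (read-pair) level and summarized per (taxon, gene) as

   * mean depth  `= aligned bases / region length`,
   * FPKM  `= fragments × 10⁹ / (region length × total mapped fragments)`,
   * depth per genome  `= gene mean depth / taxon genome-wide mean depth`
     (≈ gene copies per genome).

Copies of a gene add: a two-copy gene at 10× coverage reports mean depth ~20
and depth-per-genome ~2.

Downstream modules tabularize profiles across samples, compare two groups
(log₂ fold change, Wilcoxon rank-sum or Welch p-values, Benjamini–Hochberg
q-values), rank features by random-forest variable importance under
leave-one-out cross-validation (500 trees, importances scaled so the top
feature is 100, selection cutoff 50), and render red→green HTML heatmaps.

A synthetic-metagenome generator plants 900-bp gene cassettes at known copy
numbers in random genomes and emits every input format (FASTA, SAM with true
coordinates, assignment/taxonomy/alignment tables) together with the exact
ground truth `true abundance = coverage × copy number`, so the whole pipeline
is developed and tested without any assembler, aligner, or reference
database.

## Worked example

```r
library(jointprofiler)

## simulate a small community with known gene copy numbers
spec <- community_spec(n_species = 3, genome_length = 40000,
                       genes_per_genome = 5, coverage = 10, seed = 7)
sim <- simulate_metagenome(spec, "demo")

## run the full pipeline on the emitted files
prof <- profile_metagenome(
  contigs_path  = "demo/contigs.fasta",
  taxa_path     = "demo/taxa.tsv",
  taxonomy_path = "demo/taxonomy.tsv",
  proteins_path = "demo/proteins.tsv",
  sam_path      = "demo/reads.sam",
  gene_map_path = "demo/gene_map.tsv",
  rank = "species")

head(prof[, c("taxon_label", "gene_id", "fragment_count",
              "mean_depth", "depth_per_genome")], 3)
#>          taxon_label gene_id fragment_count mean_depth depth_per_genome
#> 1 Genus_01 species_1  K00001            107   18.85396         1.885396
#> 2 Genus_01 species_1  K00002            175   32.06243         3.206243
#> 3 Genus_01 species_1  K00003            230   41.71014         4.171014
```

`K00001` was planted at 2 copies in this genome: its mean depth is ~2 × the
10× coverage and its depth-per-genome is ~1.9 estimated copies (`K00002` and
`K00003` were planted at 3 and 4 copies). Comparing all 15 (taxon, gene)
estimates with the planted truth:

```r
m <- merge(prof, sim$community$truth,
           by.x = c("taxon_label", "gene_id"),
           by.y = c("taxon_name", "gene_id"))
cor(m$true_abundance, m$mean_depth)
#> [1] 0.9815563
```

The same steps are available from a shell through the thin CLI wrapper
(`inst/cli/jointprofiler`): `simulate`, `profile`, `table`, `compare`,
`predict`, `heatmap`, each with `--help`-documented flags, exit code 0/1/2
(success / data error / usage error) and byte-stable output for a fixed
`--seed`.

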