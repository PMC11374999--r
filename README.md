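# genopack

Versioned, gene-anchored data packages for microbial genomes and pangenomes.

Comparative and functional microbiology increasingly revolves around a single
organism (or genus) accumulating heterogeneous data over years: a genome, its
gene calls, several generations of functional annotation, dozens to hundreds
of transcriptomes, proteomes, mutant-fitness screens, and — at the genus
level — hundreds of related genomes with their pangenome, phylogeny and trait
profiles. `genopack` gives that accumulation a durable shape: a
**self-contained, versioned data package** anchored on the genome, in which
every dataset is a checksummed *layer* referenced to gene identifiers, every
addition bumps a MAJOR.MINOR version with a changelog entry, and the whole
object exports to universal formats (JSON manifest, TSV, FASTA, newick) that
round-trip losslessly.

It is aimed at microbiologists and bioinformaticians who maintain such
organism-centric compendia and want reproducible, queryable, citable data
objects rather than folders of ad hoc files.

## What it computes

Around the container, the package implements the analyses such compendia are
typically used for:

- **Expression meta-analysis.** Per-sample TPM
  (`TPM_g = (r_g / Σ_h r_h) × 10⁶` with `r_g = count_g / length_g`, or mean
  coverage directly), NSAF for proteomes
  (`NSAF_p = (SpC_p / L_p) / Σ_i (SpC_i / L_i)`), proportional expression over
  a named gene collection (each row normalized to sum to 1),
  Euclidean-distance/Ward-linkage clustering for heatmap display, and
  two-sided Student or Welch t-tests between condition groups with BH
  q-values.
- **Pangenome construction.** All-vs-all amino-acid similarity; *minbit*
  filtering (`minbit = s_ab / min(s_aa, s_bb)`, default threshold 0.5);
  Markov clustering (default inflation 2.0) into gene clusters with binary
  presence vectors and consensus annotations; fragment-based average
  nucleotide identity (1020 bp fragments, both strands, 30 % identity
  cutoff).
- **Completeness-aware Bayesian core/accessory classification.** For each
  cluster, the core model scores absences as incompleteness dropout
  (`LL_core = Σ_{present} ln c_i + Σ_{absent} ln(1 − c_i)`, with genome
  completeness `c_i`), against an accessory model in which genome *i* draws
  its `n_i` accessory genes from a pool of `G_acc` clusters
  (`p_i = 1 − (1 − 1/G_acc)^{n_i}`); labels iterate to a fixed point and a
  cluster is core iff the log-likelihood ratio is positive.
- **Trait profiling and phylogeny.** CAZyme counts per category (GH, GT, PL,
  CE, AA, CBM) per genome, normalized by the per-category maximum;
  concatenated single-copy-core alignments with partition tables; newick
  I/O, midpoint rooting, and Robinson–Foulds topology comparison.
- **Synthetic fixtures.** Seed-deterministic generators for every input
  class (genomes with open reading frames, coverage samples, presence
  matrices with completeness dropout), so the full pipeline is testable at
  desk scale.

## Worked example

```r
library(genopack)

pkg <- simulate_genome(seed = 1)   # toy genome with annotations + collection
pkg
#> <dm_package 'toy_genome' (genome) v1.3>
#>   genome: 2 contig(s), 3756 bp, 12 gene(s)
#>   layers: 3
#>     - annotation:COG [annotation_source] added in v1.1
#>     - annotation:CAZyme [annotation_source] added in v1.2
#>     - collection:transporters [collection] added in v1.3

genome_stats(pkg)
#> total_length = 3756, gc_fraction = 0.510, num_genes = 12, genes_per_kbp = 3.19

# add four simulated transcriptome samples as versioned layers
genes <- gene_calls(pkg); lens <- genes$stop - genes$start
set.seed(1)
samples <- simulate_coverage_samples(1, genes$gene_id, lens,
                                     rates = runif(nrow(genes), 0.2, 2),
                                     n_samples = 4)
for (s in names(samples))
  pkg <- add_coverage_layer(pkg, s, samples[[s]], total_mapped_reads = 1e5)
package_version_string(pkg)
#> [1] "1.7"        # each layer bumped MINOR

# proportional expression of the transporter collection (rows sum to 1)
prop <- proportional_expression(collection_tpm_matrix(pkg, "transporters"))
round(prop[, 1:3], 3)
#>        0     1     2
#> S1 0.095 0.127 0.176
#> S2 0.098 0.124 0.177
#> S3 0.098 0.127 0.179
#> S4 0.098 0.125 0.178

# a 3-genome pangenome: 5 shared genes + 2 unique per genome -> 11 clusters
gs  <- simulate_related_genomes(seed = 1)
pan <- classify_pan_core(build_pangenome(gs))
pan
#> <dm_pangenome: 3 genomes, 11 gene clusters>
#>   core: 5, accessory: 6
head(pan$core, 3)
#>   cluster_id  ll_core ll_accessory   llr label
#> 1   GC_00001 -0.0030      -3.5569 3.554  core
#> 2   GC_00002 -0.0030      -3.5569 3.554  core
#> 3   GC_00003 -0.0030      -3.5569 3.554  core
```

The five clusters present in all three genomes are classified core (positive
log-likelihood ratio: the core model explains their ubiquity far better than
an accessory draw would), the six genome-specific singletons accessory.

A small command-line wrapper for the package-management verbs is installed
at `inst/scripts/dm` (`dm create|info|verify|stats|export|import|fixtures`).

## Scope

Upstream discovery steps are consumed as their standard file formats, not
recomputed: gene calling (import GFF3 or tabular calls), HMM/orthology
annotation (import annotation TSVs), read QC and mapping (import per-gene
count/coverage TSVs), completeness estimation (import genome metadata), and
maximum-likelihood tree inference (import newick).
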