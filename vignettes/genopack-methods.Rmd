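---
title: "genopack: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genopack: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genopack)
```

This vignette is the package's own account of the science it implements: the
container model, the statistical machinery, the defaults and why they are
what they are, what the synthetic generators do and do not emulate, and the
places where the design was genuinely open.

## The package container

A `dm_package` is a versioned compendium anchored on a genome (or a genome
set). The genome spine — contigs, gene calls, functional annotations — fixes
a universe of dense integer gene identifiers; every subsequent dataset is a
*layer* keyed to those identifiers. Three rules give the container its
guarantees:

1. **Canonical serialization.** A layer's checksum is the MD5 digest of a
   canonical text form: UTF-8, tab-separated, fixed column order, rows sorted
   bytewise. Row order therefore never affects a checksum, and numeric cells
   are rendered at 15 significant digits — a fixpoint of the
   string → double → string round trip — so a layer re-read from its TSV
   export hashes identically to the in-memory original.
2. **Semantic versioning.** Additive operations (registering a layer,
   appending annotations) bump MINOR; destructive ones (removing a layer)
   bump MAJOR. Versions never decrease, and layers are immutable: registering
   layer *N* cannot change the digest of layers 1..*N − 1*.
3. **Universal-format export.** `export_package()` writes a JSON manifest,
   one TSV per tabular layer, FASTA for sequences and newick for trees;
   `import_package()` verifies every digest on the way back in. Export
   followed by import is the identity on the manifest and all layer
   checksums.

The store is an in-memory R object with a directory-based interchange
format; there is no daemon or database dependency, which keeps a package a
plain, inspectable file tree. DOIs are metadata only — no registration or
upload is performed.

Internally all coordinates are 0-based half-open; GFF3's 1-based closed
convention is converted at the I/O boundary, and the GFF3 round trip
reproduces the original coordinates exactly. Annotation sources (COG, KOfam,
Pfam, CAZyme, custom curations…) are kept side by side and never merged,
because curated updates routinely coexist with automated sources and
collapsing them would lose provenance.

## Expression normalization

`tpm_normalize()` implements transcripts per million with two rate modes,
because per-gene inputs arrive in two shapes. With read counts the rate is
`count / length`; with mean coverage the values are already
length-normalized and are used as rates directly. Either way
`TPM = rate / Σ rates × 10⁶`, so each non-degenerate sample sums to exactly
one million; an all-zero sample yields all zeros with a warning rather than
an error, since empty samples legitimately occur in meta-analyses. The mode
is recorded in layer provenance. The sample's `total_mapped_reads`
denominator is caller-supplied (the sequencing depth is knowledge the caller
has and the table may not); when absent it defaults to the column sum with a
warning.

`nsaf_normalize()` computes the normalized spectral abundance factor,
`(SpC_p / L_p) / Σ_i (SpC_i / L_i)`, which sums to 1 over detected proteins
and makes spectral counts comparable across proteomes. An all-zero proteome
is an error — "no detected proteins" is a data problem, not a quantity.

`proportional_expression()` divides each sample's values by the sum over a
gene collection, the quantity a proportional-expression heatmap displays.
It is invariant to any per-sample scale factor, so it can be computed from
TPM or raw rates interchangeably. Display clustering uses Euclidean distance
with Ward linkage (`hclust` method `"ward.D2"`, the variance-minimizing Ward
criterion for Euclidean input); the output is orderings and merge trees, not
a rendered image — plotting is an export concern.

Group contrasts are two-sided t-tests. The default is the classic
equal-variance Student test, matching the common default of scientific
t-test implementations; Welch is exposed for unequal variances. Both raw
p-values and Benjamini–Hochberg q-values are reported, with raw p as the
primary column. When both groups have zero variance and equal means the test
is defined as `t = 0, p = 1` rather than `NaN`. By default tests operate on
the proportional matrix (the displayed quantity); callers can pass TPM
instead.

## Pangenome construction

Gene clustering follows the conventional similarity-graph pipeline:

- **Scoring.** All-vs-all local amino-acid alignment (BLOSUM62, gap open 10,
  extend 1) over the translated gene calls. The scorer is pluggable, and
  external search results (e.g. DIAMOND/BLAST tabular output with self-hits)
  can be imported instead via `similarity_edges_from_table()`.
- **minbit filtering.** Each pair score is normalized by the smaller of the
  two self-scores: `minbit = s_ab / min(s_aa, s_bb)`, a 0..1 heuristic that
  penalizes partial-length matches. Edges below 0.5 are dropped. The
  threshold is conventional for this pipeline family and config-exposed.
- **Markov clustering.** Flow simulation on the column-stochastic graph
  matrix: alternate expansion (matrix squaring) and inflation (elementwise
  power 2.0 with renormalization), pruning entries below 1e−10, until the
  matrix changes by less than 1e−8. Clusters are the connected components of
  the converged flow's support. The procedure is deterministic for a given
  graph; self-loops equal to the maximum incident weight are added for
  convergence. Inflation (granularity) is config-exposed; 2.0 is the
  standard default.

Consensus annotations take, per source, the most frequent accession among a
cluster's member genes, breaking ties lexicographically so rebuilds are
reproducible. Presence is binary: within-genome paralogs keep cluster
membership but contribute a single presence bit.

**ANI** is fragment-based: genome A is chopped into non-overlapping 1020 bp
fragments (a whole-contig fragment when a contig is shorter), each aligned
locally against genome B on both strands, and the mean percent identity of
fragments above 30 % identity is reported together with the aligned
fraction. The measure is asymmetric by construction and reported both ways;
a genome against itself is exactly 100 because every fragment aligns
full-length without mismatch. Fragment size and the identity cutoff are
arguments.

## Bayesian core/accessory classification

Genome completeness `c_i` ∈ (0, 1] is read as the probability that a truly
present gene was recovered — the key to calling core genes in collections
dominated by incomplete MAGs, where a naive "present in ≥ 95 % of genomes"
rule undercounts the core. Two models compete per cluster `g` with observed
presence `x_{g,i}`:

- **Core:** the cluster is in every genome; absences are dropout.
  `LL_core = Σ_{x=1} ln c_i + Σ_{x=0} ln(1 − c_i)`.
- **Accessory:** genome `i` carries `n_i` observed accessory genes drawn
  from a pool of `G_acc` accessory clusters, so it contains a given
  accessory cluster with `p_i = 1 − (1 − 1/G_acc)^{n_i}`.
  `LL_acc = Σ_{x=1} ln p_i + Σ_{x=0} ln(1 − p_i)`.

A cluster is core iff `LLR = LL_core − LL_acc > 0`. Because `G_acc` and
`n_i` depend on the labels, classification starts from the clusters present
in more than 95 % of genomes and iterates to a fixed point (at most 50
rounds; in practice a handful).

Numerical guards: `ln(1 − c_i)` is undefined at `c_i = 1`, so completeness
is floored at 0.999 inside the logarithms — a genome can never be *certain*
to contain a gene it appears to lack. Symmetrically, `p_i` is clamped to
[1e−9, 0.998], strictly below the floored completeness ceiling, so that in
the all-genomes-complete limit a cluster present everywhere always prefers
the core model and a single absence always defeats it; in that limit the
classification is exact by construction. The initialization threshold and
iteration cap are arguments. Exact numerical agreement with any particular
external implementation of this model family is not claimed; the structure,
not a specific codebase, is the contract.

## Phylogeny handling

Alignment blocks for single-copy core genes arrive pre-aligned (alignment
itself is out of scope); `concatenate_scg_alignments()` validates
single-copy-ness and equal widths, gap-fills genomes missing a block, and
emits the supermatrix with a RAxML-style partition table. Tree inference is
likewise out of scope: trees are imported as newick.

Midpoint rooting (via `phangorn`) places the root halfway along the longest
leaf-to-leaf path — equivalently, the rooting minimizing the maximum
root-to-leaf depth, which the test suite verifies against a brute-force
search over every edge. Topology comparison uses the Robinson–Foulds
distance (bipartitions unique to one tree), normalized by `2(n − 3)`;
it is verified against an exhaustive bipartition enumeration. RF is a
deliberately simple quantitative proxy for visual tree-comparison
workflows; no significance statement is attached to it.

CAZyme profiling parses the category as the leading letters of the family
accession (GH13 → GH); accessions outside GH/GT/PL/CE/AA/CBM are collected
under "other" with a warning. Whether a multi-family gene counts once per
category or once per hit is ambiguous in common usage, so both modes exist;
the default counts genes, not hits, to avoid double-counting multi-domain
proteins within a category.

## The synthetic generators

The generators exist so that every operation has a closed loop from input
files to results without external data, at sizes a laptop handles in
seconds. Each draws from its own stream derived from the master seed, so
adding a generator never perturbs another's output.

- `simulate_genome()` emits open reading frames (ATG + non-stop codons +
  stop) on both strands, non-overlapping, across contigs at a target GC,
  plus COG/CAZyme annotations and a grouped transporter collection —
  a scaled-down analogue of a multi-system transporter inventory with
  substrate-binding/permease/ATPase components.
- `simulate_coverage_samples()` draws per-gene counts from a multinomial
  over `rate × length` at a chosen library size, the simplest model in
  which TPM recovers the rates exactly in expectation.
- `simulate_pangenome()` defaults mirror the recovery experiment the
  classifier is tested under: 30 genomes, completeness ~ Uniform(0.7, 0.95),
  200 core clusters, 800 accessory clusters with per-cluster presence
  probability ~ Uniform(0.05, 0.5), observation = truth thinned by
  completeness dropout.

What they do **not** emulate: real codon usage or sequence homology
structure (unique genes are random ORFs, so similarity between non-shared
genes is effectively zero), contamination (extra genes from foreign
genomes), correlated dropout along contigs, overdispersed expression counts,
or batch effects between studies. Passing tests therefore demonstrate
algorithmic correctness under the stated models, not robustness to every
artifact of real data; the classifier's recovery rates, in particular, are
statements about completeness-dropout noise, not about mis-binned MAGs.

## Problem sizes and determinism

The shipped tests and the acceptance script run the clustering oracle on
20-node graphs, tree oracles on trees of up to 8 leaves (100 replicates),
core-recovery on 20 simulated pangenomes of 1,000 clusters × 30 genomes,
and t-test calibration on 2,000 genes × 12 samples — sizes chosen so the
whole suite completes in a few minutes while keeping every Monte-Carlo
check's standard error well inside its asserted band. All randomness flows
from explicit seeds; reruns are bit-reproducible.

## Known limitations

- The built-in aligner-based similarity graph is quadratic in total gene
  count; hundreds of genomes require importing external search results.
- ANI's local-alignment search is exhaustive per fragment and likewise
  desk-scale by design.
- The package object lives in memory; layers are not lazily loaded.
- No merge/diff between divergent package forks, no remote sync, no access
  control; versioning is linear.
- The accessory model treats genomes as independent draws from one pool; it
  does not model lineage-specific accessory gene families.
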