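# Deterministic synthetic-data generators. Every input class the toolkit
# consumes (genomes, gene calls, annotations, coverage samples, proteomes,
# pangenome presence matrices) can be generated at toy scale from a seed,
# so the whole pipeline is testable without external downloads.
#
# Each generator draws from its own stream, derived from the master seed, so
# adding a generator never perturbs the output of an existing one.

stream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 100003 + offset) %% 2147483629)
}

with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(stream_seed(seed, offset))
  force(expr)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

random_orf <- function(aa_length, gc) {
  # ATG + non-stop codons + TAA; stops are resampled so the frame is open
  codons <- character(aa_length - 1L)
  k <- 1L
  while (k <= length(codons)) {
    cod <- paste(random_bases(3L, gc), collapse = "")
    if (cod %in% STOP_CODONS) next
    codons[k] <- cod
    k <- k + 1L
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

assemble_genome <- function(orfs, gc, intergenic_bp, n_contigs, contig_prefix) {
  n <- length(orfs)
  strands <- rep(c("+", "-"), length.out = n)
  contig_of <- sort(rep(seq_len(n_contigs), length.out = n))
  contigs <- character(n_contigs)
  calls <- empty_gene_calls()
  for (ci in seq_len(n_contigs)) {
    seq_parts <- paste(random_bases(intergenic_bp, gc), collapse = "")
    pos <- intergenic_bp
    for (gi in which(contig_of == ci)) {
      placed <- if (strands[gi] == "+") orfs[gi] else revcomp_chr(orfs[gi])
      calls <- rbind(calls, data.frame(
        gene_id = gi - 1L, contig = paste0(contig_prefix, ci),
        start = as.integer(pos), stop = as.integer(pos + nchar(placed)),
        strand = strands[gi],
        partial = FALSE, source = "synthetic", stringsAsFactors = FALSE))
      spacer <- paste(random_bases(intergenic_bp, gc), collapse = "")
      seq_parts <- paste0(seq_parts, placed, spacer)
      pos <- pos + nchar(placed) + intergenic_bp
    }
    contigs[ci] <- seq_parts
  }
  names(contigs) <- paste0(contig_prefix, seq_len(n_contigs))
  list(contigs = contigs, gene_calls = calls)
}

#' Simulate a genome package
#'
#' Generates a toy genome: non-overlapping protein-coding genes on both
#' strands across `n_contigs` contigs at a target GC content, with CAZyme
#' and COG annotations and a grouped "transporters" gene collection
#' (substrate-binding / permease / ATPase components per system, a
#' scaled-down version of a multi-system transporter inventory).
#'
#' @param seed Master seed; the same seed gives byte-identical output.
#' @param n_genes Number of genes (default 12).
#' @param gene_length_aa Protein length in amino acids (default 80).
#' @param gc_content Target GC fraction (default 0.5).
#' @param n_contigs Number of contigs (default 2).
#' @param intergenic_bp Spacer length between genes (default 60).
#' @param n_transporter_systems Transporter systems in the collection; each
#'   takes 3 consecutive genes (substrate_binding, permease, ATPase).
#' @param cazyme_families Pool of CAZyme family accessions assigned to a
#'   subset of genes.
#' @param name Package name.
#' @return A `dm_package` with genome, gene calls, `COG` and `CAZyme`
#'   annotation layers and a `transporters` collection.
#' @export
simulate_genome <- function(seed = 1, n_genes = 12, gene_length_aa = 80,
                            gc_content = 0.5, n_contigs = 2, intergenic_bp = 60,
                            n_transporter_systems = 2,
                            cazyme_families = c("GH13", "GH5", "GT2", "PL1", "CBM48", "CE1"),
                            name = "toy_genome") {
  stopifnot(n_genes >= 1, gene_length_aa >= 10, gc_content > 0, gc_content < 1)
  if (3 * n_transporter_systems > n_genes) {
    stop("need at least 3 genes per transporter system")
  }
  with_stream(seed, 11L, {
    orfs <- vapply(seq_len(n_genes), function(i) random_orf(gene_length_aa, gc_content),
                   character(1))
    g <- assemble_genome(orfs, gc_content, intergenic_bp, n_contigs,
                         contig_prefix = paste0(name, "_c"))
    pkg <- create_package(name, "genome")
    pkg <- set_genome_sequences(pkg, g$contigs)
    pkg$genome$gene_calls <- g$gene_calls

    gene_ids <- g$gene_calls$gene_id
    cog <- data.frame(gene_id = gene_ids,
                      accession = sprintf("COG%04d", seq_along(gene_ids)),
                      `function` = sprintf("hypothetical function %d", seq_along(gene_ids)),
                      score = round(stats::runif(length(gene_ids), 50, 500), 1),
                      check.names = FALSE, stringsAsFactors = FALSE)
    pkg <- import_functional_annotations(pkg, cog, source = "COG")

    n_caz <- max(1L, n_genes %/% 3L)
    caz_genes <- sort(sample(gene_ids, n_caz))
    caz <- data.frame(gene_id = caz_genes,
                      accession = sample(cazyme_families, n_caz, replace = TRUE),
                      `function` = "carbohydrate-active enzyme",
                      check.names = FALSE, stringsAsFactors = FALSE)
    pkg <- import_functional_annotations(pkg, caz, source = "CAZyme")

    if (n_transporter_systems > 0) {
      roles <- c("substrate_binding", "permease", "ATPase")
      t_genes <- gene_ids[seq_len(3 * n_transporter_systems)]
      groups <- paste0("system_", rep(seq_len(n_transporter_systems), each = 3), ":",
                       rep(roles, n_transporter_systems))
      pkg <- define_collection(pkg, "transporters", t_genes, groups)
    }
    pkg
  })
}

#' Simulate a set of related genomes for pangenome tests
#'
#' Generates `n_genomes` genomes that share `n_shared` identical genes and
#' carry `n_unique` genome-specific genes each, so the expected pangenome
#' has `n_shared` clusters of size `n_genomes` plus
#' `n_genomes * n_unique` singletons.
#'
#' @inheritParams simulate_genome
#' @param n_genomes Number of genomes (default 3).
#' @param n_shared Genes shared identically by all genomes.
#' @param n_unique Genome-specific genes per genome.
#' @return Named list of `dm_package` genome packages.
#' @export
simulate_related_genomes <- function(seed = 1, n_genomes = 3, n_shared = 5,
                                     n_unique = 2, gene_length_aa = 60,
                                     gc_content = 0.5, intergenic_bp = 40) {
  with_stream(seed, 23L, {
    shared <- vapply(seq_len(n_shared), function(i) random_orf(gene_length_aa, gc_content),
                     character(1))
    out <- list()
    for (gi in seq_len(n_genomes)) {
      gname <- paste0("genome_", gi)
      uniq <- vapply(seq_len(n_unique), function(i) random_orf(gene_length_aa, gc_content),
                     character(1))
      orfs <- c(shared, uniq)
      g <- assemble_genome(orfs, gc_content, intergenic_bp, n_contigs = 1L,
                           contig_prefix = paste0(gname, "_c"))
      pkg <- create_package(gname, "genome")
      pkg <- set_genome_sequences(pkg, g$contigs)
      pkg$genome$gene_calls <- g$gene_calls
      ann <- data.frame(
        gene_id = g$gene_calls$gene_id,
        accession = c(sprintf("COG%04d", seq_len(n_shared)),
                      sprintf("COG9%03d", (gi - 1L) * n_unique + seq_len(n_unique))),
        `function` = "synthetic gene",
        check.names = FALSE, stringsAsFactors = FALSE)
      pkg <- import_functional_annotations(pkg, ann, source = "COG")
      out[[gname]] <- pkg
    }
    out
  })
}

#' Simulate per-sample per-gene read counts
#'
#' Draws each sample's counts from a multinomial over `rates * lengths`
#' (expression rate times gene length, the expected read share under uniform
#' coverage) at the given library size; mean coverage assumes 100 bp reads.
#' The proportional-expression truth is recoverable from `rates`.
#'
#' @param seed Master seed.
#' @param gene_ids Integer gene ids.
#' @param gene_lengths Gene lengths in bp.
#' @param rates Non-negative per-gene expression rates (one vector applied to
#'   all samples, or a genes x samples matrix).
#' @param n_samples Number of samples (ignored when `rates` is a matrix).
#' @param library_size Total reads per sample (default 1e5).
#' @return Named list of data frames (`gene_id`, `read_count`,
#'   `mean_coverage`), one per sample.
#' @export
simulate_coverage_samples <- function(seed = 1, gene_ids, gene_lengths, rates,
                                      n_samples = 1, library_size = 1e5) {
  if (any(rates < 0)) stop("rates must be non-negative")
  if (is.matrix(rates)) {
    n_samples <- ncol(rates)
  } else {
    rates <- matrix(rep(rates, n_samples), ncol = n_samples)
  }
  stopifnot(nrow(rates) == length(gene_ids), length(gene_lengths) == length(gene_ids))
  with_stream(seed, 37L, {
    out <- lapply(seq_len(n_samples), function(s) {
      w <- rates[, s] * gene_lengths
      counts <- if (sum(w) == 0) rep(0L, length(w)) else {
        as.integer(stats::rmultinom(1, size = library_size, prob = w / sum(w)))
      }
      data.frame(gene_id = gene_ids, read_count = counts,
                 mean_coverage = counts * 100 / gene_lengths,
                 stringsAsFactors = FALSE)
    })
    names(out) <- paste0("S", seq_len(n_samples))
    out
  })
}

#' Simulate a pangenome presence matrix with completeness dropout
#'
#' True presence: core clusters occur in every genome; each accessory
#' cluster occurs in a genome with its own per-cluster probability drawn
#' uniformly from `presence_range`. Observed presence applies completeness
#' dropout: a truly present gene is observed with probability `c_i`, the
#' genome's completeness. True labels are returned for recovery scoring.
#'
#' @param seed Master seed.
#' @param n_genomes Number of genomes (default 30).
#' @param n_core True core clusters (default 200).
#' @param n_accessory True accessory clusters (default 800).
#' @param completeness_range Uniform range for per-genome completeness
#'   (default `c(0.7, 0.95)`).
#' @param presence_range Uniform range for per-cluster accessory presence
#'   probability (default `c(0.05, 0.5)`).
#' @return List with `presence` (observed binary matrix),
#'   `true_presence`, `completeness`, `truth` (label vector).
#' @export
simulate_pangenome <- function(seed = 1, n_genomes = 30, n_core = 200,
                               n_accessory = 800,
                               completeness_range = c(0.7, 0.95),
                               presence_range = c(0.05, 0.5)) {
  with_stream(seed, 53L, {
    n <- n_core + n_accessory
    comp <- stats::runif(n_genomes, completeness_range[1], completeness_range[2])
    truth <- rep(c("core", "accessory"), c(n_core, n_accessory))
    true_presence <- matrix(0L, n, n_genomes)
    true_presence[seq_len(n_core), ] <- 1L
    if (n_accessory > 0) {
      pp <- stats::runif(n_accessory, presence_range[1], presence_range[2])
      true_presence[n_core + seq_len(n_accessory), ] <-
        matrix(stats::rbinom(n_accessory * n_genomes, 1, rep(pp, n_genomes)),
               n_accessory, n_genomes)
    }
    dropout <- matrix(stats::rbinom(n * n_genomes, 1, rep(comp, each = n)),
                      n, n_genomes)
    observed <- true_presence * dropout
    rownames(observed) <- rownames(true_presence) <-
      sprintf("SC_%05d", seq_len(n))
    colnames(observed) <- colnames(true_presence) <-
      sprintf("g%02d", seq_len(n_genomes))
    names(comp) <- colnames(observed)
    list(presence = observed, true_presence = true_presence,
         completeness = comp, truth = truth)
  })
}

#' Write a genome package's inputs as plain files
#'
#' Emits the fixture in the same formats the import operations read (FASTA,
#' external gene-calls TSV, annotation TSVs), closing the generator/import
#' loop.
#'
#' @param pkg A `dm_package` (e.g. from [simulate_genome()]).
#' @param out_dir Output directory.
#' @return Invisible named vector of written paths.
#' @export
write_fixture_files <- function(pkg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(out_dir, "genome.fasta"),
             gene_calls = file.path(out_dir, "gene_calls.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pkg$genome$contigs),
                              paths[["fasta"]], width = 80L)
  write_canonical_tsv(gene_calls(pkg), paths[["gene_calls"]])
  for (src in unique(functional_annotations(pkg)$source)) {
    p <- file.path(out_dir, paste0("annotations_", safe_filename(src), ".tsv"))
    ann <- functional_annotations(pkg, src)
    write_canonical_tsv(ann[, c("gene_id", "accession", "function", "score")], p)
    paths[[paste0("annotations_", src)]] <- p
  }
  invisible(paths)
}
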