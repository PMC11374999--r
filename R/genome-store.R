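# Genome sequences, gene calls and multi-source functional annotations:
# the coordinate / gene-id spine every data layer references.
#
# Coordinates are stored 0-based half-open; GFF3 (1-based closed) is
# converted at the I/O boundary. Gene ids are dense integers assigned in
# file order at import and stable thereafter.

#' Load genome sequences from FASTA
#'
#' Reads contigs, uppercases them and validates the alphabet (`A,C,G,T,N`)
#' and id uniqueness.
#'
#' @param fasta_path Path to a FASTA file.
#' @return Named character vector of uppercase contig sequences.
#' @export
load_genome_sequences <- function(fasta_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no sequences in ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("illegal characters in contig(s): ", paste(ids[bad], collapse = ", "))
  }
  stats::setNames(chars, ids)
}

#' Attach genome sequences to a package
#'
#' @param pkg A `dm_package` of kind `"genome"`.
#' @param contigs Named character vector from [load_genome_sequences()], or a
#'   FASTA path.
#' @return The updated package.
#' @export
set_genome_sequences <- function(pkg, contigs) {
  stopifnot(inherits(pkg, "dm_package"))
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- load_genome_sequences(contigs)
  }
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("contigs must be named")
  }
  pkg$genome$contigs <- stats::setNames(toupper(contigs), names(contigs))
  pkg
}

empty_gene_calls <- function() {
  data.frame(gene_id = integer(0), contig = character(0), start = integer(0),
             stop = integer(0), strand = character(0), partial = logical(0),
             source = character(0), stringsAsFactors = FALSE)
}

validate_gene_calls <- function(calls, contigs) {
  clen <- nchar(contigs)
  unknown <- !(calls$contig %in% names(contigs))
  if (any(unknown)) {
    stop("gene call row(s) ", paste(which(unknown), collapse = ", "),
         " reference unknown contig(s): ",
         paste(unique(calls$contig[unknown]), collapse = ", "))
  }
  if (any(!calls$strand %in% c("+", "-"))) {
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(calls$strand, c("+", "-"))), collapse = ", "))
  }
  oob <- calls$start < 0L | calls$start >= calls$stop |
    calls$stop > clen[calls$contig]
  if (any(oob)) {
    stop("out-of-bounds coordinates for gene(s): ",
         paste(calls$gene_id[oob], collapse = ", "))
  }
  invisible(calls)
}

#' Import gene calls
#'
#' Reads gene models from GFF3 (1-based closed coordinates, converted to the
#' internal 0-based half-open convention) or from a tabular external-calls
#' file with columns `gene_id, contig, start, stop, strand, partial` already
#' in 0-based half-open coordinates. Gene ids are dense integers in file
#' order (`0..n-1`) for GFF3; the external format supplies its own.
#'
#' @param pkg A `dm_package` with genome sequences attached.
#' @param path Input file.
#' @param format `"gff3"` or `"external_tsv"`.
#' @return The updated package; the number of imported genes is
#'   `nrow(gene_calls(pkg))`.
#' @export
import_gene_calls <- function(pkg, path, format = c("gff3", "external_tsv")) {
  stopifnot(inherits(pkg, "dm_package"))
  format <- match.arg(format)
  if (is.null(pkg$genome$contigs)) stop("load genome sequences before gene calls")

  calls <- if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type %in% c("CDS", "gene")]
    if (length(gr) == 0L) stop("no CDS/gene features in ", path)
    # prefer CDS when both present
    if (any(gr$type == "CDS")) gr <- gr[gr$type == "CDS"]
    strand <- as.character(BiocGenerics::strand(gr))
    partial <- if (!is.null(gr$partial)) {
      tolower(as.character(gr$partial)) %in% c("true", "1", "yes")
    } else rep(FALSE, length(gr))
    data.frame(
      gene_id = seq_along(gr) - 1L,
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      stop = BiocGenerics::end(gr),
      strand = strand,
      partial = partial,
      source = if (!is.null(gr$source)) as.character(gr$source) else "gff3",
      stringsAsFactors = FALSE
    )
  } else {
    df <- read_layer_tsv(path)
    need <- c("gene_id", "contig", "start", "stop", "strand")
    missing <- setdiff(need, names(df))
    if (length(missing)) stop("external_tsv is missing column(s): ",
                              paste(missing, collapse = ", "))
    data.frame(
      gene_id = as.integer(df$gene_id),
      contig = as.character(df$contig),
      start = as.integer(df$start),
      stop = as.integer(df$stop),
      strand = as.character(df$strand),
      partial = if ("partial" %in% names(df)) as.logical(df$partial) else FALSE,
      source = if ("source" %in% names(df)) as.character(df$source) else "external",
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(calls$gene_id)) stop("duplicate gene_id in ", path)
  validate_gene_calls(calls, pkg$genome$contigs)
  pkg$genome$gene_calls <- calls
  pkg
}

#' @rdname import_gene_calls
#' @export
gene_calls <- function(pkg) {
  if (is.null(pkg$genome$gene_calls)) empty_gene_calls() else pkg$genome$gene_calls
}

#' Export gene calls as GFF3 (1-based closed coordinates)
#' @param pkg A `dm_package` with gene calls.
#' @param path Output GFF3 path.
#' @export
export_gene_calls_gff3 <- function(pkg, path) {
  calls <- gene_calls(pkg)
  if (nrow(calls) == 0L) stop("no gene calls to export")
  gr <- GenomicRanges::GRanges(
    seqnames = calls$contig,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$stop),
    strand = calls$strand
  )
  gr$type <- "CDS"
  gr$source <- calls$source
  gr$ID <- as.character(calls$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Import functional annotations
#'
#' Reads a TSV with columns `gene_id, accession, function` and optional
#' `score` (e-value or bitscore), stores the rows for `source` and registers
#' (or updates) the `annotation:<source>` layer. Annotations from different
#' sources are kept side by side, never merged. A re-import without
#' `overwrite` appends only new `(gene_id, accession)` pairs; with
#' `overwrite` the source's table is replaced.
#'
#' @param pkg A `dm_package` with gene calls.
#' @param tsv_path Annotation TSV path (or a data frame).
#' @param source Annotation source name, e.g. `"COG"`, `"KOfam"`, `"CAZyme"`.
#' @param overwrite Replace the existing table for this source.
#' @return The updated package.
#' @export
import_functional_annotations <- function(pkg, tsv_path, source, overwrite = FALSE) {
  stopifnot(inherits(pkg, "dm_package"))
  df <- if (is.data.frame(tsv_path)) tsv_path else read_layer_tsv(tsv_path)
  need <- c("gene_id", "accession", "function")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("annotation table is missing column(s): ",
                            paste(missing, collapse = ", "))
  ann <- data.frame(gene_id = as.integer(df$gene_id),
                    source = source,
                    accession = as.character(df$accession),
                    `function` = as.character(df[["function"]]),
                    score = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if ("score" %in% names(df) && anyNA(ann$score) && !anyNA(df$score)) {
    stop("malformed score value(s) in annotation table")
  }
  known <- gene_calls(pkg)$gene_id
  bad <- !(ann$gene_id %in% known)
  if (any(bad)) {
    stop("annotation row(s) ", paste(which(bad), collapse = ", "),
         " reference unknown gene_id(s): ",
         paste(unique(ann$gene_id[bad]), collapse = ", "))
  }

  layer_id <- paste0("annotation:", source)
  existing <- pkg$genome$annotations
  existing_src <- if (is.null(existing)) NULL else existing[existing$source == source, , drop = FALSE]

  if (!is.null(existing_src) && nrow(existing_src) > 0L && !overwrite) {
    key_old <- paste(existing_src$gene_id, existing_src$accession)
    key_new <- paste(ann$gene_id, ann$accession)
    ann <- rbind(existing_src, ann[!(key_new %in% key_old), , drop = FALSE])
  }
  rownames(ann) <- NULL

  rest <- if (is.null(existing)) NULL else existing[existing$source != source, , drop = FALSE]
  pkg$genome$annotations <- rbind(rest, ann)
  rownames(pkg$genome$annotations) <- NULL

  if (layer_id %in% package_layers(pkg)) {
    update_layer(pkg, layer_id, ann,
                 paste0("updated annotations for source '", source, "'"))
  } else {
    register_layer(pkg, layer_id, "annotation_source", ann,
                   provenance = paste0("functional annotations, source=", source))
  }
}

#' @rdname import_functional_annotations
#' @export
functional_annotations <- function(pkg, source = NULL) {
  ann <- pkg$genome$annotations
  if (is.null(ann)) {
    ann <- data.frame(gene_id = integer(0), source = character(0),
                      accession = character(0), `function` = character(0),
                      score = numeric(0), check.names = FALSE)
  }
  if (!is.null(source)) ann <- ann[ann$source %in% source, , drop = FALSE]
  ann
}

#' Basic genome statistics
#'
#' GC fraction is computed over informative bases only (`N` excluded); gene
#' density is genes per kilobase of total genome length.
#'
#' @param pkg A `dm_package` with genome sequences.
#' @return List with `total_length`, `gc_fraction`, `num_genes`,
#'   `genes_per_kbp`.
#' @export
genome_stats <- function(pkg) {
  contigs <- pkg$genome$contigs
  if (is.null(contigs) || length(contigs) == 0L) stop("package has no genome sequences")
  seqs <- Biostrings::DNAStringSet(contigs)
  freq <- colSums(Biostrings::alphabetFrequency(seqs)[, c("A", "C", "G", "T"), drop = FALSE])
  total_length <- sum(nchar(contigs))
  informative <- sum(freq)
  gc <- if (informative == 0) NA_real_ else (freq[["G"]] + freq[["C"]]) / informative
  n_genes <- nrow(gene_calls(pkg))
  list(total_length = total_length,
       gc_fraction = gc,
       num_genes = n_genes,
       genes_per_kbp = n_genes / (total_length / 1000))
}

#' Extract a gene's DNA sequence
#'
#' Returns the spliced-out gene sequence; minus-strand genes are
#' reverse-complemented.
#'
#' @param pkg A `dm_package`.
#' @param gene_id Integer gene id.
#' @return DNA string.
#' @export
get_gene_sequence <- function(pkg, gene_id) {
  calls <- gene_calls(pkg)
  row <- calls[calls$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown gene_id ", gene_id)
  contig <- pkg$genome$contigs[[row$contig]]
  s <- substr(contig, row$start + 1L, row$stop)
  if (row$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Check that every annotation joins to a gene call
#' @param pkg A `dm_package`.
#' @return Integer vector of orphan gene ids (empty on a valid package).
#' @export
orphan_annotations <- function(pkg) {
  ann <- functional_annotations(pkg)
  setdiff(unique(ann$gene_id), gene_calls(pkg)$gene_id)
}
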