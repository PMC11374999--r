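# Gene-referenced experimental layers: per-sample transcript coverage,
# proteome spectral counts with NSAF, arbitrary per-gene data, and named
# gene collections ("bins"). TPM/NSAF arithmetic lives here too.

#' TPM normalization
#'
#' Transcripts per million. In `mode = "count"` the per-gene rate is
#' `read_count / length`; in `mode = "coverage"` the supplied values are mean
#' coverages, which are already length-normalized and are used as rates
#' directly. TPM is each rate divided by the sum of rates, times 1e6, so a
#' non-degenerate sample sums to exactly one million.
#'
#' @param values Named numeric vector of read counts (`mode = "count"`) or
#'   mean coverages (`mode = "coverage"`).
#' @param gene_lengths Positive gene lengths in bp, matching `values`
#'   (required for `mode = "count"`; ignored for `"coverage"`).
#' @param mode `"count"` or `"coverage"`.
#' @return Named numeric vector of TPM values.
#' @examples
#' tpm_normalize(c(A = 100, B = 300, C = 0), c(A = 1000, B = 1000, C = 500))
#' @export
tpm_normalize <- function(values, gene_lengths = NULL, mode = c("count", "coverage")) {
  mode <- match.arg(mode)
  if (any(values < 0, na.rm = TRUE)) stop("negative values")
  rates <- if (mode == "count") {
    if (is.null(gene_lengths)) stop("gene_lengths required for mode = 'count'")
    if (length(gene_lengths) != length(values)) stop("lengths do not match values")
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
    values / gene_lengths
  } else {
    values
  }
  total <- sum(rates)
  if (total == 0) {
    warning("all-zero sample: TPM is all zeros")
    return(stats::setNames(rep(0, length(values)), names(values)))
  }
  stats::setNames(rates / total * 1e6, names(values))
}

#' NSAF normalization
#'
#' Normalized spectral abundance factor: each protein's spectral count is
#' divided by its length, and the resulting rates are normalized to sum to 1
#' across detected proteins, making abundances comparable across proteomes.
#'
#' @param spectral_counts Named non-negative numeric vector.
#' @param lengths_aa Positive protein lengths (amino acids), matching.
#' @return Named numeric vector of NSAF values summing to 1.
#' @export
nsaf_normalize <- function(spectral_counts, lengths_aa) {
  if (length(spectral_counts) != length(lengths_aa)) stop("lengths do not match counts")
  if (any(lengths_aa <= 0)) stop("protein lengths must be positive")
  if (any(spectral_counts < 0)) stop("negative spectral counts")
  rates <- spectral_counts / lengths_aa
  total <- sum(rates)
  if (total == 0) stop("no detected proteins (all spectral counts zero)")
  stats::setNames(rates / total, names(spectral_counts))
}

coverage_layer_id <- function(sample_id) paste0("coverage:", sample_id)

#' Add a per-sample coverage layer
#'
#' Registers one transcriptome (or metagenome) sample's per-gene read counts
#' and mean coverages as a versioned layer. Genes absent from the table are
#' imputed as zero with a warning; the sample's total mapped reads (the TPM
#' denominator the sample was sequenced at) defaults to the read-count column
#' sum with a warning when not supplied.
#'
#' @param pkg A `dm_package` with gene calls.
#' @param sample_id Unique sample identifier.
#' @param counts Data frame (or TSV path) with columns `gene_id`,
#'   `read_count` and optionally `mean_coverage`.
#' @param total_mapped_reads Integer denominator for the sample.
#' @return The updated package.
#' @export
add_coverage_layer <- function(pkg, sample_id, counts, total_mapped_reads = NULL) {
  stopifnot(inherits(pkg, "dm_package"))
  if (coverage_layer_id(sample_id) %in% package_layers(pkg)) {
    stop("sample '", sample_id, "' already has a coverage layer")
  }
  if (!is.data.frame(counts)) counts <- read_layer_tsv(counts)
  if (!all(c("gene_id", "read_count") %in% names(counts))) {
    stop("counts need columns gene_id and read_count")
  }
  if (any(counts$read_count < 0)) stop("negative read counts")
  genes <- gene_calls(pkg)$gene_id
  if (length(genes) == 0L) stop("import gene calls before coverage layers")

  df <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  idx <- match(genes, counts$gene_id)
  df$read_count <- ifelse(is.na(idx), 0, counts$read_count[idx])
  df$mean_coverage <- if ("mean_coverage" %in% names(counts)) {
    ifelse(is.na(idx), 0, counts$mean_coverage[idx])
  } else 0
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " gene(s) missing from sample '", sample_id,
            "'; imputed zero")
  }
  if (is.null(total_mapped_reads)) {
    total_mapped_reads <- sum(df$read_count)
    warning("total_mapped_reads not supplied for '", sample_id,
            "'; defaulting to the column sum (", total_mapped_reads, ")")
  }
  register_layer(pkg, coverage_layer_id(sample_id), "coverage_sample", df,
                 provenance = paste0("coverage sample ", sample_id),
                 meta = list(sample_id = sample_id,
                             total_mapped_reads = total_mapped_reads))
}

#' Merge coverage samples into a genes x samples matrix
#'
#' @param pkg A `dm_package` with coverage layers.
#' @param sample_ids Samples to merge (default: all coverage layers, in
#'   registration order).
#' @param value `"read_count"` or `"mean_coverage"`.
#' @return Numeric matrix, rows = gene ids, columns = samples.
#' @export
merge_samples <- function(pkg, sample_ids = NULL, value = c("read_count", "mean_coverage")) {
  value <- match.arg(value)
  recs <- Filter(function(r) r$layer_type == "coverage_sample", pkg$manifest$layers)
  all_samples <- vapply(recs, function(r) r$meta$sample_id, character(1))
  if (is.null(sample_ids)) sample_ids <- all_samples
  missing <- setdiff(sample_ids, all_samples)
  if (length(missing)) stop("no coverage layer for sample(s): ",
                            paste(missing, collapse = ", "))
  genes <- gene_calls(pkg)$gene_id
  mat <- vapply(sample_ids, function(s) {
    df <- get_layer(pkg, coverage_layer_id(s))
    df[[value]][match(genes, df$gene_id)]
  }, numeric(length(genes)))
  if (length(genes) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, sample_ids))
  rownames(mat) <- as.character(genes)
  mat
}

#' Sample total mapped reads recorded at import
#' @inheritParams merge_samples
#' @export
sample_total_reads <- function(pkg, sample_ids = NULL) {
  recs <- Filter(function(r) r$layer_type == "coverage_sample", pkg$manifest$layers)
  totals <- vapply(recs, function(r) as.numeric(r$meta$total_mapped_reads), numeric(1))
  names(totals) <- vapply(recs, function(r) r$meta$sample_id, character(1))
  if (!is.null(sample_ids)) totals <- totals[sample_ids]
  totals
}

#' Add a proteome layer with NSAF
#'
#' Stores spectral counts per protein (keyed by gene id) and their NSAF
#' values as a versioned layer.
#'
#' @param pkg A `dm_package`.
#' @param sample_id Proteome sample id.
#' @param proteome Data frame (or TSV path) with columns `gene_id`,
#'   `spectral_count`, `length_aa`.
#' @return The updated package.
#' @export
add_proteome_layer <- function(pkg, sample_id, proteome) {
  if (!is.data.frame(proteome)) proteome <- read_layer_tsv(proteome)
  need <- c("gene_id", "spectral_count", "length_aa")
  if (!all(need %in% names(proteome))) {
    stop("proteome needs columns ", paste(need, collapse = ", "))
  }
  nsaf <- nsaf_normalize(proteome$spectral_count, proteome$length_aa)
  df <- data.frame(gene_id = proteome$gene_id,
                   spectral_count = proteome$spectral_count,
                   length_aa = proteome$length_aa,
                   nsaf = as.numeric(nsaf), stringsAsFactors = FALSE)
  register_layer(pkg, paste0("proteome:", sample_id), "proteome", df,
                 provenance = paste0("proteome sample ", sample_id, ", NSAF-normalized"),
                 meta = list(sample_id = sample_id))
}

#' Import an arbitrary per-gene data layer
#'
#' Numeric or categorical values keyed to gene ids (e.g. mutant availability,
#' fitness scores).
#'
#' @param pkg A `dm_package` with gene calls.
#' @param layer_name Layer name; registered as `misc:<layer_name>`.
#' @param values Data frame (or TSV path) with columns `gene_id`, `value`.
#' @return The updated package.
#' @export
import_misc_data <- function(pkg, layer_name, values) {
  if (!is.data.frame(values)) values <- read_layer_tsv(values)
  if (!all(c("gene_id", "value") %in% names(values))) {
    stop("misc data needs columns gene_id and value")
  }
  known <- gene_calls(pkg)$gene_id
  bad <- !(values$gene_id %in% known)
  if (any(bad)) {
    stop("misc data row(s) ", paste(which(bad), collapse = ", "),
         " reference unknown gene_id(s)")
  }
  register_layer(pkg, paste0("misc:", layer_name), "misc_gene_data",
                 values, provenance = paste0("misc gene data '", layer_name, "'"))
}

#' Define a named gene collection ("bin")
#'
#' An ordered set of genes analyzed jointly, optionally grouped (e.g.
#' transporter systems with substrate-binding / permease / ATPase components).
#'
#' @param pkg A `dm_package` with gene calls.
#' @param name Collection name; registered as `collection:<name>`.
#' @param gene_ids Ordered gene ids, no duplicates.
#' @param groups Optional per-gene group labels (recycled names not allowed;
#'   same length as `gene_ids`).
#' @return The updated package.
#' @export
define_collection <- function(pkg, name, gene_ids, groups = NULL) {
  known <- gene_calls(pkg)$gene_id
  if (anyDuplicated(gene_ids)) stop("duplicate gene id(s) in collection")
  bad <- !(gene_ids %in% known)
  if (any(bad)) stop("unknown gene id(s) in collection: ",
                     paste(gene_ids[bad], collapse = ", "))
  if (!is.null(groups) && length(groups) != length(gene_ids)) {
    stop("groups must match gene_ids in length")
  }
  df <- data.frame(gene_id = gene_ids,
                   group = if (is.null(groups)) NA_character_ else as.character(groups),
                   stringsAsFactors = FALSE)
  register_layer(pkg, paste0("collection:", name), "collection", df,
                 provenance = paste0("gene collection '", name, "'"))
}

#' @rdname define_collection
#' @export
get_collection <- function(pkg, name) get_layer(pkg, paste0("collection:", name))

#' Summarize a gene collection across samples
#'
#' One row per collection gene (in collection order) with its group label,
#' concatenated annotations, and per-sample read counts and TPM values.
#' Deterministic row and column order; re-export is byte-identical.
#'
#' @param pkg A `dm_package`.
#' @param collection Collection name.
#' @param samples Sample ids (default: all coverage samples).
#' @return Data frame.
#' @export
summarize_collection <- function(pkg, collection, samples = NULL) {
  coll <- get_collection(pkg, collection)
  if (nrow(coll) == 0L) stop("collection '", collection, "' is empty")
  counts <- merge_samples(pkg, samples, value = "read_count")
  samples <- colnames(counts)
  calls <- gene_calls(pkg)
  lengths <- (calls$stop - calls$start)[match(as.integer(rownames(counts)), calls$gene_id)]
  ann <- functional_annotations(pkg)

  out <- data.frame(gene_id = coll$gene_id, group = coll$group,
                    stringsAsFactors = FALSE)
  out$annotations <- vapply(coll$gene_id, function(g) {
    rows <- ann[ann$gene_id == g, , drop = FALSE]
    if (nrow(rows) == 0L) return("")
    rows <- rows[order(rows$source, rows$accession, method = "radix"), , drop = FALSE]
    paste(paste0(rows$source, ":", rows$accession), collapse = ";")
  }, character(1))
  idx <- match(as.character(coll$gene_id), rownames(counts))
  for (s in samples) {
    tpm <- tpm_normalize(counts[, s], lengths, mode = "count")
    out[[paste0("read_count_", s)]] <- counts[idx, s]
    out[[paste0("tpm_", s)]] <- as.numeric(tpm[idx])
  }
  out
}
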