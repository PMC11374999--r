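# Transporter-style expression analysis over a gene collection:
# proportional expression per sample, Euclidean/Ward clustering for display,
# and two-group t-tests with optional BH adjustment.

#' Build a samples x genes TPM matrix for a gene collection
#'
#' @param pkg A `dm_package` with coverage layers.
#' @param collection Collection name.
#' @param samples Sample ids (default: all coverage samples).
#' @return Numeric matrix, rows = samples, columns = gene ids (collection
#'   order), of TPM values computed per sample over the whole genome.
#' @export
collection_tpm_matrix <- function(pkg, collection, samples = NULL) {
  coll <- get_collection(pkg, collection)
  counts <- merge_samples(pkg, samples, value = "read_count")
  calls <- gene_calls(pkg)
  lengths <- (calls$stop - calls$start)[match(as.integer(rownames(counts)), calls$gene_id)]
  tpm <- apply(counts, 2, tpm_normalize, gene_lengths = lengths, mode = "count")
  rownames(tpm) <- rownames(counts)
  out <- t(tpm[as.character(coll$gene_id), , drop = FALSE])
  attr(out, "groups") <- stats::setNames(coll$group, as.character(coll$gene_id))
  out
}

#' Proportional expression over a gene collection
#'
#' Per sample (row), divides each gene's value by the sum over the collection
#' genes, so each row sums to 1: the quantity displayed in a
#' proportional-expression heatmap. All-zero rows stay zero with a warning.
#'
#' @param tpm_matrix Samples x genes numeric matrix (e.g. from
#'   [collection_tpm_matrix()]).
#' @param genes Optional subset of column names defining the collection
#'   (default: all columns).
#' @return Samples x genes matrix of row proportions.
#' @export
proportional_expression <- function(tpm_matrix, genes = NULL) {
  m <- as.matrix(tpm_matrix)
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(m))
    if (length(missing)) stop("collection gene(s) not in matrix: ",
                              paste(missing, collapse = ", "))
    m <- m[, as.character(genes), drop = FALSE]
  }
  if (ncol(m) == 0L) stop("empty collection")
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) left as zeros: ",
            paste(rownames(m)[zero], collapse = ", "))
    totals[zero] <- 1
  }
  sweep(m, 1, totals, "/")
}

#' Hierarchical clustering of an expression matrix for display
#'
#' Euclidean distance with Ward linkage (`hclust` method `"ward.D2"`) on
#' rows and columns; returns orderings and merge trees, not a rendered image.
#'
#' @param matrix Samples x genes numeric matrix with >= 2 rows.
#' @param cluster_columns Also cluster columns (default TRUE when >= 2).
#' @return List with `row_order`, `col_order` (integer permutations),
#'   `row_hclust`, `col_hclust`.
#' @export
cluster_for_display <- function(matrix, cluster_columns = TRUE) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cells <- apply(bad, 1, function(ij) paste0("[", ij[1], ",", ij[2], "]"))
    stop("non-finite cell(s): ", paste(cells, collapse = ", "))
  }
  rh <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
  ch <- NULL
  co <- seq_len(ncol(m))
  if (cluster_columns && ncol(m) >= 2L) {
    ch <- stats::hclust(stats::dist(t(m), method = "euclidean"), method = "ward.D2")
    co <- ch$order
  }
  list(row_order = rh$order, col_order = co, row_hclust = rh, col_hclust = ch)
}

#' Two-group mean difference test for one gene
#'
#' Two-sided t-test of a gene's expression between two condition groups.
#' Default is the classic equal-variance (Student) test; Welch is available.
#' When both groups have zero variance and equal means, `p = 1` by
#' convention.
#'
#' @param matrix Samples x genes numeric matrix.
#' @param design Data frame with columns `sample_id`, `condition` (exactly 2
#'   conditions; every listed sample must be a row of the matrix).
#' @param gene Column name to test.
#' @param variant `"student"` or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
group_difference_test <- function(matrix, design, gene,
                                  variant = c("student", "welch")) {
  variant <- match.arg(variant)
  m <- as.matrix(matrix)
  if (!gene %in% colnames(m)) stop("gene '", gene, "' not in matrix")
  if (!all(design$sample_id %in% rownames(m))) {
    stop("design sample(s) not in matrix: ",
         paste(setdiff(design$sample_id, rownames(m)), collapse = ", "))
  }
  conds <- sort(unique(design$condition), method = "radix")
  if (length(conds) != 2L) stop("design must have exactly 2 conditions")
  x <- m[design$sample_id[design$condition == conds[1]], gene]
  y <- m[design$sample_id[design$condition == conds[2]], gene]
  if (length(x) < 2L || length(y) < 2L) stop("both groups need >= 2 samples")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = if (mean(x) > mean(y)) Inf else -Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Group tests across all genes of a matrix
#'
#' Runs [group_difference_test()] per column and reports raw two-sided
#' p-values together with Benjamini-Hochberg adjusted q-values.
#'
#' @inheritParams group_difference_test
#' @return Data frame with `gene`, `t`, `df`, `p`, `q`.
#' @export
group_difference_table <- function(matrix, design, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  genes <- colnames(as.matrix(matrix))
  rows <- lapply(genes, function(g) {
    res <- group_difference_test(matrix, design, g, variant = variant)
    data.frame(gene = g, t = res$t, df = res$df, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
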