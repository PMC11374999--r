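# CAZyme category profiling: per-genome counts of carbohydrate-active enzyme
# families grouped into the standard categories (GH, GT, PL, CE, AA, CBM),
# plus normalization by the per-category maximum for cross-clade display.

CAZYME_CATEGORIES <- c("GH", "GT", "PL", "CE", "AA", "CBM")

cazyme_category <- function(accession) {
  cat <- sub("^([A-Za-z]+).*$", "\\1", accession)
  toupper(cat)
}

#' Count CAZymes per category per genome
#'
#' Categories are the leading letters of the family accession (GH13 -> GH);
#' accessions outside the six standard categories are collected under
#' `"other"` with a warning. By default a gene annotated with several
#' families of the same category counts once for that category
#' (`per_gene = TRUE`); set `per_gene = FALSE` to count every hit.
#'
#' @param genomes Named list of `dm_package` genome packages, or a
#'   `dm_pangenome` (counted over consensus annotations by member genome).
#' @param source Annotation source holding CAZyme hits (default `"CAZyme"`).
#' @param per_gene Count distinct categories per gene rather than hits.
#' @return Integer matrix, genomes x categories.
#' @export
count_cazymes <- function(genomes, source = "CAZyme", per_gene = TRUE) {
  per_genome_ann <- if (inherits(genomes, "dm_pangenome")) {
    pan <- genomes
    caz <- pan$consensus[pan$consensus$source == source, , drop = FALSE]
    if (nrow(caz) == 0L) stop("no annotations from source '", source, "'")
    memb <- merge(pan$clusters, caz[, c("cluster_id", "accession")], by = "cluster_id")
    ids <- pan$genomes$genome_id
    stats::setNames(lapply(ids, function(g) {
      d <- memb[memb$genome_id == g, , drop = FALSE]
      data.frame(gene_id = d$gene_id, accession = d$accession,
                 stringsAsFactors = FALSE)
    }), ids)
  } else {
    found <- vapply(genomes, function(p) {
      nrow(functional_annotations(p, source)) > 0
    }, logical(1))
    if (!any(found)) stop("no annotations from source '", source, "'")
    lapply(genomes, function(p) {
      a <- functional_annotations(p, source)
      data.frame(gene_id = a$gene_id, accession = a$accession,
                 stringsAsFactors = FALSE)
    })
  }

  cats <- CAZYME_CATEGORIES
  saw_other <- FALSE
  counts <- t(vapply(per_genome_ann, function(ann) {
    if (nrow(ann) == 0L) return(stats::setNames(integer(length(cats) + 1L), c(cats, "other")))
    ann$category <- cazyme_category(ann$accession)
    unknown <- !(ann$category %in% cats)
    if (any(unknown)) {
      saw_other <<- TRUE
      ann$category[unknown] <- "other"
    }
    if (per_gene) ann <- unique(ann[, c("gene_id", "category")])
    tab <- table(factor(ann$category, levels = c(cats, "other")))
    stats::setNames(as.integer(tab), names(tab))
  }, integer(length(cats) + 1L)))
  if (saw_other) warning("accession(s) outside the standard categories counted as 'other'")
  if (!saw_other) counts <- counts[, cats, drop = FALSE]
  counts
}

#' Normalize category counts by the per-category maximum
#'
#' Each cell becomes `count / max over genomes of that category`, so the
#' max-attaining genome scores 1.0; categories absent everywhere stay 0.
#'
#' @param counts Genomes x categories matrix from [count_cazymes()].
#' @return Numeric matrix of fractions in 0..1.
#' @export
normalize_by_category_max <- function(counts) {
  m <- as.matrix(counts)
  maxima <- apply(m, 2, max)
  maxima[maxima == 0] <- 1
  sweep(m, 2, maxima, "/")
}

#' Order a profile matrix to match a tree's leaves
#'
#' Reorders the genome rows to the leaf order of an attached phylogeny so
#' profiles can be drawn alongside the tree.
#'
#' @param counts Genomes x categories matrix.
#' @param tree `ape::phylo` tree whose tip labels are genome ids.
#' @return The reordered matrix.
#' @export
order_by_tree <- function(counts, tree) {
  leaves <- tree_leaf_order(tree)
  missing <- setdiff(leaves, rownames(counts))
  if (length(missing)) stop("profile rows missing for leaf/leaves: ",
                            paste(missing, collapse = ", "))
  counts[leaves, , drop = FALSE]
}
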