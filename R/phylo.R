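# Phylogeny I/O and comparison: concatenated single-copy-core alignments,
# newick read/write, midpoint rooting, tree attachment to a pangenome, and
# Robinson-Foulds topology distance.

#' Concatenate single-copy-core alignment blocks into a supermatrix
#'
#' Each block is one gene cluster's pre-aligned amino-acid sequences, exactly
#' one per genome (single copy). Blocks are concatenated per genome in the
#' given block order; genomes missing from a block are filled with gaps with
#' a warning. A partition table records block boundaries (1-based, closed).
#'
#' @param blocks Named list of blocks; each block is a named character vector
#'   (genome id -> aligned sequence, equal lengths within a block).
#' @param roster Character vector of genome ids to include (default: union of
#'   block genomes).
#' @return List with `supermatrix` (named character vector) and `partitions`
#'   (data frame `block`, `start`, `end`).
#' @export
concatenate_scg_alignments <- function(blocks, roster = NULL) {
  if (length(blocks) == 0L) stop("no alignment blocks")
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  if (is.null(roster)) {
    roster <- sort(unique(unlist(lapply(blocks, names))), method = "radix")
  }
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    if (is.null(names(b))) stop("block '", bn, "' has unnamed rows")
    if (anyDuplicated(names(b))) {
      stop("block '", bn, "' is not single-copy: duplicated genome(s) ",
           paste(unique(names(b)[duplicated(names(b))]), collapse = ", "))
    }
    if (length(unique(nchar(b))) != 1L) {
      stop("block '", bn, "' has rows of unequal length")
    }
  }
  widths <- vapply(blocks, function(b) nchar(b[[1]]), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  partitions <- data.frame(block = names(blocks), start = starts, end = ends,
                           stringsAsFactors = FALSE)
  rownames(partitions) <- NULL

  rows <- vapply(roster, function(g) {
    paste(vapply(names(blocks), function(bn) {
      b <- blocks[[bn]]
      if (g %in% names(b)) b[[g]] else strrep("-", nchar(b[[1]]))
    }, character(1)), collapse = "")
  }, character(1))
  missing_any <- vapply(roster, function(g) {
    any(!vapply(blocks, function(b) g %in% names(b), logical(1)))
  }, logical(1))
  if (any(missing_any)) {
    warning("genome(s) missing from some block(s), gap-filled: ",
            paste(roster[missing_any], collapse = ", "))
  }
  list(supermatrix = rows, partitions = partitions)
}

#' Write a supermatrix as FASTA plus a RAxML-style partition file
#'
#' @param concat Result of [concatenate_scg_alignments()].
#' @param fasta_path,partition_path Output paths.
#' @export
write_supermatrix <- function(concat, fasta_path, partition_path = NULL) {
  seqs <- Biostrings::AAStringSet(concat$supermatrix)
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  if (!is.null(partition_path)) {
    lines <- sprintf("PROT, %s = %d-%d", concat$partitions$block,
                     concat$partitions$start, concat$partitions$end)
    writeLines(lines, partition_path)
  }
  invisible(fasta_path)
}

#' Newick tree I/O
#'
#' Thin wrappers over `ape` with validation: leaf labels must be unique and
#' serialization is lossless for topology and branch lengths.
#'
#' @param path Newick file path.
#' @return `read_newick()` returns an `ape::phylo`; `write_newick()` its path.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  tree
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' path's two endpoint leaves are equidistant from the root — equivalently,
#' the rooting that minimizes the maximum root-to-leaf distance.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return The rooted tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  phangorn::midpoint(tree)
}

#' Leaf order of a tree (for display alignment)
#' @param tree An `ape::phylo`.
#' @export
tree_leaf_order <- function(tree) {
  tree$tip.label[tree$edge[tree$edge[, 2] <= length(tree$tip.label), 2]]
}

#' Attach a phylogeny to a pangenome
#'
#' Stores the tree under a named role after checking that every leaf is a
#' genome of the roster. Re-attaching an identical tree is a no-op.
#'
#' @param pan A `dm_pangenome`.
#' @param tree An `ape::phylo` with tip labels in the genome roster.
#' @param role e.g. `"core_phylogeny"` or `"cazyme_phylogeny:GH"`.
#' @return The updated pangenome.
#' @export
attach_tree <- function(pan, tree, role = "core_phylogeny") {
  stopifnot(inherits(pan, "dm_pangenome"), inherits(tree, "phylo"))
  extras <- setdiff(tree$tip.label, pan$genomes$genome_id)
  if (length(extras)) {
    stop("tree leaf/leaves not in the genome roster: ",
         paste(extras, collapse = ", "))
  }
  if (!is.null(pan$trees[[role]]) &&
      identical(layer_checksum(pan$trees[[role]]), layer_checksum(tree))) {
    return(pan)
  }
  pan$trees[[role]] <- tree
  pan
}

#' Attach a tree to a versioned package as a layer
#'
#' Registers the newick text as a `tree` layer in a `dm_package`; attaching a
#' tree with an identical checksum again does not bump the version.
#'
#' @param pkg A `dm_package`.
#' @param tree An `ape::phylo`.
#' @param role Layer name suffix; layer id is `tree:<role>`.
#' @return The updated package.
#' @export
attach_tree_layer <- function(pkg, tree, role = "core_phylogeny") {
  stopifnot(inherits(pkg, "dm_package"), inherits(tree, "phylo"))
  layer_id <- paste0("tree:", role)
  if (layer_id %in% package_layers(pkg)) {
    rec <- pkg$manifest$layers[[which(package_layers(pkg) == layer_id)]]
    if (identical(rec$checksum, layer_checksum(tree))) return(pkg)
    return(update_layer(pkg, layer_id, tree, paste0("updated tree '", role, "'")))
  }
  register_layer(pkg, layer_id, "tree", tree,
                 provenance = paste0("phylogeny, role=", role))
}

#' Robinson-Foulds topology distance
#'
#' Counts the bipartitions present in exactly one of two unrooted trees on
#' the same leaf set; the normalized form divides by `2 (n - 3)`, the
#' maximum for two fully resolved trees.
#'
#' @param tree_a,tree_b `ape::phylo` trees with identical leaf sets.
#' @return List with `rf` and `normalized`.
#' @export
topology_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("trees have different leaf sets")
  }
  rf <- as.numeric(phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b),
                                     check.labels = TRUE))
  n <- length(tree_a$tip.label)
  denom <- 2 * (n - 3)
  list(rf = rf, normalized = if (denom > 0) rf / denom else 0)
}
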