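# Pangenome construction and analysis.
#
# Pipeline: all-vs-all amino-acid similarity -> minbit filtering (score over
# the smaller self-score, threshold 0.5) -> Markov clustering (inflation 2.0)
# into gene clusters -> presence/absence matrix, consensus annotations,
# fragment-based ANI, and completeness-aware Bayesian core/accessory
# classification. All thresholds are arguments.

qualify <- function(genome_id, gene_id) paste0(genome_id, "::", gene_id)

translate_orf <- function(dna) {
  if (nchar(dna) %% 3 != 0) dna <- substr(dna, 1, nchar(dna) - nchar(dna) %% 3)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

default_protein_scorer <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  function(a, b) {
    Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                  substitutionMatrix = mat, gapOpening = 10,
                                  gapExtension = 1, type = "local",
                                  scoreOnly = TRUE)
  }
}

collect_proteins <- function(genomes) {
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    stop("genomes must be a named list")
  }
  rows <- lapply(names(genomes), function(g) {
    pkg <- genomes[[g]]
    calls <- gene_calls(pkg)
    if (nrow(calls) == 0L) stop("genome '", g, "' has no gene calls")
    data.frame(genome_id = g, gene_id = calls$gene_id,
               node = qualify(g, calls$gene_id),
               aa = vapply(calls$gene_id, function(id) {
                 translate_orf(get_gene_sequence(pkg, id))
               }, character(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All-vs-all protein similarity graph with minbit filtering
#'
#' Scores every pair of genes (across and within genomes) with a local
#' amino-acid alignment, normalizes each pair score by the smaller of the two
#' self-alignment scores (`minbit`, a 0..1 homology heuristic), and keeps
#' edges at or above `min_minbit`.
#'
#' @param genomes Named list of `dm_package` objects (kind `"genome"`) with
#'   gene calls.
#' @param scorer Optional `function(aa_a, aa_b) -> numeric score`; the default
#'   is a BLOSUM62 local alignment. External search results can be converted
#'   with [similarity_edges_from_table()].
#' @param min_minbit Minimum minbit to keep an edge (default 0.5).
#' @return Data frame with columns `from`, `to` (genome-qualified gene ids),
#'   `score`, `minbit`, `weight` (= minbit).
#' @export
compute_similarity_graph <- function(genomes, scorer = NULL, min_minbit = 0.5) {
  prot <- collect_proteins(genomes)
  if (is.null(scorer)) scorer <- default_protein_scorer()
  n <- nrow(prot)
  self_scores <- vapply(seq_len(n), function(i) {
    tryCatch(as.numeric(scorer(prot$aa[i], prot$aa[i])),
             error = function(e) NA_real_)
  }, numeric(1))

  from <- character(0); to <- character(0); score <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        s <- tryCatch(as.numeric(scorer(prot$aa[i], prot$aa[j])),
                      error = function(e) {
                        warning("scorer failed for pair (", prot$node[i], ", ",
                                prot$node[j], "); pair skipped")
                        NA_real_
                      })
        if (is.na(s) || s <= 0) next
        from <- c(from, prot$node[i]); to <- c(to, prot$node[j])
        score <- c(score, s)
      }
    }
  }
  mins <- pmin(self_scores[match(from, prot$node)], self_scores[match(to, prot$node)])
  minbit <- ifelse(is.na(mins) | mins <= 0, 0, score / mins)
  keep <- minbit >= min_minbit
  out <- data.frame(from = from[keep], to = to[keep], score = score[keep],
                    minbit = minbit[keep], stringsAsFactors = FALSE)
  out$weight <- out$minbit
  attr(out, "nodes") <- prot$node
  out
}

#' Convert an external similarity search table to minbit edges
#'
#' @param hits Data frame with columns `query`, `target`, `bitscore`
#'   (genome-qualified ids); must include self hits (`query == target`) for
#'   the minbit denominators.
#' @param min_minbit Minimum minbit to keep an edge.
#' @return Edge data frame as in [compute_similarity_graph()].
#' @export
similarity_edges_from_table <- function(hits, min_minbit = 0.5) {
  need <- c("query", "target", "bitscore")
  if (!all(need %in% names(hits))) stop("hits need columns ", paste(need, collapse = ", "))
  selfs <- hits[hits$query == hits$target, , drop = FALSE]
  self_score <- tapply(selfs$bitscore, selfs$query, max)
  cross <- hits[hits$query != hits$target, , drop = FALSE]
  a <- pmin(cross$query, cross$target); b <- pmax(cross$query, cross$target)
  key <- paste(a, b, sep = "\r")
  score <- tapply(cross$bitscore, key, max)
  pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  mins <- pmin(self_score[pairs[, 1]], self_score[pairs[, 2]])
  if (anyNA(mins)) stop("missing self hit(s) for: ",
                        paste(unique(c(pairs[, 1], pairs[, 2])[is.na(c(
                          self_score[pairs[, 1]], self_score[pairs[, 2]]))]),
                          collapse = ", "))
  minbit <- as.numeric(score) / as.numeric(mins)
  keep <- minbit >= min_minbit
  out <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                    score = as.numeric(score)[keep], minbit = minbit[keep],
                    stringsAsFactors = FALSE)
  out$weight <- out$minbit
  rownames(out) <- NULL
  attr(out, "nodes") <- sort(unique(c(hits$query, hits$target)), method = "radix")
  out
}

#' Markov clustering of a weighted undirected graph
#'
#' Simulates flow on the graph: the column-stochastic transition matrix is
#' alternately squared (expansion) and raised elementwise to `inflation`
#' with renormalization, until the matrix stops changing; the sets of nodes
#' attached to the same attractors form the clusters. Deterministic for a
#' given graph.
#'
#' @param edges Data frame with columns `from`, `to`, `weight` (self loops
#'   are added internally).
#' @param inflation Inflation exponent (>= 1, default 2).
#' @param nodes Optional node universe; nodes without edges become singleton
#'   clusters.
#' @param max_iter,tol,prune Iteration controls.
#' @return List of character vectors (clusters), each sorted; clusters
#'   ordered by decreasing size then lexicographically by first member.
#' @export
mcl_cluster <- function(edges, inflation = 2, nodes = NULL, max_iter = 100,
                        tol = 1e-8, prune = 1e-10) {
  if (inflation < 1) stop("inflation must be >= 1")
  nodes <- sort(unique(c(nodes, edges$from, edges$to)), method = "radix")
  if (length(nodes) == 0L) return(list())
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0L) {
    i <- match(edges$from, nodes); j <- match(edges$to, nodes)
    w <- edges$weight
    M[cbind(i, j)] <- pmax(M[cbind(i, j)], w)
    M[cbind(j, i)] <- pmax(M[cbind(j, i)], w)
  }
  # self loops: the maximum incident weight (1 for isolated nodes), the
  # usual regularization that guarantees convergence
  loops <- apply(M, 2, max)
  diag(M) <- ifelse(loops > 0, loops, 1)
  M <- sweep(M, 2, colSums(M), "/")

  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }

  support <- (M > 1e-6) | (t(M) > 1e-6)
  diag(support) <- TRUE
  # connected components of the attractor support graph
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(support[v, ] & comp == 0L)
      queue <- c(queue, nb)
    }
  }
  clusters <- lapply(split(nodes, comp), sort, method = "radix")
  names(clusters) <- NULL
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, `[[`, character(1), 1L), method = "radix")
  clusters[ord]
}

#' Build a pangenome from genome packages
#'
#' Runs the similarity graph + minbit + Markov clustering pipeline across at
#' least two genomes, assembles gene clusters with binary presence vectors
#' over genomes, and derives consensus annotations (per source, the most
#' frequent accession among member genes; ties broken lexicographically).
#'
#' @param genomes Named list of `dm_package` genome packages with gene calls.
#' @param metadata Optional data frame with columns `genome_id`, `type`
#'   (`"isolate"`/`"MAG"`), `completeness` (0..1), `contamination`; defaults
#'   to isolates at completeness 1.
#' @param min_minbit,inflation Clustering parameters (see
#'   [compute_similarity_graph()], [mcl_cluster()]).
#' @param scorer Optional custom protein scorer.
#' @param edges Optional precomputed edge table (e.g. from
#'   [similarity_edges_from_table()]); skips alignment.
#' @return A `dm_pangenome` object: genome roster, cluster membership table,
#'   presence matrix, consensus annotations and parameters.
#' @export
build_pangenome <- function(genomes, metadata = NULL, min_minbit = 0.5,
                            inflation = 2, scorer = NULL, edges = NULL) {
  if (length(genomes) < 2L) stop("a pangenome needs at least 2 genomes")
  prot <- collect_proteins(genomes)
  if (is.null(edges)) {
    edges <- compute_similarity_graph(genomes, scorer = scorer,
                                      min_minbit = min_minbit)
  }
  clusters <- mcl_cluster(edges, inflation = inflation, nodes = prot$node)

  ids <- sprintf("GC_%05d", seq_along(clusters))
  membership <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    parts <- do.call(rbind, strsplit(clusters[[k]], "::", fixed = TRUE))
    data.frame(cluster_id = ids[k], genome_id = parts[, 1],
               gene_id = as.integer(parts[, 2]), stringsAsFactors = FALSE)
  }))
  rownames(membership) <- NULL

  genome_ids <- names(genomes)
  presence <- matrix(0L, length(clusters), length(genome_ids),
                     dimnames = list(ids, genome_ids))
  hit <- unique(membership[, c("cluster_id", "genome_id")])
  presence[cbind(hit$cluster_id, hit$genome_id)] <- 1L

  # consensus annotation per cluster and source
  all_ann <- do.call(rbind, lapply(genome_ids, function(g) {
    ann <- functional_annotations(genomes[[g]])
    if (nrow(ann) == 0L) return(NULL)
    ann$node <- qualify(g, ann$gene_id)
    ann
  }))
  consensus <- NULL
  if (!is.null(all_ann) && nrow(all_ann) > 0L) {
    node_cluster <- stats::setNames(membership$cluster_id,
                                    qualify(membership$genome_id, membership$gene_id))
    all_ann$cluster_id <- node_cluster[all_ann$node]
    all_ann <- all_ann[!is.na(all_ann$cluster_id), , drop = FALSE]
    grp <- split(all_ann, paste(all_ann$cluster_id, all_ann$source, sep = "\r"))
    consensus <- do.call(rbind, lapply(grp, function(d) {
      tab <- sort(table(d$accession), decreasing = TRUE)
      best <- sort(names(tab)[tab == max(tab)], method = "radix")[1]
      data.frame(cluster_id = d$cluster_id[1], source = d$source[1],
                 accession = best,
                 `function` = d[["function"]][match(best, d$accession)],
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
    consensus <- consensus[order(consensus$cluster_id, consensus$source,
                                 method = "radix"), , drop = FALSE]
    rownames(consensus) <- NULL
  } else {
    consensus <- data.frame(cluster_id = character(0), source = character(0),
                            accession = character(0), `function` = character(0),
                            check.names = FALSE, stringsAsFactors = FALSE)
  }

  if (is.null(metadata)) {
    metadata <- data.frame(genome_id = genome_ids, type = "isolate",
                           completeness = 1, contamination = 0,
                           stringsAsFactors = FALSE)
  }
  if (!all(genome_ids %in% metadata$genome_id)) {
    stop("metadata is missing genome(s): ",
         paste(setdiff(genome_ids, metadata$genome_id), collapse = ", "))
  }
  metadata <- metadata[match(genome_ids, metadata$genome_id), , drop = FALSE]
  rownames(metadata) <- NULL

  structure(list(
    genomes = metadata,
    clusters = membership,
    presence = presence,
    consensus = consensus,
    core = NULL,
    ani = NULL,
    trees = list(),
    params = list(min_minbit = min_minbit, inflation = inflation),
    provenance = sprintf("built from %d genomes (minbit >= %g, inflation %g)",
                         length(genome_ids), min_minbit, inflation)
  ), class = "dm_pangenome")
}

#' @export
print.dm_pangenome <- function(x, ...) {
  cat(sprintf("<dm_pangenome: %d genomes, %d gene clusters>\n",
              nrow(x$genomes), nrow(x$presence)))
  if (!is.null(x$core)) {
    cat(sprintf("  core: %d, accessory: %d\n", sum(x$core$label == "core"),
                sum(x$core$label == "accessory")))
  }
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Gene clusters per genome
#' @param pan A `dm_pangenome`.
#' @return Named integer vector.
#' @export
gene_clusters_per_genome <- function(pan) colSums(pan$presence > 0)

#' Fragment-based average nucleotide identity
#'
#' Chops genome `a` into non-overlapping fragments, aligns each (both
#' strands) against genome `b` with a local nucleotide alignment, keeps
#' fragments whose best percent identity is at least
#' `min_frag_identity * 100`, and averages their identities. Asymmetric by
#' construction; a genome against itself is exactly 100.
#'
#' @param a,b Named character vectors of contigs, or `dm_package` objects.
#' @param fragment_bp Fragment size (default 1020 bp). Contigs shorter than
#'   one fragment contribute a single whole-contig fragment.
#' @param min_frag_identity Minimum fractional identity to retain a fragment.
#' @return List with `ani` (percent) and `aligned_fraction` (retained /
#'   total fragments).
#' @export
compute_ani <- function(a, b, fragment_bp = 1020, min_frag_identity = 0.3) {
  get_contigs <- function(x) {
    if (inherits(x, "dm_package")) x$genome$contigs else x
  }
  a <- get_contigs(a); b <- get_contigs(b)
  if (is.null(a) || is.null(b) || !length(a) || !length(b)) {
    stop("both genomes need sequences")
  }
  frags <- unlist(lapply(unname(a), function(contig) {
    len <- nchar(contig)
    if (len < fragment_bp) return(contig)
    starts <- seq.int(1L, len - fragment_bp + 1L, by = fragment_bp)
    vapply(starts, function(s) substr(contig, s, s + fragment_bp - 1L), character(1))
  }))
  subjects <- Biostrings::DNAStringSet(unname(b))
  subjects <- c(subjects, Biostrings::reverseComplement(subjects))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)

  idents <- vapply(frags, function(fr) {
    pat <- Biostrings::DNAString(fr)
    scores <- vapply(seq_along(subjects), function(k) {
      Biostrings::pairwiseAlignment(pat, subjects[[k]], type = "local",
                                    substitutionMatrix = submat,
                                    gapOpening = 4, gapExtension = 2,
                                    scoreOnly = TRUE)
    }, numeric(1))
    best <- which.max(scores)
    aln <- Biostrings::pairwiseAlignment(pat, subjects[[best]], type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 4, gapExtension = 2)
    Biostrings::pid(aln, type = "PID1")
  }, numeric(1))

  keep <- idents >= min_frag_identity * 100
  list(ani = if (any(keep)) mean(idents[keep]) else NA_real_,
       aligned_fraction = mean(keep))
}

#' Pairwise ANI matrix over a set of genomes
#'
#' @param genomes Named list of contig vectors or `dm_package` objects.
#' @param ... Passed to [compute_ani()].
#' @return List with `ani` and `aligned_fraction` matrices (diagonal 100 / 1).
#' @export
ani_matrix <- function(genomes, ...) {
  ids <- names(genomes)
  n <- length(ids)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  af <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { ani[i, j] <- 100; af[i, j] <- 1; next }
      res <- compute_ani(genomes[[i]], genomes[[j]], ...)
      ani[i, j] <- res$ani; af[i, j] <- res$aligned_fraction
    }
  }
  list(ani = ani, aligned_fraction = af)
}

#' Completeness-aware Bayesian core/accessory classification
#'
#' For each gene cluster, compares the log-likelihood of a core model — the
#' cluster is truly in every genome and absences are explained by genome
#' incompleteness (`c_i` = probability a truly present gene was recovered) —
#' against an accessory model in which genome `i` draws its `n_i` observed
#' accessory genes from a pool of `G_acc` accessory clusters, giving
#' per-genome observation probability `p_i = 1 - (1 - 1/G_acc)^n_i`. Labels
#' start from the clusters present in more than `init_prevalence` of the
#' genomes and are iterated to a fixed point, re-estimating the accessory
#' pool from the current labels each round.
#'
#' @param presence Binary matrix, clusters x genomes.
#' @param completeness Numeric vector in (0, 1], one per genome (floored at
#'   0.999 inside the logs).
#' @param init_prevalence Initial core prevalence threshold (default 0.95).
#' @param max_iter Maximum label iterations (default 50).
#' @return Data frame with `cluster_id`, `ll_core`, `ll_accessory`, `llr`
#'   (core minus accessory log-likelihood) and `label` (`"core"` iff
#'   `llr > 0`); the number of iterations is in `attr(, "iterations")`.
#' @export
bayesian_pan_core <- function(presence, completeness, init_prevalence = 0.95,
                              max_iter = 50) {
  X <- as.matrix(presence)
  if (!all(X %in% c(0, 1))) stop("presence matrix must be binary")
  if (length(completeness) != ncol(X)) {
    stop("completeness must have one value per genome")
  }
  if (any(completeness <= 0 | completeness > 1)) {
    stop("completeness must lie in (0, 1]")
  }
  storage.mode(X) <- "double"
  cf <- pmin(completeness, 0.999)
  ll_core <- as.numeric(X %*% log(cf) + (1 - X) %*% log(1 - cf))

  core <- rowMeans(X) > init_prevalence
  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    acc <- !core
    G_acc <- sum(acc)
    if (G_acc == 0L) {
      p <- rep(1e-9, ncol(X))
    } else {
      n_i <- colSums(X[acc, , drop = FALSE])
      p <- 1 - (1 - 1 / G_acc)^n_i
      # keep p strictly below the floored completeness ceiling so a
      # ubiquitous cluster can never tie the core model
      p <- pmin(pmax(p, 1e-9), 0.998)
    }
    ll_acc <- as.numeric(X %*% log(p) + (1 - X) %*% log(1 - p))
    llr <- ll_core - ll_acc
    new_core <- llr > 0
    if (identical(new_core, core)) { core <- new_core; break }
    core <- new_core
  }
  out <- data.frame(
    cluster_id = if (is.null(rownames(X))) as.character(seq_len(nrow(X))) else rownames(X),
    ll_core = ll_core,
    ll_accessory = ll_acc,
    llr = llr,
    label = ifelse(core, "core", "accessory"),
    stringsAsFactors = FALSE
  )
  attr(out, "iterations") <- iterations
  out
}

#' Classify a pangenome's clusters as core or accessory
#'
#' Applies [bayesian_pan_core()] to the pangenome's presence matrix using the
#' completeness values from its genome roster, and stores the result.
#'
#' @param pan A `dm_pangenome`.
#' @param ... Passed to [bayesian_pan_core()].
#' @return The pangenome with `$core` filled in.
#' @export
classify_pan_core <- function(pan, ...) {
  stopifnot(inherits(pan, "dm_pangenome"))
  pan$core <- bayesian_pan_core(pan$presence, pan$genomes$completeness, ...)
  pan
}

#' Subset a pangenome by a cluster predicate
#'
#' @param pan A `dm_pangenome`.
#' @param predicate Either a character vector of cluster ids, a logical
#'   vector over clusters (in presence-matrix order), or a function taking a
#'   per-cluster info list (`cluster_id`, `annotations` data frame, `label`)
#'   and returning `TRUE`/`FALSE`.
#' @param description Free-text provenance note.
#' @return A new `dm_pangenome` with only the matching clusters; the genome
#'   roster is preserved.
#' @export
subset_pangenome <- function(pan, predicate, description = NULL) {
  stopifnot(inherits(pan, "dm_pangenome"))
  ids <- rownames(pan$presence)
  keep <- if (is.character(predicate)) {
    ids %in% predicate
  } else if (is.logical(predicate)) {
    if (length(predicate) != length(ids)) stop("logical predicate length mismatch")
    predicate
  } else if (is.function(predicate)) {
    vapply(ids, function(cid) {
      info <- list(
        cluster_id = cid,
        annotations = pan$consensus[pan$consensus$cluster_id == cid, , drop = FALSE],
        label = if (is.null(pan$core)) NA_character_ else
          pan$core$label[match(cid, pan$core$cluster_id)]
      )
      isTRUE(predicate(info))
    }, logical(1))
  } else stop("predicate must be character, logical or a function")

  if (!any(keep)) warning("predicate matches no clusters; returning empty pangenome")
  kept <- ids[keep]
  out <- pan
  out$presence <- pan$presence[keep, , drop = FALSE]
  out$clusters <- pan$clusters[pan$clusters$cluster_id %in% kept, , drop = FALSE]
  out$consensus <- pan$consensus[pan$consensus$cluster_id %in% kept, , drop = FALSE]
  if (!is.null(pan$core)) {
    out$core <- pan$core[pan$core$cluster_id %in% kept, , drop = FALSE]
  }
  out$provenance <- paste0(pan$provenance, "; subset: ",
                           if (is.null(description)) paste0(sum(keep), " clusters kept")
                           else description)
  out
}
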