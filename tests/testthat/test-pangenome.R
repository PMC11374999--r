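test_that("minbit normalizes pair scores by the smaller self score", {
  hits <- data.frame(
    query = c("g1::0", "g2::0", "g1::0", "g1::1", "g2::1"),
    target = c("g1::0", "g2::0", "g2::0", "g1::1", "g2::1"),
    bitscore = c(100, 80, 50, 60, 70))
  edges <- similarity_edges_from_table(hits, min_minbit = 0)
  e <- edges[edges$from == "g1::0" & edges$to == "g2::0", ]
  expect_equal(e$minbit, 50 / 80)  # 0.625

  # identical proteins score minbit 1 with the built-in scorer
  gs <- simulate_related_genomes(seed = 5, n_genomes = 2, n_shared = 1, n_unique = 0)
  g <- compute_similarity_graph(gs)
  expect_equal(nrow(g), 1)
  expect_equal(g$minbit, 1.0, tolerance = 1e-12)
})

test_that("similarity graph drops sub-threshold edges between unrelated proteins", {
  gs <- simulate_related_genomes(seed = 6, n_genomes = 2, n_shared = 2, n_unique = 2)
  g <- compute_similarity_graph(gs, min_minbit = 0.5)
  # only the two shared genes should connect across genomes
  cross <- g[sub("::.*", "", g$from) != sub("::.*", "", g$to), ]
  expect_equal(nrow(cross), 2)
  expect_true(all(g$minbit >= 0.5 & g$minbit <= 1 + 1e-9))
})

test_that("Markov clustering resolves cliques, singletons and random graphs", {
  # two disconnected uniform cliques
  cl <- function(nodes) {
    p <- t(combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = 1, stringsAsFactors = FALSE)
  }
  edges <- rbind(cl(c("a1", "a2", "a3")), cl(c("b1", "b2", "b3", "b4")))
  res <- mcl_cluster(edges, inflation = 2)
  expect_length(res, 2)
  expect_identical(partition_key(res),
                   sort(c("a1,a2,a3", "b1,b2,b3,b4")))

  # a node with no edges is its own cluster
  res2 <- mcl_cluster(edges, nodes = c("lonely"))
  expect_true("lonely" %in% unlist(res2))
  expect_length(res2, 3)

  expect_length(mcl_cluster(edges[0, ]), 0)

  # agreement with the loop-based reference on random 20-node graphs
  set.seed(99)
  for (i in 1:10) {
    g <- random_weighted_graph(20)
    mine <- mcl_cluster(g$edges, nodes = g$nodes)
    ref <- reference_mcl(g$edges, nodes = g$nodes)
    expect_identical(partition_key(mine), partition_key(ref))
  }
})

test_that("pangenome of 3 genomes with 5 shared + 2 unique genes has 11 clusters", {
  gs <- simulate_related_genomes(seed = 1, n_genomes = 3, n_shared = 5, n_unique = 2)
  pan <- build_pangenome(gs)
  expect_equal(nrow(pan$presence), 11)
  sizes <- table(table(pan$clusters$cluster_id))
  expect_equal(unname(sizes[["3"]]), 5)
  expect_equal(unname(sizes[["1"]]), 6)
  expect_equal(unname(gene_clusters_per_genome(pan)), rep(7L, 3))

  # partition: every gene lands in exactly one cluster
  total_genes <- sum(vapply(gs, function(p) nrow(gene_calls(p)), integer(1)))
  expect_equal(nrow(pan$clusters), total_genes)
  expect_false(anyDuplicated(paste(pan$clusters$genome_id, pan$clusters$gene_id)) > 0)

  # consensus annotation: shared clusters carry the shared COG accession
  shared_cl <- rownames(pan$presence)[rowSums(pan$presence) == 3]
  cons <- pan$consensus[pan$consensus$cluster_id %in% shared_cl, ]
  expect_setequal(cons$accession, sprintf("COG%04d", 1:5))

  expect_error(build_pangenome(gs[1]), "at least 2")
})

test_that("a within-genome duplicate gene keeps binary presence", {
  gs <- simulate_related_genomes(seed = 8, n_genomes = 2, n_shared = 2, n_unique = 1)
  # duplicate gene 0 of genome_1 by appending an identical call at a new id
  p1 <- gs$genome_1
  calls <- gene_calls(p1)
  dup <- calls[1, ]; dup$gene_id <- max(calls$gene_id) + 1L
  p1$genome$gene_calls <- rbind(calls, dup)
  gs$genome_1 <- p1
  pan <- build_pangenome(gs)
  cl_of_dup <- pan$clusters$cluster_id[pan$clusters$genome_id == "genome_1" &
                                         pan$clusters$gene_id == dup$gene_id]
  expect_equal(sum(pan$clusters$cluster_id == cl_of_dup &
                     pan$clusters$genome_id == "genome_1"), 2)
  expect_equal(pan$presence[cl_of_dup, "genome_1"], 1L)
})

test_that("Bayesian core classification matches its closed forms", {
  # N = 2, c = 0.9 both, present in both: LL_core = 2 ln 0.9
  X <- matrix(c(1, 1, 0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("both", "one"), NULL))
  res <- bayesian_pan_core(X, c(0.9, 0.9))
  expect_equal(res$ll_core[1], 2 * log(0.9), tolerance = 1e-12)

  # present in all of 30 genomes at c = 0.9 -> core
  sim <- simulate_pangenome(seed = 2, n_genomes = 30, n_core = 50, n_accessory = 200)
  X30 <- rbind(everywhere = rep(1L, 30), sim$presence)
  res30 <- bayesian_pan_core(X30, rep(0.9, 30))
  expect_equal(res30$label[1], "core")
  expect_equal(res30$ll_core[1], 30 * log(0.9), tolerance = 1e-12)

  # present in 1 of 30 at c = 0.95 -> accessory
  X1 <- rbind(rare = c(1L, rep(0L, 29)), sim$presence)
  res1 <- bayesian_pan_core(X1, rep(0.95, 30))
  expect_equal(res1$label[1], "accessory")

  expect_error(bayesian_pan_core(matrix(2, 1, 2), c(1, 1)), "binary")
  expect_error(bayesian_pan_core(matrix(1, 1, 2), c(0, 1)), "completeness")
})

test_that("classification is exact in the completeness-1 limit", {
  sim <- simulate_pangenome(seed = 4, n_genomes = 25, n_core = 40,
                            n_accessory = 160, completeness_range = c(1, 1))
  expect_identical(sim$presence, sim$true_presence)  # no dropout
  res <- bayesian_pan_core(sim$presence, sim$completeness)
  in_all <- rowSums(sim$presence) == ncol(sim$presence)
  expect_identical(res$label == "core", unname(in_all))
})

test_that("core recovery is high under realistic completeness dropout", {
  sens <- fpr <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_pangenome(seed = 100 + s)
    res <- bayesian_pan_core(sim$presence, sim$completeness)
    sens[s] <- mean(res$label[sim$truth == "core"] == "core")
    fpr[s] <- mean(res$label[sim$truth == "accessory"] == "core")
  }
  expect_gte(median(sens), 0.95)
  expect_lte(median(fpr), 0.05)
})

test_that("pangenome subsetting honors predicates and composes", {
  gs <- simulate_related_genomes(seed = 1)
  for (g in names(gs)) {
    caz <- data.frame(gene_id = 0L, accession = c("GH13"), `function` = "caz",
                      check.names = FALSE)
    gs[[g]] <- import_functional_annotations(gs[[g]], caz, source = "CAZyme")
  }
  pan <- build_pangenome(gs)
  pan <- classify_pan_core(pan)

  has_caz <- function(info) "CAZyme" %in% info$annotations$source
  sub <- subset_pangenome(pan, has_caz)
  expect_true(nrow(sub$presence) >= 1)
  expect_true(all(vapply(rownames(sub$presence), function(cid) {
    "CAZyme" %in% sub$consensus$source[sub$consensus$cluster_id == cid]
  }, logical(1))))
  expect_identical(sub$genomes, pan$genomes)  # roster preserved

  core_sub <- subset_pangenome(pan, function(info) identical(info$label, "core"))
  expect_setequal(rownames(core_sub$presence),
                  pan$core$cluster_id[pan$core$label == "core"])

  # subset of a subset equals a single subset with the conjunction
  both1 <- subset_pangenome(subset_pangenome(pan, has_caz),
                            function(info) identical(info$label, "core"))
  both2 <- subset_pangenome(pan, function(info) {
    has_caz(info) && identical(info$label, "core")
  })
  expect_identical(rownames(both1$presence), rownames(both2$presence))

  expect_warning(subset_pangenome(pan, function(info) FALSE), "no clusters")
})
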