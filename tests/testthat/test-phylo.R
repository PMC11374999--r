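test_that("SCG alignment concatenation builds the supermatrix with partitions", {
  blocks <- list(
    b1 = c(g1 = "MKLVNTWQAV", g2 = "MKLVNSWQAV", g3 = "MKIVNTWQAV"),
    b2 = c(g1 = "AAAAACCCCCDDDDD", g2 = "AAAATCCCCCDDDDD", g3 = "AAAAACCCCCDDDDE"))
  res <- concatenate_scg_alignments(blocks)
  expect_equal(unique(nchar(res$supermatrix)), 25)
  expect_equal(res$partitions$start, c(1, 11))
  expect_equal(res$partitions$end, c(10, 25))

  # genome absent from block 2 -> gap fill
  blocks2 <- blocks
  blocks2$b2 <- blocks2$b2[c("g1", "g2")]
  expect_warning(res2 <- concatenate_scg_alignments(blocks2), "gap-filled")
  expect_equal(substr(res2$supermatrix[["g3"]], 11, 25), strrep("-", 15))

  # not single-copy / unequal widths are rejected
  dup <- blocks
  names(dup$b1)[2] <- "g1"
  expect_error(concatenate_scg_alignments(dup), "not single-copy")
  uneq <- blocks
  uneq$b1[["g2"]] <- "MK"
  expect_error(concatenate_scg_alignments(uneq), "unequal length")

  f <- withr::local_tempfile(fileext = ".fasta")
  p <- withr::local_tempfile(fileext = ".txt")
  write_supermatrix(res, f, p)
  back <- Biostrings::readAAStringSet(f)
  expect_equal(as.character(back[["g2"]]), res$supermatrix[["g2"]])
  expect_match(readLines(p)[1], "PROT, b1 = 1-10")
})

test_that("newick serialization is lossless and idempotent", {
  txt <- "((A:1,B:3):1,C:6);"
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(txt, f)
  tr <- read_newick(f)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,A:2):1,C:3);", bad)
  expect_error(read_newick(bad), "duplicate")
})

test_that("midpoint rooting equalizes the diameter endpoints on the worked tree", {
  tr <- ape::read.tree(text = "((A:1,B:3):1,C:6);")
  rooted <- midpoint_root(tr)
  nd <- ape::dist.nodes(rooted)
  root <- length(rooted$tip.label) + 1L
  depths <- setNames(nd[root, seq_along(rooted$tip.label)], rooted$tip.label)
  # longest path B-C of length 10: both 5 from the root; A at 1 + (5 - 3) = 3
  expect_equal(unname(depths["B"]), 5)
  expect_equal(unname(depths["C"]), 5)
  expect_equal(unname(depths["A"]), 3)

  # idempotence
  again <- midpoint_root(rooted)
  nd2 <- ape::dist.nodes(again)
  expect_equal(sort(unname(nd2[length(again$tip.label) + 1L, seq_along(again$tip.label)])),
               sort(unname(depths)), tolerance = 1e-9)

  # two-leaf tree splits the 6-length path 3/3
  two <- midpoint_root(ape::read.tree(text = "(A:2,B:4);"))
  ndt <- ape::dist.nodes(two)
  expect_equal(unname(ndt[3, 1:2]), c(3, 3))

  expect_error(midpoint_root(ape::read.tree(text = "((A,B),C);")), "branch lengths")
})

test_that("midpoint rooting minimizes the maximum root-to-leaf depth (brute force)", {
  set.seed(7)
  for (i in 1:25) {
    tr <- random_bl_tree(sample(4:8, 1))
    rooted <- midpoint_root(tr)
    expect_equal(max_root_depth(rooted), bruteforce_minmax_depth(tr),
                 tolerance = 1e-9)
  }
})

test_that("RF distance agrees with exhaustive bipartition comparison", {
  a <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  b <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  res <- topology_distance(a, b)
  expect_equal(res$rf, 2)
  expect_equal(res$normalized, 1)
  expect_equal(topology_distance(a, a)$rf, 0)

  # star vs resolved: RF = number of internal bipartitions of the resolved tree
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  resolved <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  expect_equal(topology_distance(star, resolved)$rf,
               length(tree_bipartitions(resolved)))

  expect_error(topology_distance(a, star), "different leaf sets")

  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    t1 <- random_bl_tree(n)
    t2 <- t1
    t2$tip.label <- sample(t1$tip.label)  # same labels, shuffled topology
    expect_equal(topology_distance(t1, t2)$rf, reference_rf(t1, t2))
  }
})

test_that("trees attach to pangenomes with roster validation and idempotence", {
  gs <- simulate_related_genomes(seed = 1)
  pan <- build_pangenome(gs)
  tree <- ape::read.tree(text = "((genome_1:1,genome_2:1):1,genome_3:2);")
  pan <- attach_tree(pan, tree, "core_phylogeny")
  expect_identical(ape::write.tree(pan$trees$core_phylogeny), ape::write.tree(tree))

  stray <- ape::read.tree(text = "((genome_1:1,X:1):1,genome_3:2);")
  expect_error(attach_tree(pan, stray), "X")

  # versioned layer on a package: identical re-attach does not bump version
  pkg <- create_package("pan_pkg", "pangenome")
  pkg <- attach_tree_layer(pkg, tree, "core_phylogeny")
  v1 <- package_version_string(pkg)
  pkg <- attach_tree_layer(pkg, tree, "core_phylogeny")
  expect_equal(package_version_string(pkg), v1)
})
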