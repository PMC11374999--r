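test_that("TPM matches hand-computed values and conserves the million", {
  tpm <- tpm_normalize(c(A = 100, B = 300, C = 0), c(A = 1000, B = 1000, C = 500))
  expect_equal(tpm, c(A = 250000, B = 750000, C = 0))
  expect_equal(sum(tpm), 1e6)

  expect_equal(unname(tpm_normalize(c(g = 42), c(g = 123))), 1e6)

  cov <- tpm_normalize(c(10, 30), mode = "coverage")
  expect_equal(unname(cov), c(250000, 750000))

  expect_warning(z <- tpm_normalize(c(0, 0), c(10, 10)), "all-zero")
  expect_equal(unname(z), c(0, 0))
})

test_that("TPM is scale invariant and conserved on random samples", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    counts <- rpois(n, 50)
    counts[sample(n, 1)] <- counts[sample(n, 1)] + 1  # ensure nonzero
    lens <- sample(100:3000, n)
    t1 <- tpm_normalize(counts, lens)
    expect_equal(sum(t1), 1e6, tolerance = 1e-9)
    expect_equal(tpm_normalize(counts * 7, lens), t1, tolerance = 1e-12)
  }
})

test_that("NSAF matches hand-derived values and sums to one", {
  expect_equal(unname(nsaf_normalize(c(10, 30), c(100, 300))), c(0.5, 0.5))
  expect_equal(unname(nsaf_normalize(c(10), c(100))), 1.0)
  expect_equal(unname(nsaf_normalize(c(10, 10), c(100, 100))), c(0.5, 0.5))
  set.seed(5)
  spc <- rpois(30, 20) + 1
  expect_equal(sum(nsaf_normalize(spc, sample(50:500, 30))), 1, tolerance = 1e-12)
  expect_error(nsaf_normalize(c(0, 0), c(10, 10)), "no detected proteins")
})

test_that("coverage layers impute missing genes, reject duplicates, and merge", {
  pkg <- make_toy_package(seed = 2)
  genes <- gene_calls(pkg)$gene_id
  full <- data.frame(gene_id = genes, read_count = seq_along(genes) * 5,
                     mean_coverage = seq_along(genes) * 0.5)
  pkg <- add_coverage_layer(pkg, "S1", full, total_mapped_reads = 1e4)

  partial <- full[-4, ]
  expect_warning(pkg <- add_coverage_layer(pkg, "S2", partial,
                                           total_mapped_reads = 1e4),
                 "imputed zero")
  expect_equal(get_layer(pkg, "coverage:S2")$read_count[4], 0)

  expect_error(add_coverage_layer(pkg, "S1", full, total_mapped_reads = 1e4),
               "already has")
  expect_error(add_coverage_layer(pkg, "S3",
                                  transform(full, read_count = -read_count),
                                  total_mapped_reads = 1e4), "negative")

  m <- merge_samples(pkg)
  expect_equal(dim(m), c(length(genes), 2))
  expect_equal(unname(m[, "S1"]), get_layer(pkg, "coverage:S1")$read_count)
  expect_equal(unname(m[, "S2"]), get_layer(pkg, "coverage:S2")$read_count)
  expect_equal(unname(sample_total_reads(pkg, "S1")), 1e4)
})

test_that("proteome layers carry NSAF values that sum to one", {
  pkg <- make_toy_package(seed = 2)
  prot <- data.frame(gene_id = gene_calls(pkg)$gene_id[1:6],
                     spectral_count = c(4, 0, 9, 2, 7, 1),
                     length_aa = c(100, 250, 80, 300, 150, 90))
  pkg <- add_proteome_layer(pkg, "P1", prot)
  nsaf <- get_layer(pkg, "proteome:P1")$nsaf
  expect_equal(sum(nsaf), 1, tolerance = 1e-9)
  expect_true(all(nsaf >= 0 & nsaf <= 1))
})

test_that("misc data and collections validate gene ids and preserve order", {
  pkg <- make_toy_package(seed = 2)
  genes <- gene_calls(pkg)$gene_id
  mut <- data.frame(gene_id = genes,
                    value = c(rep("yes", length(genes) - 2), "no", "no"))
  pkg <- import_misc_data(pkg, "mutant_available", mut)
  expect_equal(sum(get_layer(pkg, "misc:mutant_available")$value == "no"), 2)

  expect_error(import_misc_data(pkg, "x", data.frame(gene_id = 999, value = 1)),
               "unknown gene_id")

  ids <- rev(genes[1:6])
  pkg <- define_collection(pkg, "six", ids, groups = rep(c("a", "b"), 3))
  expect_equal(get_collection(pkg, "six")$gene_id, ids)  # order preserved
  expect_error(define_collection(pkg, "dup", c(1, 1, 2)), "duplicate")
})

test_that("collection summaries are deterministic and keep all-zero genes", {
  pkg <- make_toy_package(seed = 4)
  genes <- gene_calls(pkg)$gene_id
  cov1 <- data.frame(gene_id = genes, read_count = c(0, seq_along(genes)[-1] * 3))
  cov2 <- data.frame(gene_id = genes, read_count = c(0, rev(seq_along(genes)[-1]) * 2))
  pkg <- add_coverage_layer(pkg, "S1", cov1, total_mapped_reads = 500)
  pkg <- add_coverage_layer(pkg, "S2", cov2, total_mapped_reads = 500)

  s <- summarize_collection(pkg, "transporters")
  coll <- get_collection(pkg, "transporters")
  expect_equal(nrow(s), nrow(coll))
  expect_equal(ncol(s), 3 + 2 * 2)  # gene, group, annotations + 2 per sample
  expect_true(all(c("tpm_S1", "tpm_S2") %in% names(s)))
  # gene 0 has zero coverage everywhere but its row is retained
  expect_true(0 %in% s$gene_id)
  expect_equal(s[s$gene_id == 0, "read_count_S1"], 0)

  s2 <- summarize_collection(pkg, "transporters")
  expect_identical(s, s2)
})
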