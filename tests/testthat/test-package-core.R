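test_that("package creation sets the initial empty state", {
  pkg <- create_package("rpom", "genome")
  expect_equal(package_version_string(pkg), "1.0")
  expect_length(package_layers(pkg), 0)
  expect_equal(pkg$manifest$changelog[[1]]$description, "created")

  pan_pkg <- create_package("genus_pan", "pangenome")
  expect_equal(pan_pkg$manifest$package_kind, "pangenome")

  expect_error(create_package("", "genome"), "non-empty")
  expect_error(create_package("x", "plasmid"))
})

test_that("layer registration bumps MINOR and leaves earlier layers untouched", {
  pkg <- create_package("p", "genome")
  df1 <- data.frame(gene_id = 0:2, value = c(1.5, 2, 3))
  pkg <- register_layer(pkg, "misc:a", "misc_gene_data", df1)
  expect_equal(package_version_string(pkg), "1.1")
  expect_length(package_layers(pkg), 1)

  expect_error(register_layer(pkg, "misc:a", "misc_gene_data", df1),
               "already registered")

  pkg <- register_layer(pkg, "misc:b", "misc_gene_data", data.frame(gene_id = 0, value = 9))
  sums_before <- vapply(pkg$manifest$layers, `[[`, "", "checksum")
  pkg <- register_layer(pkg, "misc:c", "misc_gene_data", data.frame(gene_id = 1, value = 7))
  expect_equal(package_version_string(pkg), "1.3")
  sums_after <- vapply(pkg$manifest$layers[1:2], `[[`, "", "checksum")
  expect_identical(unname(sums_before), unname(sums_after))
})

test_that("version is monotone over mixed operations and removal bumps MAJOR", {
  pkg <- create_package("p", "genome")
  seen <- package_version_string(pkg)
  cmp <- function(a, b) {
    pa <- as.integer(strsplit(a, ".", fixed = TRUE)[[1]])
    pb <- as.integer(strsplit(b, ".", fixed = TRUE)[[1]])
    pa[1] < pb[1] || (pa[1] == pb[1] && pa[2] <= pb[2])
  }
  for (i in 1:4) {
    pkg <- register_layer(pkg, paste0("misc:", i), "misc_gene_data",
                          data.frame(gene_id = i, value = i))
    expect_true(cmp(seen, package_version_string(pkg)))
    seen <- package_version_string(pkg)
  }
  pkg <- remove_layer(pkg, "misc:2")
  expect_equal(package_version_string(pkg), "2.0")
  expect_true(cmp(seen, "2.0"))
  expect_length(package_layers(pkg), 3)
})

test_that("checksums are row-order invariant but content sensitive", {
  df <- data.frame(gene_id = 0:2, value = c(10, 20, 30))
  expect_identical(layer_checksum(df), layer_checksum(df[c(3, 1, 2), ]))
  df2 <- df; df2$value[2] <- 21
  expect_false(identical(layer_checksum(df), layer_checksum(df2)))
})

test_that("verify_integrity flags exactly the corrupted layer", {
  pkg <- create_package("p", "genome")
  expect_equal(nrow(verify_integrity(pkg)), 0)

  pkg <- register_layer(pkg, "misc:a", "misc_gene_data", data.frame(gene_id = 0, value = 1))
  pkg <- register_layer(pkg, "misc:b", "misc_gene_data", data.frame(gene_id = 1, value = 2))
  rep <- verify_integrity(pkg)
  expect_true(all(rep$status == "ok"))

  pkg$layers[["misc:a"]]$value <- 99  # byte-flip equivalent
  rep <- verify_integrity(pkg)
  expect_equal(rep$status[rep$layer_id == "misc:a"], "mismatch")
  expect_equal(rep$status[rep$layer_id == "misc:b"], "ok")
})

test_that("export -> import round trip preserves manifest and layer checksums", {
  pkg <- make_toy_package(seed = 7)
  genes <- gene_calls(pkg)
  cov <- data.frame(gene_id = genes$gene_id,
                    read_count = seq_len(nrow(genes)) * 10,
                    mean_coverage = seq_len(nrow(genes)) * 1.5)
  pkg <- add_coverage_layer(pkg, "S1", cov, total_mapped_reads = 1000)
  pkg <- attach_tree_layer(pkg, ape::read.tree(text = "((a:1,b:2):1,c:3);"), "demo")

  d <- withr::local_tempdir()
  export_package(pkg, d)
  pkg2 <- import_package(d)

  expect_equal(pkg2$manifest$package_name, pkg$manifest$package_name)
  expect_equal(pkg2$manifest$version, pkg$manifest$version)
  expect_identical(vapply(pkg2$manifest$layers, `[[`, "", "checksum"),
                   vapply(pkg$manifest$layers, `[[`, "", "checksum"))
  expect_true(all(verify_integrity(pkg2)$status == "ok"))

  # exported files are readable by generic parsers
  tsvs <- list.files(file.path(d, "layers"), pattern = "\\.tsv$", full.names = TRUE)
  expect_gt(length(tsvs), 0)
  for (f in tsvs) expect_silent(read.delim(f, sep = "\t", check.names = FALSE))
  expect_s4_class(Biostrings::readDNAStringSet(file.path(d, "genome.fasta")),
                  "DNAStringSet")
})

test_that("import errors name a deleted layer file and detect tampering", {
  pkg <- create_package("p", "genome")
  pkg <- register_layer(pkg, "misc:x", "misc_gene_data", data.frame(gene_id = 0, value = 5))
  pkg <- register_layer(pkg, "misc:y", "misc_gene_data", data.frame(gene_id = 1, value = 6))
  d <- withr::local_tempdir()
  export_package(pkg, d)

  file.remove(file.path(d, "layers", "misc_x.tsv"))
  expect_error(import_package(d), "misc:x")

  d2 <- withr::local_tempdir()
  export_package(pkg, d2)
  path <- file.path(d2, "layers", "misc_y.tsv")
  txt <- readLines(path)
  txt[2] <- sub("6", "7", txt[2])
  writeLines(txt, path)
  expect_error(import_package(d2), "checksum mismatch.*misc:y")
})
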