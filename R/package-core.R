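# Versioned package container: manifest, layer registry, changelog,
# integrity verification and universal-format export/import.

LAYER_TYPES <- c("annotation_source", "coverage_sample", "proteome",
                 "misc_gene_data", "collection", "tree", "ani", "clusters")

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_version <- function(v) {
  parts <- strsplit(v, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))) ||
      any(as.integer(parts) < 0L)) {
    stop("version must be MAJOR.MINOR with non-negative integers, got '", v, "'")
  }
  as.integer(parts)
}

bump_version <- function(v, which = c("minor", "major")) {
  which <- match.arg(which)
  p <- parse_version(v)
  if (which == "minor") paste(p[1], p[2] + 1L, sep = ".") else paste(p[1] + 1L, 0L, sep = ".")
}

version_leq <- function(a, b) {
  pa <- parse_version(a); pb <- parse_version(b)
  pa[1] < pb[1] || (pa[1] == pb[1] && pa[2] <= pb[2])
}

#' Create a new data package
#'
#' A package is the versioned, self-describing container the rest of the
#' toolkit operates on: it is anchored on a genome (kind `"genome"`) or on a
#' set of genomes (kind `"pangenome"`), and accumulates checksummed,
#' gene-referenced data layers under MAJOR.MINOR versioning with a changelog.
#'
#' @param name Non-empty package name.
#' @param kind `"genome"` or `"pangenome"`.
#' @param doi Optional DOI string (metadata only; nothing is registered).
#' @return A `dm_package` object at version `"1.0"` with no layers.
#' @examples
#' pkg <- create_package("toy", "genome")
#' package_version_string(pkg)
#' @export
create_package <- function(name, kind = c("genome", "pangenome"), doi = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("package name must be a non-empty string")
  }
  kind <- match.arg(kind)
  now <- utc_now()
  structure(list(
    manifest = list(
      package_name = name,
      package_kind = kind,
      version = "1.0",
      doi = doi,
      created = now,
      modified = now,
      layers = list(),
      changelog = list(list(version = "1.0", timestamp = now,
                            description = "created",
                            layers_added = character(), layers_removed = character()))
    ),
    genome = list(contigs = NULL, gene_calls = NULL, annotations = NULL),
    pangenome = NULL,
    layers = list()
  ), class = "dm_package")
}

#' @export
print.dm_package <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<dm_package '%s' (%s) v%s>\n", m$package_name, m$package_kind, m$version))
  if (!is.null(m$doi)) cat("  doi:", m$doi, "\n")
  if (!is.null(x$genome$contigs)) {
    cat(sprintf("  genome: %d contig(s), %d bp, %d gene(s)\n",
                length(x$genome$contigs), sum(nchar(x$genome$contigs)),
                if (is.null(x$genome$gene_calls)) 0L else nrow(x$genome$gene_calls)))
  }
  cat(sprintf("  layers: %d\n", length(m$layers)))
  for (rec in m$layers) {
    cat(sprintf("    - %s [%s] added in v%s\n", rec$layer_id, rec$layer_type,
                rec$added_in_version))
  }
  invisible(x)
}

#' @rdname create_package
#' @param pkg A `dm_package`.
#' @export
package_version_string <- function(pkg) pkg$manifest$version

#' @rdname create_package
#' @export
package_layers <- function(pkg) {
  vapply(pkg$manifest$layers, `[[`, character(1), "layer_id")
}

append_changelog <- function(pkg, description, added = character(), removed = character()) {
  now <- utc_now()
  pkg$manifest$modified <- now
  pkg$manifest$changelog <- c(pkg$manifest$changelog,
                              list(list(version = pkg$manifest$version, timestamp = now,
                                        description = description,
                                        layers_added = added, layers_removed = removed)))
  pkg
}

#' Register a data layer
#'
#' Stores `content` under `layer_id`, computes its checksum, bumps the MINOR
#' version and appends a changelog entry. Layers are immutable: registering a
#' new layer never changes the checksum of an existing one.
#'
#' @param pkg A `dm_package`.
#' @param layer_id Unique layer identifier (convention: `"type:name"`).
#' @param layer_type One of `"annotation_source"`, `"coverage_sample"`,
#'   `"proteome"`, `"misc_gene_data"`, `"collection"`, `"tree"`, `"ani"`,
#'   `"clusters"`.
#' @param content A data frame, matrix, named character vector or `phylo` tree.
#' @param provenance Free-text description of where the layer came from.
#' @param meta Optional list of small scalar metadata (kept in the manifest,
#'   not checksummed).
#' @return The updated package.
#' @export
register_layer <- function(pkg, layer_id, layer_type, content, provenance = "",
                           meta = NULL) {
  stopifnot(inherits(pkg, "dm_package"))
  if (!layer_type %in% LAYER_TYPES) {
    stop("unknown layer_type '", layer_type, "'")
  }
  if (layer_id %in% package_layers(pkg)) {
    stop("layer '", layer_id, "' is already registered")
  }
  checksum <- layer_checksum(content)
  pkg$manifest$version <- bump_version(pkg$manifest$version, "minor")
  rec <- list(layer_id = layer_id, layer_type = layer_type,
              provenance = provenance, added_in_version = pkg$manifest$version,
              checksum = checksum)
  if (!is.null(meta)) rec$meta <- meta
  pkg$manifest$layers <- c(pkg$manifest$layers, list(rec))
  pkg$layers[[layer_id]] <- content
  append_changelog(pkg, paste0("registered layer '", layer_id, "'"),
                   added = layer_id)
}

# Replace an existing layer's content in place (e.g. an annotation re-import
# with overwrite). Additive update: bumps MINOR and refreshes the checksum.
update_layer <- function(pkg, layer_id, content, description) {
  idx <- which(package_layers(pkg) == layer_id)
  if (length(idx) != 1L) stop("layer '", layer_id, "' is not registered")
  new_sum <- layer_checksum(content)
  if (identical(new_sum, pkg$manifest$layers[[idx]]$checksum)) return(pkg)
  pkg$manifest$version <- bump_version(pkg$manifest$version, "minor")
  pkg$manifest$layers[[idx]]$checksum <- new_sum
  pkg$layers[[layer_id]] <- content
  append_changelog(pkg, description, added = layer_id)
}

#' Remove a layer (destructive; bumps MAJOR)
#'
#' @inheritParams register_layer
#' @return The updated package.
#' @export
remove_layer <- function(pkg, layer_id) {
  idx <- which(package_layers(pkg) == layer_id)
  if (length(idx) != 1L) stop("layer '", layer_id, "' is not registered")
  pkg$manifest$version <- bump_version(pkg$manifest$version, "major")
  pkg$manifest$layers[[idx]] <- NULL
  pkg$layers[[layer_id]] <- NULL
  append_changelog(pkg, paste0("removed layer '", layer_id, "'"), removed = layer_id)
}

#' Get a layer's content
#' @inheritParams register_layer
#' @export
get_layer <- function(pkg, layer_id) {
  if (!layer_id %in% package_layers(pkg)) stop("layer '", layer_id, "' is not registered")
  pkg$layers[[layer_id]]
}

#' Verify package integrity
#'
#' Recomputes every layer's checksum from its stored content and compares it
#' with the checksum recorded in the manifest.
#'
#' @param pkg A `dm_package`.
#' @return Data frame with columns `layer_id`, `status` (`"ok"` or
#'   `"mismatch"`) and `reason`.
#' @export
verify_integrity <- function(pkg) {
  stopifnot(inherits(pkg, "dm_package"))
  recs <- pkg$manifest$layers
  out <- data.frame(layer_id = character(0), status = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  for (rec in recs) {
    content <- pkg$layers[[rec$layer_id]]
    row <- if (is.null(content)) {
      c(rec$layer_id, "mismatch", "layer content missing")
    } else {
      actual <- tryCatch(layer_checksum(content), error = function(e) NA_character_)
      if (is.na(actual)) c(rec$layer_id, "mismatch", "unreadable content")
      else if (identical(actual, rec$checksum)) c(rec$layer_id, "ok", "")
      else c(rec$layer_id, "mismatch", "checksum differs from manifest")
    }
    out[nrow(out) + 1L, ] <- row
  }
  out
}

safe_filename <- function(layer_id) gsub("[^A-Za-z0-9._-]", "_", layer_id)

#' Export / import a package in universal formats
#'
#' `export_package()` writes the package to a directory as a JSON manifest,
#' one TSV per tabular layer, FASTA for genome sequences and newick for tree
#' layers. `import_package()` reads such a directory back and verifies every
#' layer checksum; the round trip is the identity on the manifest and all
#' layer checksums.
#'
#' @param pkg A `dm_package`.
#' @param out_dir Output directory (created if needed).
#' @return `export_package()` returns `out_dir` invisibly; `import_package()`
#'   returns the reconstructed `dm_package`.
#' @export
export_package <- function(pkg, out_dir) {
  stopifnot(inherits(pkg, "dm_package"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "layers"), showWarnings = FALSE)

  layer_files <- list()
  for (rec in pkg$manifest$layers) {
    content <- pkg$layers[[rec$layer_id]]
    fn <- if (inherits(content, "phylo")) {
      f <- file.path("layers", paste0(safe_filename(rec$layer_id), ".nwk"))
      ape::write.tree(content, file.path(out_dir, f))
      f
    } else {
      f <- file.path("layers", paste0(safe_filename(rec$layer_id), ".tsv"))
      write_canonical_tsv(content, file.path(out_dir, f))
      f
    }
    layer_files[[rec$layer_id]] <- fn
  }

  if (!is.null(pkg$genome$contigs)) {
    seqs <- Biostrings::DNAStringSet(pkg$genome$contigs)
    Biostrings::writeXStringSet(seqs, file.path(out_dir, "genome.fasta"), width = 80L)
  }
  if (!is.null(pkg$genome$gene_calls)) {
    write_canonical_tsv(pkg$genome$gene_calls, file.path(out_dir, "gene_calls.tsv"))
  }

  manifest <- pkg$manifest
  manifest$layers <- lapply(manifest$layers, function(rec) {
    rec$file <- layer_files[[rec$layer_id]]
    rec
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  invisible(out_dir)
}

#' @rdname export_package
#' @param dir Directory previously written by `export_package()`.
#' @export
import_package <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  manifest$changelog <- lapply(manifest$changelog, function(e) {
    e$layers_added <- as.character(unlist(e$layers_added))
    e$layers_removed <- as.character(unlist(e$layers_removed))
    e
  })

  pkg <- structure(list(
    manifest = manifest,
    genome = list(contigs = NULL, gene_calls = NULL, annotations = NULL),
    pangenome = NULL,
    layers = list()
  ), class = "dm_package")

  fasta <- file.path(dir, "genome.fasta")
  if (file.exists(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    pkg$genome$contigs <- stats::setNames(as.character(seqs), names(seqs))
  }
  gc_path <- file.path(dir, "gene_calls.tsv")
  if (file.exists(gc_path)) pkg$genome$gene_calls <- read_layer_tsv(gc_path)

  for (i in seq_along(pkg$manifest$layers)) {
    rec <- pkg$manifest$layers[[i]]
    path <- file.path(dir, rec$file)
    if (!file.exists(path)) {
      stop("layer '", rec$layer_id, "' is missing its file '", rec$file, "'")
    }
    content <- if (grepl("\\.nwk$", path)) ape::read.tree(path) else read_layer_tsv(path)
    actual <- layer_checksum(content)
    if (!identical(actual, rec$checksum)) {
      stop("checksum mismatch for layer '", rec$layer_id,
           "': manifest says ", rec$checksum, ", content gives ", actual)
    }
    pkg$layers[[rec$layer_id]] <- content
    pkg$manifest$layers[[i]]$file <- NULL
  }

  # rebuild the merged annotation table from annotation layers
  ann_layers <- Filter(function(r) identical(r$layer_type, "annotation_source"),
                       pkg$manifest$layers)
  if (length(ann_layers)) {
    pkg$genome$annotations <- do.call(rbind, lapply(ann_layers, function(r) {
      pkg$layers[[r$layer_id]]
    }))
    rownames(pkg$genome$annotations) <- NULL
  }
  pkg
}
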