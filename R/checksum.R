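#' @keywords internal
"_PACKAGE"

# Canonical serialization used for layer checksums and TSV export.
#
# Rules: UTF-8 text, "\n" line endings, tab-separated columns in the layer's
# stored column order. For checksumming, data rows are additionally sorted
# bytewise (radix) so the digest is independent of row order and locale;
# export preserves the stored row order (collections are ordered).

canonical_cell <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) {
    out <- ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
  } else if (is.numeric(x)) {
    # as.character() renders doubles at 15 significant digits, a fixpoint of
    # the string -> double -> string round trip, so re-imported layers hash
    # identically.
    out <- ifelse(is.na(x), "NA", as.character(x))
    out[out == "-0"] <- "0"
  } else {
    out <- ifelse(is.na(x), "NA", as.character(x))
  }
  out
}

serialize_lines <- function(content, sort_rows = FALSE) {
  if (inherits(content, "phylo")) {
    return(ape::write.tree(content))
  }
  if (is.matrix(content)) {
    df <- as.data.frame(content, stringsAsFactors = FALSE)
    df <- cbind(id = rownames(content), df, stringsAsFactors = FALSE)
    content <- df
  }
  if (is.data.frame(content)) {
    header <- paste(names(content), collapse = "\t")
    if (nrow(content) == 0L) return(header)
    cells <- vapply(content, canonical_cell, character(nrow(content)))
    if (nrow(content) == 1L) cells <- matrix(cells, nrow = 1L)
    rows <- apply(cells, 1L, paste, collapse = "\t")
    if (sort_rows) rows <- sort(rows, method = "radix")
    return(c(header, rows))
  }
  if (is.character(content)) {
    if (!is.null(names(content))) {
      rows <- paste(names(content), content, sep = "\t")
      if (sort_rows) rows <- sort(rows, method = "radix")
      return(rows)
    }
    return(content)
  }
  stop("cannot serialize layer content of class ", paste(class(content), collapse = "/"))
}

#' Content checksum of a layer
#'
#' Computes the hex digest of the canonical serialization (sorted rows, fixed
#' column order, UTF-8) of a layer's content. Identical content always yields
#' an identical checksum regardless of row order or platform.
#'
#' @param content A data frame, matrix, named character vector (sequences) or
#'   `ape::phylo` tree.
#' @return Hex digest string.
#' @export
layer_checksum <- function(content) {
  txt <- paste0(paste(serialize_lines(content, sort_rows = TRUE), collapse = "\n"), "\n")
  tf <- tempfile(fileext = ".canon")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, open = "wb")
  writeBin(charToRaw(enc2utf8(txt)), con)
  close(con)
  unname(tools::md5sum(tf))
}

write_canonical_tsv <- function(content, path) {
  lines <- serialize_lines(content, sort_rows = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"), "\n"))), con)
  invisible(path)
}

read_layer_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "", na.strings = "NA",
                          stringsAsFactors = FALSE)
  df[] <- lapply(df, function(col) utils::type.convert(col, as.is = TRUE))
  df
}
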