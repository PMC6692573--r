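#' Read a designed reporter library from disk
#'
#' Two formats are supported. \code{tsv}: tab-delimited with a header row and
#' columns \code{construct_id}, \code{reg_seq}, \code{barcode} and optionally
#' \code{reporter_context} plus free metadata columns. \code{fasta}: one
#' record per construct with header \code{construct_id|barcode} and sequence
#' \code{reg_seq} followed by \code{reporter_context}; the context length is
#' taken from \code{contextLength} (FASTA carries no field separator).
#'
#' Input is case-insensitive and uppercased on load. Duplicate barcodes and
#' non-ACGT characters are hard errors naming the offending entries.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"fasta"}.
#' @param name library name (defaults to the file name).
#' @param contextLength reporter-context length for FASTA input.
#' @param variableLength allow unequal regulatory-sequence lengths.
#' @return a \linkS4class{ReporterLibrary}, in file order.
#' @export
loadLibrary <- function(path, format = c("tsv", "fasta"), name = NULL,
                        contextLength = 0L, variableLength = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "",
                            check.names = FALSE)
    need <- c("construct_id", "reg_seq", "barcode")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0L)
      stop("missing TSV columns: ", paste(miss, collapse = ", "), call. = FALSE)
    if (!"reporter_context" %in% colnames(df)) df$reporter_context <- ""
    df$reporter_context[is.na(df$reporter_context)] <- ""
    for (col in c("reg_seq", "barcode", "reporter_context")) {
      vals <- toupper(df[[col]])
      bad <- which(!.is_dna(vals))
      if (length(bad) > 0L)
        stop(sprintf("non-ACGT character in column %s, line %d", col,
                     bad[1L] + 1L), call. = FALSE)
      df[[col]] <- vals
    }
    meta_cols <- setdiff(colnames(df), c("construct_id", "reg_seq", "barcode",
                                         "reporter_context"))
    meta <- if (length(meta_cols) > 0L) df[meta_cols] else NULL
    ReporterLibrary(df$construct_id, df$reg_seq, df$barcode,
                    df$reporter_context, name = name,
                    variableLength = variableLength, metadata = meta)
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    headers <- names(seqs)
    parts <- strsplit(headers, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("FASTA headers must be 'construct_id|barcode'", call. = FALSE)
    ids <- vapply(parts, `[`, "", 1L)
    bcs <- toupper(vapply(parts, `[`, "", 2L))
    full <- toupper(as.character(seqs))
    if (any(nchar(full) <= contextLength))
      stop("sequence shorter than declared reporter context", call. = FALSE)
    reg <- substr(full, 1L, nchar(full) - contextLength)
    ctx <- substr(full, nchar(full) - contextLength + 1L, nchar(full))
    ReporterLibrary(ids, reg, bcs, ctx, name = name,
                    variableLength = variableLength)
  }
}

#' Write a reporter library to disk
#'
#' Inverse of \code{\link{loadLibrary}}: output is parseable by
#' \code{loadLibrary} and bit-stable for a fixed library (no timestamps).
#'
#' @param lib a \linkS4class{ReporterLibrary}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"fasta"}.
#' @return \code{path}, invisibly.
#' @export
writeLibrary <- function(lib, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  methods::validObject(lib)
  df <- as.data.frame(lib@constructs)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    seqs <- Biostrings::DNAStringSet(paste0(df$reg_seq, df$reporter_context))
    names(seqs) <- paste0(df$construct_id, "|", df$barcode)
    Biostrings::writeXStringSet(seqs, path)
  }
  invisible(path)
}
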