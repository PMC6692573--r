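#' ReporterLibrary: a designed library of barcoded regulatory sequences
#'
#' Container for a pooled reporter library. Each member (construct) is a
#' regulatory sequence of fixed length placed immediately upstream of a
#' reporter ATG, identified by a unique N-terminal DNA barcode. Coordinates
#' follow the ATG convention: the first base of the reporter ATG is +1, the
#' last base of the regulatory sequence is -1, and all upstream positions
#' (including transcription start sites) are negative integers with no zero.
#'
#' @slot name library name.
#' @slot constructs a \link[S4Vectors]{DataFrame} with columns
#'   \code{construct_id}, \code{reg_seq}, \code{barcode},
#'   \code{reporter_context}, plus any free metadata columns.
#' @slot variableLength allow members of unequal regulatory-sequence length.
#'
#' @export
setClass("ReporterLibrary",
  representation(
    name = "character",
    constructs = "DataFrame",
    variableLength = "logical"
  ),
  prototype(
    name = "library",
    constructs = S4Vectors::DataFrame(
      construct_id = character(), reg_seq = character(),
      barcode = character(), reporter_context = character()
    ),
    variableLength = FALSE
  )
)

setValidity("ReporterLibrary", function(object) {
  df <- object@constructs
  need <- c("construct_id", "reg_seq", "barcode", "reporter_context")
  if (!all(need %in% colnames(df)))
    return(paste("constructs must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  for (col in c("reg_seq", "barcode", "reporter_context")) {
    bad <- which(!.is_dna(df[[col]]))
    if (length(bad) > 0L)
      msgs <- c(msgs, sprintf("non-ACGT character in %s (row %d)", col, bad[1L]))
  }
  dup <- unique(df$barcode[duplicated(df$barcode)])
  if (length(dup) > 0L)
    msgs <- c(msgs, paste("duplicate barcodes:", paste(dup, collapse = ", ")))
  if (anyDuplicated(df$construct_id))
    msgs <- c(msgs, "duplicate construct_id")
  if (nrow(df) > 0L) {
    if (length(unique(nchar(df$barcode))) > 1L)
      msgs <- c(msgs, "barcodes must share one fixed length")
    if (!object@variableLength && length(unique(nchar(df$reg_seq))) > 1L)
      msgs <- c(msgs, "unequal reg_seq lengths (set variableLength = TRUE to allow)")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a ReporterLibrary
#'
#' @param construct_id unique member identifiers.
#' @param reg_seq regulatory sequences (A/C/G/T only; case-insensitive,
#'   uppercased on entry).
#' @param barcode member barcodes, one fixed length, unique within the
#'   library.
#' @param reporter_context constant sequence joining the regulatory sequence
#'   to the reporter ATG and barcode (may be empty).
#' @param name library name.
#' @param variableLength allow unequal regulatory-sequence lengths.
#' @param metadata optional data.frame of free per-construct annotation
#'   (e.g. donor phylum, source gene class).
#' @return a \linkS4class{ReporterLibrary}.
#' @examples
#' lib <- ReporterLibrary(
#'   construct_id = c("p1", "p2"),
#'   reg_seq = c("ACGTACGT", "TTGACAAT"),
#'   barcode = c("AAAA", "CCCC")
#' )
#' barcodes(lib)
#' @export
ReporterLibrary <- function(construct_id, reg_seq, barcode,
                            reporter_context = "", name = "library",
                            variableLength = FALSE, metadata = NULL) {
  df <- S4Vectors::DataFrame(
    construct_id = as.character(construct_id),
    reg_seq = toupper(as.character(reg_seq)),
    barcode = toupper(as.character(barcode)),
    reporter_context = toupper(rep_len(as.character(reporter_context),
                                       length(construct_id)))
  )
  if (!is.null(metadata)) {
    stopifnot(nrow(metadata) == nrow(df))
    for (col in colnames(metadata)) df[[col]] <- metadata[[col]]
  }
  methods::new("ReporterLibrary", name = name, constructs = df,
               variableLength = variableLength)
}

#' @describeIn ReporterLibrary number of constructs
#' @param x a ReporterLibrary.
#' @export
setMethod("length", "ReporterLibrary", function(x) nrow(x@constructs))

#' @export
setMethod("constructIds", "ReporterLibrary", function(x) x@constructs$construct_id)

#' @export
setMethod("regSeqs", "ReporterLibrary", function(x) {
  stats::setNames(Biostrings::DNAStringSet(x@constructs$reg_seq),
                  x@constructs$construct_id)
})

#' @export
setMethod("barcodes", "ReporterLibrary", function(x) {
  stats::setNames(x@constructs$barcode, x@constructs$construct_id)
})

#' @export
setMethod("reporterContexts", "ReporterLibrary", function(x) {
  stats::setNames(x@constructs$reporter_context, x@constructs$construct_id)
})

#' @export
setMethod("barcodeIndex", "ReporterLibrary", function(x) {
  stats::setNames(x@constructs$construct_id, x@constructs$barcode)
})

setMethod("show", "ReporterLibrary", function(object) {
  df <- object@constructs
  cat(sprintf("ReporterLibrary '%s': %d constructs\n", object@name, nrow(df)))
  if (nrow(df) > 0L) {
    cat(sprintf("  reg_seq length: %s nt | barcode length: %d nt\n",
                paste(unique(nchar(df$reg_seq)), collapse = "/"),
                nchar(df$barcode[1L])))
    extra <- setdiff(colnames(df),
                     c("construct_id", "reg_seq", "barcode", "reporter_context"))
    if (length(extra) > 0L)
      cat("  metadata columns:", paste(extra, collapse = ", "), "\n")
  }
})

#' ReporterCounts: per-construct sequencing read counts
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} holding one integer
#' assay \code{counts} with rows = library constructs and one column per
#' sequencing file, annotated in \code{colData} with \code{sample},
#' \code{replicate} and \code{kind} (\code{"DNA"} or \code{"RNA"}).
#'
#' @export
setClass("ReporterCounts", contains = "SummarizedExperiment")

setValidity("ReporterCounts", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msgs <- character()
  if (!all(c("sample", "replicate", "kind") %in% colnames(cd)))
    msgs <- c(msgs, "colData needs sample, replicate, kind")
  else if (!all(cd$kind %in% c("DNA", "RNA")))
    msgs <- c(msgs, "kind must be DNA or RNA")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'counts' required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0) || any(m != round(m)))
      msgs <- c(msgs, "counts must be non-negative integers")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' ActivitySet: per-construct transcriptional activity estimates
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with rows = constructs
#' and columns = samples, holding assays \code{txRaw} (relative-RNA over
#' relative-DNA ratio), \code{txLog10}, \code{txZ} (Z-score of txLog10
#' across constructs passing the DNA-abundance filter), \code{passFilter}
#' (summed DNA count at or above the cutoff) and \code{inactive} (passed the
#' DNA filter but had zero RNA).
#'
#' @export
setClass("ActivitySet", contains = "SummarizedExperiment")

setValidity("ActivitySet", function(object) {
  need <- c("txRaw", "txLog10", "txZ", "passFilter", "inactive")
  miss <- setdiff(need, SummarizedExperiment::assayNames(object))
  if (length(miss) > 0L)
    paste("missing assays:", paste(miss, collapse = ", "))
  else TRUE
})

#' TssCallSet: transcription start site calls for a library
#'
#' Holds, per construct, the clustered mRNA 5'-end pileup and the resulting
#' primary and secondary transcription start site calls. Positions are in bp
#' from the reporter ATG (negative upstream). A primary TSS is the
#' representative of the unique cluster holding > 70\% of 5'-end reads with
#' > 200 reads; secondary TSSs represent other clusters holding > 10\%.
#'
#' @slot calls \link[S4Vectors]{DataFrame} with columns \code{construct_id},
#'   \code{primary_tss} (NA when no primary call), \code{primary_fraction},
#'   \code{primary_count}, \code{total_reads}, \code{secondaries}
#'   (comma-joined positions, "" when none).
#' @slot clusters named list (by construct_id) of data.frames with columns
#'   \code{representative}, \code{count}, \code{fraction}.
#'
#' @export
setClass("TssCallSet",
  representation(calls = "DataFrame", clusters = "list"),
  prototype(calls = S4Vectors::DataFrame(
    construct_id = character(), primary_tss = integer(),
    primary_fraction = numeric(), primary_count = integer(),
    total_reads = integer(), secondaries = character()
  ), clusters = list())
)

setValidity("TssCallSet", function(object) {
  df <- object@calls
  need <- c("construct_id", "primary_tss", "primary_fraction",
            "primary_count", "total_reads", "secondaries")
  if (!all(need %in% colnames(df)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  if (!all(names(object@clusters) %in% df$construct_id))
    return("clusters keyed by unknown construct_id")
  TRUE
})

#' @export
setMethod("length", "TssCallSet", function(x) nrow(x@calls))

#' @export
setMethod("primaryTss", "TssCallSet", function(x) {
  stats::setNames(x@calls$primary_tss, x@calls$construct_id)
})

#' @export
setMethod("secondaryTss", "TssCallSet", function(x) {
  out <- lapply(x@calls$secondaries, function(s) {
    if (is.na(s) || s == "") integer() else as.integer(strsplit(s, ",")[[1L]])
  })
  stats::setNames(out, x@calls$construct_id)
})

#' @export
setMethod("tssClusters", "TssCallSet", function(x) x@clusters)

setMethod("show", "TssCallSet", function(object) {
  df <- object@calls
  cat(sprintf("TssCallSet: %d constructs, %d with a primary TSS\n",
              nrow(df), sum(!is.na(df$primary_tss))))
})

#' PWMatrix: a position probability matrix with log-odds scoring
#'
#' Per-position base probabilities (columns sum to one) with a background
#' distribution; scores are log2 odds in bits.
#'
#' @slot probs 4 x width numeric matrix, rows A/C/G/T.
#' @slot background length-4 base probabilities.
#' @slot pseudocount pseudocount applied when the matrix was estimated.
#'
#' @export
setClass("PWMatrix",
  representation(probs = "matrix", background = "numeric",
                 pseudocount = "numeric"),
  prototype(probs = matrix(0.25, 4, 1, dimnames = list(DNA_BASES, NULL)),
            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
            pseudocount = 0.5)
)

setValidity("PWMatrix", function(object) {
  p <- object@probs
  msgs <- character()
  if (!identical(rownames(p), DNA_BASES))
    msgs <- c(msgs, "probs rows must be A, C, G, T")
  if (any(abs(colSums(p) - 1) > 1e-9))
    msgs <- c(msgs, "each position must sum to 1")
  if (any(p <= 0))
    msgs <- c(msgs, "all probabilities must be > 0 (apply a pseudocount)")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-9)
    msgs <- c(msgs, "background must be 4 probabilities summing to 1")
  if (length(msgs) > 0L) msgs else TRUE
})

#' @export
setMethod("pwmProbs", "PWMatrix", function(x) x@probs)

#' @export
setMethod("pwmWidth", "PWMatrix", function(x) ncol(x@probs))

#' @export
setMethod("consensusSeq", "PWMatrix", function(x) {
  paste(rownames(x@probs)[apply(x@probs, 2L, which.max)], collapse = "")
})

setMethod("show", "PWMatrix", function(object) {
  cat(sprintf("PWMatrix: width %d, consensus %s\n",
              pwmWidth(object), consensusSeq(object)))
})

#' PromoterModel: a fitted linear model of transcriptional activity
#'
#' Ordinary least squares fit of Z-scored log10 activity on standardized
#' promoter sequence features, with the standardization constants needed to
#' apply it to new libraries and to convert predictions back to the log10
#' scale.
#'
#' @slot coefficients per-feature weights (standardized scale).
#' @slot intercept model intercept.
#' @slot featureCenter,featureScale standardization constants for X.
#' @slot log10Center,log10Scale mean/SD of txLog10 over the training
#'   constructs, used to map Z-scale predictions back to log10.
#' @slot trainFraction fraction of data used for training.
#' @slot rTrain,rTest Pearson correlations (NA when not evaluated).
#' @slot fracWithin1Log fraction of test predictions within one log10 unit.
#'
#' @export
setClass("PromoterModel",
  representation(
    coefficients = "numeric", intercept = "numeric",
    featureCenter = "numeric", featureScale = "numeric",
    log10Center = "numeric", log10Scale = "numeric",
    trainFraction = "numeric", rTrain = "numeric", rTest = "numeric",
    fracWithin1Log = "numeric"
  ),
  prototype(trainFraction = 1, rTrain = NA_real_, rTest = NA_real_,
            fracWithin1Log = NA_real_, log10Center = 0, log10Scale = 1)
)

setMethod("show", "PromoterModel", function(object) {
  cat(sprintf("PromoterModel: %d features, r_train = %.3f, r_test = %.3f\n",
              length(object@coefficients), object@rTrain, object@rTest))
})
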