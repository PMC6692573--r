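#' Tabulate demultiplexed reads into a count table
#'
#' Counts assigned reads per (construct, sample, replicate, kind). Every
#' library construct appears as a row (zeros allowed); each column's sum
#' equals the number of assigned reads in the corresponding input. By
#' default counting is barcode-based: RNA reads that failed the
#' regulatory-segment QC still count toward abundance (set
#' \code{countsFrom = "match"} to restrict to QC-passing reads).
#'
#' @param reads a \code{data.table} from \code{\link{assignReads}}, or a list
#'   of them (one per sequencing file). Supplying two inputs with the same
#'   (sample, replicate, kind) key is an error.
#' @param lib a \linkS4class{ReporterLibrary}.
#' @param countsFrom \code{"barcode"} (default) or \code{"match"}.
#' @return a \linkS4class{ReporterCounts}.
#' @export
tabulateCounts <- function(reads, lib, countsFrom = c("barcode", "match")) {
  countsFrom <- match.arg(countsFrom)
  if (data.table::is.data.table(reads)) reads <- list(reads)
  key_of <- function(r) {
    k <- attr(r, "filekey")
    if (!is.null(k)) k else unique(as.data.frame(
      r[, c("sample", "replicate", "kind")]))
  }
  key_df <- do.call(rbind, lapply(reads, key_of))
  keys <- paste(key_df$sample, key_df$replicate, key_df$kind, sep = "|")
  if (anyDuplicated(keys))
    stop("duplicate (sample, replicate, kind) across inputs: ",
         keys[duplicated(keys)][1L], call. = FALSE)
  all_reads <- data.table::rbindlist(reads)
  construct_id <- pass_qc <- kind <- NULL  # data.table NSE guard
  assigned <- all_reads[!is.na(construct_id) & construct_id != "UNASSIGNED"]
  if (countsFrom == "match" && nrow(assigned) > 0L)
    assigned <- assigned[pass_qc | kind == "DNA"]
  ids <- constructIds(lib)
  tab <- assigned[, .N, by = c("construct_id", "sample", "replicate", "kind")]
  cols <- unique(data.table::as.data.table(key_df))
  data.table::setorder(cols, sample, kind, replicate)
  colkey <- paste(cols$sample, cols$replicate, cols$kind, sep = "|")
  m <- matrix(0L, nrow = length(ids), ncol = nrow(cols),
              dimnames = list(ids, colkey))
  if (nrow(tab) > 0L) {
    tk <- paste(tab$sample, tab$replicate, tab$kind, sep = "|")
    keep <- tab$construct_id %in% ids
    m[cbind(match(tab$construct_id[keep], ids), match(tk[keep], colkey))] <-
      tab$N[keep]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(sample = cols$sample,
                                   replicate = cols$replicate,
                                   kind = cols$kind, row.names = colkey)
  )
  methods::new("ReporterCounts", se)
}

#' Compute transcriptional activities from a count table
#'
#' For each sample, DNA and RNA counts are first summed over replicates.
#' With relative abundances rel_RNA_i = RNA_i / sum(RNA) and
#' rel_DNA_i = DNA_i / sum(DNA), the transcriptional activity of construct i
#' is the ratio Tx_i = rel_RNA_i / rel_DNA_i. Constructs pass the abundance
#' filter when their summed DNA count reaches \code{dnaMinReads} (default
#' 15), which suppresses noise from poorly represented library members.
#' log10(Tx) is computed over passing constructs with nonzero RNA and
#' converted to Z-scores (population SD) across those constructs.
#'
#' Constructs that pass the DNA filter but have zero RNA are reported as
#' inactive (NA activity) unless \code{pseudocount > 0}, in which case the
#' pseudocount is added to every RNA count before normalization.
#'
#' @param counts a \linkS4class{ReporterCounts}.
#' @param dnaMinReads minimum summed DNA reads for a construct to pass.
#' @param pseudocount added to RNA counts (default 0 = off).
#' @return an \linkS4class{ActivitySet} with one column per sample.
#' @export
computeActivity <- function(counts, dnaMinReads = 15L, pseudocount = 0) {
  methods::validObject(counts)
  m <- SummarizedExperiment::assay(counts, "counts")
  cd <- SummarizedExperiment::colData(counts)
  samples <- unique(cd$sample)
  n <- nrow(m)
  mk <- function() matrix(NA_real_, n, length(samples),
                          dimnames = list(rownames(m), samples))
  txRaw <- mk(); txLog10 <- mk(); txZ <- mk()
  passFilter <- matrix(FALSE, n, length(samples),
                       dimnames = list(rownames(m), samples))
  inactive <- passFilter
  dnaSum <- mk(); rnaSum <- mk()
  for (s in samples) {
    dcols <- which(cd$sample == s & cd$kind == "DNA")
    rcols <- which(cd$sample == s & cd$kind == "RNA")
    if (length(dcols) == 0L || length(rcols) == 0L)
      stop("sample ", s, " needs at least one DNA and one RNA column",
           call. = FALSE)
    dna <- rowSums(m[, dcols, drop = FALSE])
    rna <- rowSums(m[, rcols, drop = FALSE]) + pseudocount
    if (sum(dna) == 0)
      stop("sample ", s, " has all-zero DNA counts", call. = FALSE)
    rel_dna <- dna / sum(dna)
    rel_rna <- rna / sum(rna)
    tx <- ifelse(rel_dna > 0, rel_rna / rel_dna, NA_real_)
    pass <- dna >= dnaMinReads
    inact <- pass & rna == 0
    lg <- ifelse(pass & rna > 0 & rel_dna > 0, log10(tx), NA_real_)
    use <- !is.na(lg)
    if (any(use)) {
      mu <- mean(lg[use])
      sd_pop <- sqrt(mean((lg[use] - mu)^2))
      z <- ifelse(use, if (sd_pop > 0) (lg - mu) / sd_pop else 0, NA_real_)
    } else z <- lg
    txRaw[, s] <- tx; txLog10[, s] <- lg; txZ[, s] <- z
    passFilter[, s] <- pass; inactive[, s] <- inact
    dnaSum[, s] <- dna; rnaSum[, s] <- rna
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(txRaw = txRaw, txLog10 = txLog10, txZ = txZ,
                  passFilter = passFilter, inactive = inactive,
                  dnaCount = dnaSum, rnaCount = rnaSum),
    colData = S4Vectors::DataFrame(sample = samples, row.names = samples)
  )
  out <- methods::new("ActivitySet", se)
  S4Vectors::metadata(out)$dnaMinReads <- dnaMinReads
  S4Vectors::metadata(out)$pseudocount <- pseudocount
  out
}

#' Pearson concordance between two activity profiles
#'
#' Correlation of log10 activities over the constructs passing the DNA
#' filter (with defined activity) in both inputs.
#'
#' @param a,b \linkS4class{ActivitySet}s over the same library.
#' @param sampleA,sampleB sample (column) to compare in each.
#' @param scale compare on \code{"log10"} (default) or \code{"z"} scale.
#' @return list with \code{r} and \code{n} (shared passing constructs).
#' @export
replicateConcordance <- function(a, b, sampleA = 1L, sampleB = 1L,
                                 scale = c("log10", "z")) {
  scale <- match.arg(scale)
  assay_name <- if (scale == "log10") "txLog10" else "txZ"
  va <- SummarizedExperiment::assay(a, assay_name)[, sampleA]
  vb <- SummarizedExperiment::assay(b, assay_name)[, sampleB]
  shared <- intersect(names(va)[!is.na(va)], names(vb)[!is.na(vb)])
  if (length(shared) < 3L)
    stop("fewer than 3 shared passing constructs", call. = FALSE)
  list(r = .pearson(va[shared], vb[shared]), n = length(shared))
}
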