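#' Detect construct depletion and enriched sequence motifs
#'
#' Compares a construct's representation in an input DNA pool against an
#' output pool (e.g. before and after a cell-free reaction in a lysate
#' carrying an active restriction system). Each construct gets a one-sided
#' binomial test of its output count against its input fraction
#' (Benjamini-Hochberg corrected); it is called depleted when q < alpha and
#' its output/input fold change is below \code{fcThreshold}.
#'
#' Among depleted versus retained constructs, all degenerate 5-mers with at
#' most one N are then tested for presence/absence enrichment by the
#' hypergeometric test (BH-corrected) and ranked by fold-enrichment — the
#' screen that surfaces restriction recognition sites such as CCNGG.
#'
#' @param dnaIn,dnaOut named input/output count vectors over the same
#'   constructs (totals > 0).
#' @param seqs named DNA sequences of the constructs (for the k-mer screen);
#'   omit to skip motif enrichment.
#' @param fcThreshold output/input ratio below which a construct can be
#'   called depleted (default 0.5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param k k-mer width for the motif screen (default 5).
#' @return list with \code{perConstruct} (data.frame: construct_id,
#'   input_frac, output_frac, log2_fc, p, q, depleted) and
#'   \code{enrichedKmers} (data.frame: kmer, n_depleted, n_retained,
#'   fold_enrichment, p, q; zero rows when nothing is depleted).
#' @export
detectDepletion <- function(dnaIn, dnaOut, seqs = NULL, fcThreshold = 0.5,
                            alpha = 0.05, k = 5L) {
  ids <- names(dnaIn)
  if (is.null(ids) || !setequal(ids, names(dnaOut)))
    stop("dnaIn and dnaOut must be named over the same constructs",
         call. = FALSE)
  dnaOut <- dnaOut[ids]
  tin <- sum(dnaIn); tout <- sum(dnaOut)
  if (tin <= 0 || tout <= 0) stop("zero total counts", call. = FALSE)
  in_frac <- dnaIn / tin
  out_frac <- dnaOut / tout
  ratio <- ifelse(in_frac > 0, out_frac / in_frac, NA_real_)
  ## one-sided binomial: is the output count lower than expected from the
  ## input fraction?
  p <- stats::pbinom(dnaOut, size = tout, prob = pmin(pmax(in_frac, 0), 1))
  p[in_frac == 0] <- 1
  q <- stats::p.adjust(p, method = "BH")
  depleted <- !is.na(ratio) & q < alpha & ratio < fcThreshold
  per <- data.frame(
    construct_id = ids, input_frac = as.numeric(in_frac),
    output_frac = as.numeric(out_frac), log2_fc = log2(ratio),
    p = as.numeric(p), q = as.numeric(q), depleted = depleted,
    row.names = NULL
  )
  enriched <- data.frame(kmer = character(0), n_depleted = integer(0),
                         n_retained = integer(0),
                         fold_enrichment = numeric(0),
                         p = numeric(0), q = numeric(0))
  if (!is.null(seqs) && any(depleted) && any(!depleted)) {
    seqs <- toupper(seqs[ids])
    present <- lapply(seqs, .degenerate_kmers, k = k)
    dep_sets <- present[depleted]
    ret_sets <- present[!depleted]
    all_kmers <- sort(unique(unlist(dep_sets)))
    n_dep <- length(dep_sets); n_ret <- length(ret_sets)
    cnt_dep <- table(factor(unlist(dep_sets), levels = all_kmers))
    cnt_ret <- table(factor(unlist(ret_sets), levels = all_kmers))
    kd <- as.integer(cnt_dep); kr <- as.integer(cnt_ret)
    ## hypergeometric: draws = depleted set, whites = constructs containing
    ## the k-mer anywhere in the library
    pvals <- stats::phyper(kd - 1L, kd + kr, n_dep + n_ret - kd - kr,
                           n_dep, lower.tail = FALSE)
    qvals <- stats::p.adjust(pvals, method = "BH")
    fe <- (kd / n_dep) / pmax(kr / n_ret, 1 / (2 * n_ret))
    enriched <- data.frame(kmer = all_kmers, n_depleted = kd,
                           n_retained = kr, fold_enrichment = fe,
                           p = pvals, q = qvals, row.names = NULL)
    enriched <- enriched[order(-enriched$fold_enrichment, enriched$p,
                               enriched$kmer), , drop = FALSE]
    rownames(enriched) <- NULL
  }
  list(perConstruct = per, enrichedKmers = enriched)
}

## All degenerate k-mers (<= 1 N) present in one sequence: the exact k-mers
## plus each k-mer with one position masked to N.
.degenerate_kmers <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  exact <- unique(substring(seq, 1:(n - k + 1L), k:n))
  masked <- unlist(lapply(seq_len(k), function(p) {
    out <- exact
    substr(out, p, p) <- "N"
    out
  }))
  unique(c(exact, masked))
}
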