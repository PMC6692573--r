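#' Pseudo-energy of 5' mRNA secondary structure
#'
#' Scores the folding propensity of the transcript 5' end (by convention the
#' first 50 nt downstream of the transcription start site). The built-in
#' \code{nussinov} backend computes the maximum number of nested base pairs
#' (Watson-Crick plus G:U wobble, minimum hairpin loop of 3 unpaired bases)
#' by dynamic programming and reports \code{-1} per pair, a dimensionless
#' pseudo-energy that is always \eqn{\le 0}. The \code{external} backend
#' delegates to a thermodynamic folder through a one-function adapter
#' (sequence in, minimum free energy out), e.g. \code{\link{viennaFolder}}.
#'
#' Sequences are DNA strings read as their transcript (T treated as U).
#'
#' @param seq DNA string (typically at most 50 nt; transcripts truncated by
#'   the reporter ATG may be shorter).
#' @param backend \code{"nussinov"} or \code{"external"}.
#' @param folder for \code{backend = "external"}: a function taking a
#'   sequence and returning a free energy (kcal/mol).
#' @return a number \eqn{\le 0}.
#' @examples
#' fold5prime("AAAAAAAAAA")      # 0: nothing can pair
#' fold5prime("GGGGAAAACCCC")    # -4: a four-pair stem
#' @export
fold5prime <- function(seq, backend = c("nussinov", "external"),
                       folder = NULL) {
  backend <- match.arg(backend)
  seq <- toupper(seq)
  .assert_dna(seq, "folding input")
  if (backend == "external") {
    if (!is.function(folder))
      stop("external backend needs a folder function", call. = FALSE)
    return(min(0, folder(seq)))
  }
  -as.numeric(.nussinov_pairs(seq))
}

## Maximum base pairing (Nussinov) with min loop 3; pairs: AT/TA, GC/CG,
## GT/TG (DNA alphabet standing in for the transcript). Inner maximization
## is vectorized over the bifurcation point.
.nussinov_pairs <- function(seq) {
  v <- strsplit(seq, "")[[1L]]
  n <- length(v)
  if (n < 5L) return(0L)
  pairable <- matrix(FALSE, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  pairable[cbind(c("A", "T", "G", "C", "G", "T"),
                 c("T", "A", "C", "G", "T", "G"))] <- TRUE
  P <- pairable[v, v, drop = FALSE]
  M <- matrix(0L, n, n)
  for (span in 4L:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      ks <- which(P[i:(j - 4L), j]) + i - 1L
      if (length(ks) > 0L) {
        left <- ifelse(ks > i, M[i, pmax(ks - 1L, 1L)], 0L)
        cand <- max(left + M[cbind(ks + 1L, j - 1L)] + 1L)
        if (cand > best) best <- cand
      }
      M[i, j] <- best
    }
  }
  M[1L, n]
}

#' Adapter for the ViennaRNA thermodynamic folding backend
#'
#' Returns a folder function (for \code{\link{fold5prime}}'s
#' \code{external} backend) that shells out to the \code{RNAfold} binary
#' and parses the minimum free energy in kcal/mol.
#'
#' @param binary path to the RNAfold executable.
#' @return a function \code{seq -> mfe}.
#' @export
viennaFolder <- function(binary = "RNAfold") {
  if (Sys.which(binary) == "")
    stop("RNAfold binary not found on PATH", call. = FALSE)
  function(seq) {
    out <- system2(binary, args = "--noPS", input = chartr("T", "U", seq),
                   stdout = TRUE)
    last <- out[length(out)]
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", last))
  }
}
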