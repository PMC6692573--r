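#' Discover an ungapped motif by expectation-maximization
#'
#' One-occurrence-per-sequence (OOPS) EM: every input sequence is assumed to
#' contain exactly one occurrence of a motif of fixed \code{width}, at an
#' unknown offset with a uniform prior. The E-step computes the posterior
#' over offsets from the current position probability matrix against the
#' background; the M-step re-estimates the matrix from posterior-weighted
#' base counts plus a pseudocount. Initialization is deterministic: the most
#' frequent \code{width}-mer across the input (ties broken alphabetically)
#' seeds the matrix at 0.7 for its base per position.
#'
#' Callers studying promoter elements supply the discovery window themselves
#' (e.g. the 45 bp preceding each primary TSS, for the top decile of
#' promoters by activity); this function sees only the windowed sequences.
#'
#' @param seqs character vector of DNA windows (each at least \code{width}
#'   long).
#' @param width motif width (default 6, the sigma70 hexamer width).
#' @param pseudocount added to each base count in the M-step (default 0.5).
#' @param minSeqs minimum number of sequences required (default 20).
#' @param maxIter,tol EM stopping rule: stop when no matrix entry moves by
#'   more than \code{tol}.
#' @return a \linkS4class{PWMatrix}; background = input base frequencies.
#' @export
discoverPwm <- function(seqs, width = 6L, pseudocount = 0.5, minSeqs = 20L,
                        maxIter = 200L, tol = 1e-6) {
  seqs <- toupper(seqs)
  .assert_dna(seqs, "motif discovery input")
  if (length(seqs) < minSeqs)
    stop("need at least ", minSeqs, " sequences, got ", length(seqs),
         call. = FALSE)
  if (any(nchar(seqs) < width))
    stop("all sequences must be at least motif width", call. = FALSE)

  ## integer-encode sequences once: list of base-index vectors (A=1..T=4)
  enc <- lapply(seqs, function(s) match(strsplit(s, "")[[1L]], DNA_BASES))
  allb <- unlist(enc)
  bg <- tabulate(allb, 4L) + pseudocount
  bg <- bg / sum(bg)
  names(bg) <- DNA_BASES

  ## deterministic seed: most frequent width-mer (ties -> alphabetical)
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n >= width) substring(s, 1:(n - width + 1L), width:n) else character(0)
  }))
  tab <- sort(table(kmers), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  seed_kmer <- sort(top)[1L]
  probs <- matrix(0.1, 4L, width, dimnames = list(DNA_BASES, NULL))
  seed_idx <- match(strsplit(seed_kmer, "")[[1L]], DNA_BASES)
  probs[cbind(seed_idx, seq_len(width))] <- 0.7

  log_bg <- log(bg)
  for (iter in seq_len(maxIter)) {
    lp <- log(probs)
    counts <- matrix(0, 4L, width)
    for (v in enc) {
      n_off <- length(v) - width + 1L
      ## log-likelihood of the motif at each offset (background cancels up
      ## to a constant per sequence; keep it for numerical clarity)
      ll <- vapply(seq_len(n_off), function(o) {
        idx <- v[o:(o + width - 1L)]
        sum(lp[cbind(idx, seq_len(width))]) - sum(log_bg[idx])
      }, 0)
      post <- exp(ll - max(ll))
      post <- post / sum(post)
      for (o in seq_len(n_off)) {
        if (post[o] < 1e-12) next
        idx <- v[o:(o + width - 1L)]
        counts[cbind(idx, seq_len(width))] <-
          counts[cbind(idx, seq_len(width))] + post[o]
      }
    }
    new_probs <- sweep(counts + pseudocount, 2L,
                       colSums(counts + pseudocount), "/")
    dimnames(new_probs) <- dimnames(probs)
    delta <- max(abs(new_probs - probs))
    probs <- new_probs
    if (delta < tol) break
  }
  methods::new("PWMatrix", probs = probs, background = bg,
               pseudocount = pseudocount)
}

#' Score a sequence against a position weight matrix
#'
#' Slides the matrix over every offset and returns the best sum of
#' log2(p/background) (bits) with its offset; ties go to the smallest
#' offset.
#'
#' @param pwm a \linkS4class{PWMatrix}.
#' @param seq a DNA string at least as long as the matrix width.
#' @return list with \code{score} (bits) and \code{offset} (1-based).
#' @export
scorePwm <- function(pwm, seq) {
  seq <- toupper(seq)
  .assert_dna(seq, "sequence")
  w <- pwmWidth(pwm)
  if (nchar(seq) < w) stop("sequence shorter than matrix width", call. = FALSE)
  lo <- log2(pwm@probs / pwm@background)
  v <- match(strsplit(seq, "")[[1L]], DNA_BASES)
  n_off <- length(v) - w + 1L
  scores <- vapply(seq_len(n_off), function(o) {
    idx <- v[o:(o + w - 1L)]
    sum(lo[cbind(idx, seq_len(w))])
  }, 0)
  best <- which.max(scores)  # which.max takes the first maximum
  list(score = scores[best], offset = as.integer(best))
}

## Score many equal-role windows; returns numeric vector of best scores.
.score_many <- function(pwm, seqs) {
  vapply(seqs, function(s) {
    if (is.na(s) || nchar(s) < pwmWidth(pwm)) NA_real_
    else scorePwm(pwm, s)$score
  }, 0, USE.NAMES = FALSE)
}

#' Build a position weight matrix from fixed-probability consensus bases
#'
#' Utility for constructing reference matrices (e.g. the sigma70 TTGACA /
#' TATAAT consensus elements): each consensus base receives
#' \code{matchProb}, the other three bases share the remainder equally.
#'
#' @param consensus consensus DNA string.
#' @param matchProb probability of the consensus base per position.
#' @param background background base probabilities (default uniform).
#' @return a \linkS4class{PWMatrix}.
#' @export
consensusPwm <- function(consensus, matchProb = 0.85,
                         background = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  consensus <- toupper(consensus)
  .assert_dna(consensus, "consensus")
  idx <- match(strsplit(consensus, "")[[1L]], DNA_BASES)
  w <- length(idx)
  probs <- matrix((1 - matchProb) / 3, 4L, w,
                  dimnames = list(DNA_BASES, NULL))
  probs[cbind(idx, seq_len(w))] <- matchProb
  methods::new("PWMatrix", probs = probs, background = background,
               pseudocount = 0)
}

#' Serialize / read a position weight matrix as TSV
#'
#' Plain-text layout: one row per motif position, columns A/C/G/T, preceded
#' by a comment line carrying the background frequencies.
#'
#' @param pwm a \linkS4class{PWMatrix}.
#' @param path output path.
#' @return \code{path} (write) or a \linkS4class{PWMatrix} (read).
#' @export
writePwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#background\t",
                    paste(sprintf("%.10g", pwm@background), collapse = "\t")),
             con)
  utils::write.table(t(pwm@probs), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writePwm
#' @export
readPwm <- function(path) {
  first <- readLines(path, n = 1L)
  bg <- as.numeric(strsplit(first, "\t")[[1L]][-1L])
  names(bg) <- DNA_BASES
  m <- as.matrix(utils::read.delim(path, comment.char = "#"))
  methods::new("PWMatrix", probs = t(m)[DNA_BASES, , drop = FALSE],
               background = bg, pseudocount = 0)
}
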