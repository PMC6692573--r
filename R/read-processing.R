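#' Adaptor specification for 3'-ligated sequencing reads
#'
#' The library-preparation chemistry ligates a common adaptor carrying a
#' short stretch of random bases to the cDNA 3' end (the mRNA 5' end). In a
#' merged read the biological payload is followed by \code{nRandom} random
#' bases and then the adaptor sequence.
#'
#' @param adaptorSeq adaptor DNA sequence.
#' @param nRandom number of random ligation bases adjacent to the adaptor
#'   (default 2).
#' @return an \code{AdaptorSpec} list.
#' @export
AdaptorSpec <- function(adaptorSeq, nRandom = 2L) {
  adaptorSeq <- toupper(adaptorSeq)
  .assert_dna(adaptorSeq, "adaptor")
  stopifnot(nRandom >= 0L)
  structure(list(adaptorSeq = adaptorSeq, nRandom = as.integer(nRandom)),
            class = "AdaptorSpec")
}

.hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Merge a read pair by overlap consensus
#'
#' Aligns the 3' end of read 1 against the reverse complement of read 2 and
#' returns the consensus when a unique overlap of at least \code{minOverlap}
#' bases with mismatch fraction at most \code{maxMismatchFrac} exists. At a
#' disagreeing position the base with the higher quality wins (read 1 wins
#' ties or when no qualities are given). Ambiguous overlaps (two offsets tie
#' on score) are rejected; the merge score of an overlap of length o with m
#' mismatches is o - 2m.
#'
#' @param r1,r2 read sequences (r2 in sequencing orientation; it is
#'   reverse-complemented internally).
#' @param minOverlap minimum overlap length.
#' @param maxMismatchFrac maximum fraction of mismatching bases within the
#'   overlap.
#' @param q1,q2 optional integer quality vectors matching r1/r2.
#' @return the merged sequence, or \code{NA_character_} when rejected.
#' @export
mergePairs <- function(r1, r2, minOverlap = 10L, maxMismatchFrac = 0.1,
                       q1 = NULL, q2 = NULL) {
  if (nchar(r1) == 0L || nchar(r2) == 0L) stop("empty read", call. = FALSE)
  r2rc <- .revcomp(r2)
  q2rc <- if (!is.null(q2)) rev(q2) else NULL
  v1 <- utf8ToInt(r1); v2 <- utf8ToInt(r2rc)
  n1 <- length(v1); n2 <- length(v2)
  if (min(n1, n2) < minOverlap) return(NA_character_)
  best <- NULL; best_score <- -Inf; tied <- FALSE
  for (o in seq(from = min(n1, n2), to = minOverlap)) {
    mm <- sum(v1[(n1 - o + 1L):n1] != v2[seq_len(o)])
    if (mm / o > maxMismatchFrac) next
    score <- o - 2L * mm
    if (score > best_score) {
      best <- o; best_score <- score; tied <- FALSE
    } else if (score == best_score) {
      tied <- TRUE
    }
  }
  if (is.null(best) || tied) return(NA_character_)
  o <- best
  ov1 <- v1[(n1 - o + 1L):n1]; ov2 <- v2[seq_len(o)]
  cons <- ov1
  dis <- which(ov1 != ov2)
  if (length(dis) > 0L && !is.null(q1) && !is.null(q2rc)) {
    qq1 <- q1[(n1 - o + 1L):n1]; qq2 <- q2rc[seq_len(o)]
    take2 <- dis[qq2[dis] > qq1[dis]]
    cons[take2] <- ov2[take2]
  }
  intToUtf8(c(v1[seq_len(n1 - o)], cons, v2[-seq_len(o)]))
}

#' Trim the common adaptor and its random ligation bases
#'
#' Scans the read for the adaptor from the 3' end, allowing up to
#' \code{maxMismatches} substitutions; the rightmost acceptable placement
#' wins. The adaptor, everything 3' of it, and the \code{nRandom} random
#' ligation bases immediately 5' of it are removed.
#'
#' @param seqs character vector of merged read sequences.
#' @param spec an \code{\link{AdaptorSpec}}.
#' @param maxMismatches allowed substitutions within the adaptor match.
#' @return character vector of biological payloads; \code{NA} where the
#'   adaptor was not found or too little sequence precedes it.
#' @export
trimAdaptor <- function(seqs, spec, maxMismatches = 0L) {
  ad <- spec$adaptorSeq
  w <- nchar(ad)
  nr <- spec$nRandom
  n <- nchar(seqs)
  out <- rep(NA_character_, length(seqs))
  ## fast path: exact adaptor at the very end (the designed layout)
  end_hit <- !is.na(seqs) & n >= w + nr + 1L &
    substr(seqs, n - w + 1L, n) == ad
  out[end_hit] <- substr(seqs[end_hit], 1L, (n - w - nr)[end_hit])
  todo <- which(!end_hit & !is.na(seqs))
  if (length(todo) > 0L) {
    adv <- utf8ToInt(ad)
    for (i in todo) {
      s <- seqs[i]; v <- utf8ToInt(s)
      L <- length(v)
      if (L < w + nr + 1L) next
      for (start in seq(from = L - w + 1L, to = nr + 2L)) {
        mm <- sum(v[start:(start + w - 1L)] != adv)
        if (mm <= maxMismatches) {
          out[i] <- substr(s, 1L, start - nr - 1L)
          break
        }
      }
    }
  }
  out
}

## Count mismatches between equal-length string pairs, vectorized over pairs.
.mismatch_count <- function(a, b) {
  mapply(function(x, y) {
    if (is.na(x) || is.na(y) || nchar(x) != nchar(y)) return(NA_integer_)
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

#' Demultiplex trimmed reads to library constructs
#'
#' A read's barcode is the terminal \code{barcodeLength} bases of its
#' adaptor-trimmed payload (the barcode sits at the reporter N-terminus,
#' downstream of the constant context). Barcodes are matched exactly against
#' the library index; an optional Hamming-1 rescue is available when the
#' library's pairwise barcode distance is at least 3.
#'
#' For RNA reads the payload 5' end is the inferred mRNA 5' end: after
#' removing context and barcode, the remaining segment is aligned to the
#' construct's regulatory sequence by suffix match and its length gives the
#' transcription start position \code{five_prime_pos} (bp upstream of ATG,
#' negative). Reads whose segment mismatches the reference suffix in more
#' than one base fail QC (\code{pass_qc = FALSE}): they are excluded from
#' TSS pileups but still counted for abundance under barcode-based counting.
#'
#' @param payloads character vector of adaptor-trimmed read payloads
#'   (\code{NA} entries, e.g. adaptor-trim rejects, are passed through as
#'   rejects).
#' @param lib a \linkS4class{ReporterLibrary}.
#' @param kind \code{"DNA"} or \code{"RNA"}.
#' @param replicate replicate label.
#' @param sample sample label.
#' @param hamming1Rescue rescue unmatched barcodes at Hamming distance 1
#'   (requires pairwise library barcode distance >= 3).
#' @return a \code{data.table} with one row per input read: columns
#'   \code{construct_id} (\code{"UNASSIGNED"} for unknown barcodes, \code{NA}
#'   for rejects), \code{kind}, \code{sample}, \code{replicate},
#'   \code{five_prime_pos} (RNA only), \code{pass_qc}. The QC tally
#'   (assigned / unassigned / rejected / total) is attached as attribute
#'   \code{"qc"}.
#' @export
assignReads <- function(payloads, lib, kind = c("DNA", "RNA"),
                        replicate = "rep1", sample = "s1",
                        hamming1Rescue = FALSE) {
  kind <- match.arg(kind)
  bidx <- barcodeIndex(lib)
  df <- lib@constructs
  bc_len <- if (nrow(df) > 0L) nchar(df$barcode[1L]) else 0L
  ctx_len <- stats::setNames(nchar(df$reporter_context), df$construct_id)
  reg <- stats::setNames(df$reg_seq, df$construct_id)
  ctx <- stats::setNames(df$reporter_context, df$construct_id)
  Lvec <- stats::setNames(nchar(df$reg_seq), df$construct_id)

  n <- length(payloads)
  plen <- nchar(payloads)
  rejected <- is.na(payloads) | plen < bc_len
  bc <- rep(NA_character_, n)
  ok <- !rejected
  bc[ok] <- substr(payloads[ok], plen[ok] - bc_len + 1L, plen[ok])
  cid <- rep(NA_character_, n)
  cid[ok] <- unname(bidx[bc[ok]])

  if (hamming1Rescue) {
    if (barcodeMinHamming(lib) < 3L)
      stop("Hamming-1 rescue requires pairwise barcode distance >= 3",
           call. = FALSE)
    miss <- which(ok & is.na(cid))
    for (i in miss) {
      v <- utf8ToInt(bc[i])
      hit <- NA_character_
      for (p in seq_along(v)) for (b in utf8ToInt(paste(DNA_BASES, collapse = ""))) {
        if (b == v[p]) next
        vv <- v; vv[p] <- b
        cand <- bidx[intToUtf8(vv)]
        if (!is.na(cand)) { hit <- unname(cand); break }
      }
      cid[i] <- hit
    }
  }
  unassigned <- ok & is.na(cid)
  cid[unassigned] <- "UNASSIGNED"

  five_prime <- rep(NA_integer_, n)
  pass_qc <- !rejected & cid != "UNASSIGNED"
  if (kind == "RNA") {
    hit <- which(pass_qc)
    if (length(hit) > 0L) {
      h_cid <- cid[hit]
      tail_len <- bc_len + unname(ctx_len[h_cid])
      seg_len <- plen[hit] - tail_len
      L <- unname(Lvec[h_cid])
      good_geom <- seg_len >= 1L & seg_len <= L
      seg <- substr(payloads[hit], 1L, pmax(seg_len, 0L))
      ref_suffix <- substr(unname(reg[h_cid]),
                           pmax(L - seg_len + 1L, 1L), L)
      ctx_obs <- substr(payloads[hit], pmax(seg_len, 0L) + 1L,
                        pmax(seg_len, 0L) + unname(ctx_len[h_cid]))
      exact <- good_geom & seg == ref_suffix & ctx_obs == unname(ctx[h_cid])
      qc <- exact
      near <- which(good_geom & !exact)
      if (length(near) > 0L)
        qc[near] <- .mismatch_count(seg[near], ref_suffix[near]) <= 1L &
          ctx_obs[near] == unname(ctx[h_cid])[near]
      qc[!good_geom] <- FALSE
      pass_qc[hit] <- qc
      five_prime[hit] <- ifelse(qc, -seg_len, NA_integer_)
    }
  }

  out <- data.table::data.table(
    construct_id = cid, kind = kind, sample = sample, replicate = replicate,
    five_prime_pos = five_prime, pass_qc = pass_qc & cid != "UNASSIGNED"
  )
  qc_tally <- c(assigned = sum(cid != "UNASSIGNED", na.rm = TRUE),
                unassigned = sum(cid == "UNASSIGNED", na.rm = TRUE),
                rejected = sum(rejected),
                total = n)
  stopifnot(sum(qc_tally[c("assigned", "unassigned", "rejected")]) ==
              qc_tally["total"])
  data.table::setattr(out, "qc", qc_tally)
  ## the file-level identity survives even when no read is assigned
  data.table::setattr(out, "filekey",
                      data.frame(sample = sample, replicate = replicate,
                                 kind = kind))
  out
}

#' Minimum pairwise Hamming distance between library barcodes
#'
#' @param lib a \linkS4class{ReporterLibrary}.
#' @return the smallest pairwise distance (Inf for fewer than 2 barcodes).
#' @export
barcodeMinHamming <- function(lib) {
  bcs <- unname(barcodes(lib))
  if (length(bcs) < 2L) return(Inf)
  m <- do.call(rbind, lapply(bcs, utf8ToInt))
  best <- Inf
  for (i in seq_len(nrow(m) - 1L)) {
    d <- rowSums(m[(i + 1L):nrow(m), , drop = FALSE] !=
                   matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
    if (best == 0) break
  }
  best
}

#' Process a merged FASTQ file into demultiplexed reads
#'
#' Convenience wrapper: reads a (optionally gzipped) FASTQ of pre-merged
#' reads, trims the common adaptor with \code{\link{trimAdaptor}}, and
#' demultiplexes with \code{\link{assignReads}}.
#'
#' @param path FASTQ file of merged reads.
#' @param lib a \linkS4class{ReporterLibrary}.
#' @param spec an \code{\link{AdaptorSpec}}.
#' @inheritParams assignReads
#' @param maxMismatches substitutions allowed in the adaptor match.
#' @return as \code{\link{assignReads}}.
#' @export
processReads <- function(path, lib, spec, kind = c("DNA", "RNA"),
                         replicate = "rep1", sample = "s1",
                         maxMismatches = 0L, hamming1Rescue = FALSE) {
  kind <- match.arg(kind)
  seqs <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  payloads <- trimAdaptor(unname(seqs), spec, maxMismatches = maxMismatches)
  assignReads(payloads, lib, kind = kind, replicate = replicate,
              sample = sample, hamming1Rescue = hamming1Rescue)
}
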