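#' Build a 5'-end position pileup for one construct
#'
#' Histogram of inferred mRNA 5'-end positions (bp from ATG, negative) over
#' QC-passing RNA reads assigned to the construct.
#'
#' @param reads a \code{data.table} of processed reads (see
#'   \code{\link{assignReads}}).
#' @param constructId construct to tally.
#' @return a \code{TssPileup}: list with \code{construct_id},
#'   \code{positions} (named integer vector, names = positions) and
#'   \code{total_reads}. Zero usable reads give an empty pileup.
#' @export
buildPileup <- function(reads, constructId) {
  construct_id <- kind <- pass_qc <- five_prime_pos <- NULL
  sel <- reads[construct_id == constructId & kind == "RNA" & pass_qc &
                 !is.na(five_prime_pos)]
  counts <- integer(0)
  if (nrow(sel) > 0L) {
    tab <- table(sel$five_prime_pos)
    counts <- stats::setNames(as.integer(tab), names(tab))
    counts <- counts[order(as.integer(names(counts)))]
  }
  structure(list(construct_id = constructId, positions = counts,
                 total_reads = sum(counts)),
            class = "TssPileup")
}

## Exact weighted one-dimensional k-means over contiguous partitions,
## solved bottom-up by dynamic programming with prefix sums (the inner
## minimization is vectorized). Returns the full tables so every k up to
## kmax can be backtracked from one pass.
.dp_tables <- function(x, w, kmax) {
  n <- length(x)
  cw <- c(0, cumsum(w))
  cwx <- c(0, cumsum(w * x))
  cwx2 <- c(0, cumsum(w * x^2))
  ## weighted SSE of the contiguous block i..j (vectorized over i)
  cost <- function(is, j) {
    W <- cw[j + 1L] - cw[is]
    S <- cwx[j + 1L] - cwx[is]
    cwx2[j + 1L] - cwx2[is] - S^2 / W
  }
  D <- matrix(Inf, kmax, n)
  B <- matrix(1L, kmax, n)
  D[1L, ] <- cost(rep(1L, n), 0L + seq_len(n))
  if (kmax > 1L) {
    for (q in 2L:kmax) {
      for (j in q:n) {
        is <- q:j
        cand <- D[q - 1L, is - 1L] + cost(is, j)
        pick <- which.min(cand)          # ties -> smallest split point
        D[q, j] <- cand[pick]
        B[q, j] <- is[pick]
      }
    }
  }
  list(D = D, B = B)
}

.dp_backtrack <- function(B, k, n) {
  lab <- integer(n)
  j <- n
  for (q in seq(k, 1L)) {
    i <- if (q == 1L) 1L else B[q, j]
    lab[i:j] <- q
    j <- i - 1L
    if (j < 1L) break
  }
  lab
}

## Summarize clusters of a labelled pileup: representative = modal position
## (tie -> most upstream, i.e. most negative), count, fraction.
.summarize_clusters <- function(x, w, lab, total) {
  out <- lapply(sort(unique(lab)), function(j) {
    sel <- which(lab == j)
    cnt <- w[sel]
    best <- sel[which(cnt == max(cnt))]
    rep_pos <- min(x[best])
    data.frame(representative = rep_pos, count = sum(cnt),
               fraction = sum(cnt) / total)
  })
  do.call(rbind, out)
}

#' Cluster a TSS pileup by iterative one-dimensional clustering
#'
#' Solves weighted one-dimensional k-means (positions weighted by read
#' counts) exactly by dynamic programming over contiguous partitions,
#' starting from \code{kSeed} clusters (capped at the number of distinct
#' positions). The cluster count is then decremented, re-clustering each
#' time, while any two cluster representatives lie within \code{mergeDist}
#' bp of each other or any cluster holds less than \code{minFrac} of all
#' reads (strict: a cluster at exactly \code{minFrac} is kept), until the
#' constraints hold or k = 1. Solving each k exactly keeps the procedure
#' fully deterministic and independent of initialization. Each final
#' cluster is reported by its modal position (tie broken toward the most
#' upstream position).
#'
#' @param pileup a \code{TssPileup} from \code{\link{buildPileup}}.
#' @param kSeed initial cluster count (default 16).
#' @param mergeDist representatives this close (bp, inclusive) force a merge
#'   (default 10).
#' @param minFrac minimum read fraction per cluster (default 0.01).
#' @return data.frame with columns \code{representative}, \code{count},
#'   \code{fraction}, ordered by position; zero rows for an empty pileup.
#' @export
clusterTss <- function(pileup, kSeed = 16L, mergeDist = 10L, minFrac = 0.01) {
  x <- as.integer(names(pileup$positions))
  w <- as.numeric(pileup$positions)
  if (length(x) == 0L)
    return(data.frame(representative = integer(0), count = numeric(0),
                      fraction = numeric(0)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  total <- sum(w)
  kmax <- min(kSeed, length(x))
  tab <- .dp_tables(x, w, kmax)
  for (k in seq(from = kmax, to = 1L)) {
    lab <- .dp_backtrack(tab$B, k, length(x))
    cl <- .summarize_clusters(x, w, lab, total)
    reps <- sort(cl$representative)
    ok_dist <- length(reps) < 2L || all(diff(reps) > mergeDist)
    ok_frac <- all(cl$fraction >= minFrac)
    if (ok_dist && ok_frac) return(cl[order(cl$representative), ,
                                      drop = FALSE])
  }
  cl <- .summarize_clusters(x, w, rep(1L, length(x)), total)
  cl
}

#' Designate primary and secondary TSS calls from clusters
#'
#' The primary TSS is the representative of the unique cluster holding more
#' than \code{primaryFrac} of all 5'-end reads with more than
#' \code{primaryMinCount} reads (both strict); otherwise no primary is
#' called. Secondary TSSs are representatives of the remaining clusters
#' holding more than \code{secondaryFrac} of reads.
#'
#' @param clusters data.frame from \code{\link{clusterTss}}.
#' @param primaryFrac read-fraction threshold for the primary call
#'   (default 0.70).
#' @param primaryMinCount read-count threshold for the primary call
#'   (default 200).
#' @param secondaryFrac read-fraction threshold for secondary calls
#'   (default 0.10).
#' @return list with \code{primary} (position or NA), \code{secondaries}
#'   (integer vector), \code{primary_fraction}, \code{primary_count}.
#' @export
callTss <- function(clusters, primaryFrac = 0.70, primaryMinCount = 200L,
                    secondaryFrac = 0.10) {
  if (nrow(clusters) == 0L)
    return(list(primary = NA_integer_, secondaries = integer(0),
                primary_fraction = NA_real_, primary_count = NA_integer_))
  is_primary <- clusters$fraction > primaryFrac &
    clusters$count > primaryMinCount
  primary <- NA_integer_
  pfrac <- NA_real_; pcount <- NA_integer_
  if (sum(is_primary) == 1L) {
    primary <- as.integer(clusters$representative[is_primary])
    pfrac <- clusters$fraction[is_primary]
    pcount <- as.integer(clusters$count[is_primary])
  }
  sec <- clusters$fraction > secondaryFrac &
    clusters$representative != ifelse(is.na(primary), Inf, primary)
  list(primary = primary,
       secondaries = as.integer(sort(clusters$representative[sec])),
       primary_fraction = pfrac, primary_count = pcount)
}

#' Call transcription start sites for every library construct
#'
#' Convenience driver: builds per-construct pileups from processed RNA reads
#' and applies \code{\link{clusterTss}} and \code{\link{callTss}}.
#'
#' @param reads processed reads \code{data.table} (RNA reads with
#'   \code{pass_qc} and \code{five_prime_pos}).
#' @param lib a \linkS4class{ReporterLibrary}.
#' @inheritParams clusterTss
#' @inheritParams callTss
#' @return a \linkS4class{TssCallSet}.
#' @export
callTssAll <- function(reads, lib, kSeed = 16L, mergeDist = 10L,
                       minFrac = 0.01, primaryFrac = 0.70,
                       primaryMinCount = 200L, secondaryFrac = 0.10) {
  construct_id <- kind <- pass_qc <- five_prime_pos <- NULL
  sel <- reads[kind == "RNA" & pass_qc & !is.na(five_prime_pos) &
                 construct_id %in% constructIds(lib)]
  ids <- constructIds(lib)
  split_pos <- split(sel$five_prime_pos, sel$construct_id)
  clusters_out <- list()
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    pos <- split_pos[[id]]
    if (is.null(pos) || length(pos) == 0L) {
      rows[[i]] <- data.frame(construct_id = id, primary_tss = NA_integer_,
                              primary_fraction = NA_real_,
                              primary_count = NA_integer_,
                              total_reads = 0L, secondaries = "")
      next
    }
    tab <- table(pos)
    pile <- structure(list(
      construct_id = id,
      positions = stats::setNames(as.integer(tab), names(tab)),
      total_reads = length(pos)), class = "TssPileup")
    pile$positions <- pile$positions[order(as.integer(names(pile$positions)))]
    cl <- clusterTss(pile, kSeed = kSeed, mergeDist = mergeDist,
                     minFrac = minFrac)
    calls <- callTss(cl, primaryFrac = primaryFrac,
                     primaryMinCount = primaryMinCount,
                     secondaryFrac = secondaryFrac)
    clusters_out[[id]] <- cl
    rows[[i]] <- data.frame(
      construct_id = id, primary_tss = calls$primary,
      primary_fraction = calls$primary_fraction,
      primary_count = calls$primary_count,
      total_reads = pile$total_reads,
      secondaries = paste(calls$secondaries, collapse = ","))
  }
  calls_df <- do.call(rbind, rows)
  methods::new("TssCallSet",
               calls = S4Vectors::DataFrame(calls_df),
               clusters = clusters_out)
}

#' Fraction of primary TSS calls concordant between two call sets
#'
#' Over constructs with a primary call in both sets, the fraction whose
#' primary positions agree within \code{tolBp} bp.
#'
#' @param a,b \linkS4class{TssCallSet}s over the same library.
#' @param tolBp tolerance in bp (default 1).
#' @return list with \code{fraction} and \code{n} (shared primaries).
#' @export
tssConcordance <- function(a, b, tolBp = 1L) {
  pa <- primaryTss(a); pb <- primaryTss(b)
  shared <- intersect(names(pa)[!is.na(pa)], names(pb)[!is.na(pb)])
  if (length(shared) == 0L)
    stop("no constructs with primary calls in both sets", call. = FALSE)
  list(fraction = mean(abs(pa[shared] - pb[shared]) <= tolBp),
       n = length(shared))
}

#' Exact optimal one-dimensional weighted clustering
#'
#' Dynamic-programming solution of weighted k-means in one dimension:
#' partitions positions into k contiguous groups minimizing the total
#' weighted within-cluster sum of squares. This is the clustering engine
#' behind \code{\link{clusterTss}}, exported for direct use and for
#' cross-checking against independent implementations.
#'
#' @param x numeric positions (any order).
#' @param w positive weights.
#' @param k number of clusters.
#' @return integer cluster labels (1..k, in ascending-x order) parallel
#'   to \code{x}.
#' @export
exactCluster1D <- function(x, w, k) {
  stopifnot(length(x) == length(w), all(w > 0), k >= 1L)
  ord <- order(x)
  xs <- x[ord]; ws <- w[ord]
  n <- length(xs)
  k <- min(k, n)
  tab <- .dp_tables(xs, ws, k)
  lab <- integer(n)
  lab[ord] <- .dp_backtrack(tab$B, k, n)
  lab
}
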