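## Independent oracles used to validate the package's algorithms. These are
## deliberately different algorithms from the implementation paths they
## check (enumeration / brute force / exact DP).

## Brute-force PWM scan: score every offset explicitly from the probability
## matrix, no shared code with scorePwm's internals.
oracle_pwm_scan <- function(probs, background, seq) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(seq, "")[[1L]]
  w <- ncol(probs)
  best <- -Inf; best_off <- NA_integer_
  for (o in seq_len(length(v) - w + 1L)) {
    s <- 0
    for (j in seq_len(w)) {
      b <- match(v[o + j - 1L], bases)
      s <- s + log2(probs[b, j] / background[b])
    }
    if (s > best + 1e-12) { best <- s; best_off <- o }
  }
  list(score = unname(best), offset = best_off)
}

## Exhaustive Nussinov oracle: enumerate all nested structures recursively
## and return the maximum pair count (feasible for length <= 14).
oracle_max_pairs <- function(seq) {
  v <- strsplit(seq, "")[[1L]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    best <- rec(i, j - 1L)              # j unpaired
    for (k in i:(j - 4L)) {
      if (ok(v[k], v[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, left + rec(k + 1L, j - 1L) + 1L)
      }
    }
    best
  }
  rec(1L, length(v))
}

## Independent exact 1D weighted clustering: top-down recursion with
## memoization over (start index, clusters remaining). Written separately
## from the package's bottom-up tabulation so the two can cross-check.
oracle_cluster1d <- function(x, w, k) {
  n <- length(x)              # x must be sorted ascending
  k <- min(k, n)
  cw <- c(0, cumsum(w)); cwx <- c(0, cumsum(w * x))
  cwx2 <- c(0, cumsum(w * x^2))
  blk <- function(i, j) {     # weighted SSE of block i..j
    W <- cw[j + 1] - cw[i]; S <- cwx[j + 1] - cwx[i]
    cwx2[j + 1] - cwx2[i] - S^2 / W
  }
  memo <- new.env(parent = emptyenv())
  solve_tail <- function(i, q) {     # cluster x[i..n] into q groups
    key <- paste0(i, ".", q)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- if (q == 1L) {
      list(cost = blk(i, n), end = n)
    } else {
      best <- Inf; best_end <- i
      for (e in i:(n - q + 1L)) {
        cand <- blk(i, e) + solve_tail(e + 1L, q - 1L)$cost
        if (cand < best - 1e-12) { best <- cand; best_end <- e }
      }
      list(cost = best, end = best_end)
    }
    memo[[key]] <- res
    res
  }
  lab <- integer(n); i <- 1L
  for (q in seq(k, 1L)) {
    r <- solve_tail(i, q)
    lab[i:r$end] <- k - q + 1L
    i <- r$end + 1L
    if (i > n) break
  }
  lab
}

## TSS-calling oracle: apply the merge (<= mergeDist), prune (< minFrac) and
## primary/secondary rules on top of EXACT optimal 1D weighted clustering
## (independent top-down DP), decrementing k exactly as the algorithm does.
## Returns representatives and the primary call.
oracle_tss <- function(positions, counts, kSeed = 16L, mergeDist = 10L,
                       minFrac = 0.01, primaryFrac = 0.70,
                       primaryMinCount = 200L, secondaryFrac = 0.10) {
  total <- sum(counts)
  summarize <- function(lab) {
    do.call(rbind, lapply(sort(unique(lab)), function(g) {
      sel <- lab == g
      cnt <- counts[sel]
      best <- which(cnt == max(cnt))
      data.frame(representative = min(positions[sel][best]),
                 count = sum(cnt), fraction = sum(cnt) / total)
    }))
  }
  o <- order(positions)
  positions <- positions[o]; counts <- counts[o]
  final <- NULL
  for (k in seq(min(kSeed, length(positions)), 1L)) {
    lab <- oracle_cluster1d(positions, counts, k)
    cl <- summarize(lab)
    reps <- sort(cl$representative)
    if ((length(reps) < 2L || all(diff(reps) > mergeDist)) &&
        all(cl$fraction >= minFrac)) {
      final <- cl
      break
    }
  }
  if (is.null(final)) final <- summarize(rep(1L, length(positions)))
  is_primary <- final$fraction > primaryFrac & final$count > primaryMinCount
  primary <- if (sum(is_primary) == 1L)
    final$representative[is_primary] else NA_integer_
  sec <- final$fraction > secondaryFrac &
    final$representative != ifelse(is.na(primary), Inf, primary)
  list(clusters = final[order(final$representative), , drop = FALSE],
       primary = as.integer(primary),
       secondaries = sort(final$representative[sec]))
}

## Random pileup generator for fuzzing: a few modes with Poisson-ish spread.
fuzz_pileup <- function(max_distinct = 30L, L = 165L) {
  n_modes <- sample(1:4, 1L)
  centers <- sort(sample(seq(-L, -1L), n_modes))
  pos <- integer(0); cnt <- integer(0)
  for (c0 in centers) {
    spread <- sample(0:3, 1L)
    p <- unique(pmin(pmax(c0 + seq(-spread, spread), -L), -1L))
    w <- sample(1:500, length(p), replace = TRUE)
    pos <- c(pos, p); cnt <- c(cnt, w)
  }
  agg <- tapply(cnt, pos, sum)
  pos <- as.integer(names(agg)); cnt <- as.integer(agg)
  if (length(pos) > max_distinct) {
    keep <- sort(sample(seq_along(pos), max_distinct))
    pos <- pos[keep]; cnt <- cnt[keep]
  }
  list(positions = pos, counts = cnt)
}

## Turn a position/count pair into a TssPileup as buildPileup would.
as_pileup <- function(id, positions, counts) {
  o <- order(positions)
  structure(list(construct_id = id,
                 positions = stats::setNames(as.integer(counts[o]),
                                             positions[o]),
                 total_reads = sum(counts)),
            class = "TssPileup")
}
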