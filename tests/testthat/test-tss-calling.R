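test_that("pileups are exact histograms of QC-passing RNA 5' ends", {
  rt <- reads_table(rep("pA", 3), kind = "RNA", pos = -45L)
  p <- buildPileup(rt, "pA")
  expect_identical(p$positions, c(`-45` = 3L))
  expect_identical(p$total_reads, 3L)
  # DNA reads and QC failures are excluded; empty pileup is valid
  p0 <- buildPileup(reads_table("pA", kind = "DNA"), "pA")
  expect_identical(p0$total_reads, 0L)
  rt_bad <- reads_table("pA", kind = "RNA", pos = -45L)
  rt_bad$pass_qc <- FALSE
  expect_identical(buildPileup(rt_bad, "pA")$total_reads, 0L)
})

test_that("single-position and adjacent-position pileups cluster as the
          rules force", {
  # one position: one cluster, full fraction
  cl <- clusterTss(as_pileup("x", -45L, 300L))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$representative, -45L)
  expect_equal(cl$fraction, 1.0)
  # two positions 1 bp apart merge; the count tie breaks upstream
  cl2 <- clusterTss(as_pileup("x", c(-45L, -44L), c(150L, 150L)))
  expect_identical(nrow(cl2), 1L)
  expect_identical(cl2$representative, -45L)
})

test_that("the 1%-of-reads prune rule is strict: exactly 1% survives", {
  # 3/300 reads is exactly 1%: the minor cluster must NOT be pruned
  cl <- clusterTss(as_pileup("x", c(-60L, -20L), c(297L, 3L)))
  expect_identical(nrow(cl), 2L)
  expect_setequal(cl$representative, c(-60L, -20L))
  # just under 1% is pruned (merged away by decrementing k)
  cl2 <- clusterTss(as_pileup("x", c(-60L, -20L), c(298L, 2L)))
  expect_identical(nrow(cl2), 1L)
})

test_that("primary calls require >70% of reads AND >200 reads,
          strictly", {
  one <- data.frame(representative = -45L, count = 300, fraction = 1.0)
  expect_identical(callTss(one)$primary, -45L)
  # fraction 1.0 but only 100 reads: no primary
  low <- data.frame(representative = -45L, count = 100, fraction = 1.0)
  expect_true(is.na(callTss(low)$primary))
  # exactly 200 reads fails the strict count rule
  edge <- data.frame(representative = -45L, count = 200, fraction = 1.0)
  expect_true(is.na(callTss(edge)$primary))
  # secondary rule is strict too: 0.10 is not > 0.10
  three <- data.frame(representative = c(-60L, -40L, -20L),
                      count = c(750, 150, 100),
                      fraction = c(0.75, 0.15, 0.10))
  out <- callTss(three)
  expect_identical(out$primary, -60L)
  expect_identical(out$secondaries, -40L)
})

test_that("final clusters satisfy the call-set invariants on fuzzed
          pileups", {
  set.seed(401)
  for (i in 1:100) {
    fz <- fuzz_pileup()
    cl <- clusterTss(as_pileup("x", fz$positions, fz$counts))
    reps <- sort(cl$representative)
    if (length(reps) > 1L) expect_true(all(diff(reps) > 10L))
    expect_true(all(cl$fraction >= 0.01))
    expect_equal(sum(cl$count), sum(fz$counts))
    expect_equal(sum(cl$fraction), 1.0)
    out <- callTss(cl)
    if (!is.na(out$primary)) {
      expect_gt(out$primary_fraction, 0.70)
      expect_gt(out$primary_count, 200L)
      expect_false(out$primary %in% out$secondaries)
    }
  }
})

test_that("clustering is deterministic across repeated runs", {
  set.seed(402)
  fz <- fuzz_pileup()
  pile <- as_pileup("x", fz$positions, fz$counts)
  first <- clusterTss(pile)
  for (i in 1:5) expect_identical(clusterTss(pile), first)
})

test_that("TSS clustering matches an independent exact-clustering oracle
          with the merge/prune/call rules applied", {
  set.seed(403)
  for (i in 1:50) {
    fz <- fuzz_pileup()
    cl <- clusterTss(as_pileup("x", fz$positions, fz$counts))
    calls <- callTss(cl)
    orc <- oracle_tss(fz$positions, fz$counts)
    expect_identical(sort(cl$representative),
                     sort(orc$clusters$representative))
    expect_identical(is.na(calls$primary), is.na(orc$primary))
    if (!is.na(calls$primary))
      expect_identical(as.integer(calls$primary), orc$primary)
  }
})

test_that("library-wide TSS calling recovers planted sites and concords
          across replicates", {
  s <- small_sim()
  rna <- data.table::rbindlist(s$reads[3:4])
  calls <- callTssAll(rna, s$lib)
  pt <- primaryTss(calls)
  called <- names(pt)[!is.na(pt)]
  expect_gt(length(called), 20)
  truth_tss <- stats::setNames(s$truth$true_tss, s$truth$construct_id)
  # jitter sd 0.5: primary = truth for essentially all called constructs
  expect_gte(mean(pt[called] == truth_tss[called]), 0.95)
  # concordance between the two replicates
  per_rep <- lapply(3:4, function(i) callTssAll(s$reads[[i]], s$lib))
  cc <- tssConcordance(per_rep[[1]], per_rep[[2]], tolBp = 1L)
  expect_gte(cc$fraction, 0.90)
  # identical call sets give fraction 1; a 2-bp shift gives 0 at tol 1
  expect_equal(tssConcordance(calls, calls)$fraction, 1.0)
  shifted <- calls
  shifted@calls$primary_tss <- shifted@calls$primary_tss + 2L
  expect_equal(tssConcordance(calls, shifted, tolBp = 1L)$fraction, 0.0)
})

test_that("exact DP clustering minimizes weighted within-cluster SSE", {
  # brute-force check on tiny inputs: enumerate all contiguous partitions
  set.seed(404)
  wss <- function(x, w, lab) {
    sum(vapply(unique(lab), function(g) {
      sel <- lab == g
      mu <- sum(x[sel] * w[sel]) / sum(w[sel])
      sum(w[sel] * (x[sel] - mu)^2)
    }, 0))
  }
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- sort(sample(-80:-1, n))
    w <- sample(1:50, n, replace = TRUE)
    for (k in 2:min(3, n)) {
      lab <- exactCluster1D(x, w, k)
      best <- wss(x, w, lab)
      # enumerate all ways to place k-1 boundaries
      combos <- utils::combn(n - 1L, k - 1L)
      for (j in seq_len(ncol(combos))) {
        bnd <- combos[, j]
        lab2 <- findInterval(seq_len(n), c(1L, bnd + 1L))
        expect_gte(wss(x, w, lab2), best - 1e-9)
      }
    }
  }
})
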