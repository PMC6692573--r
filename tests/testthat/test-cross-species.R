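## Simulated profile matrix: two species blocks sharing a configurable
## fraction of activity variance.
sim_profiles <- function(n = 500, shared = 0.5, n_a = 3, n_b = 3,
                         seed = 1) {
  set.seed(seed)
  common <- rnorm(n)
  mk <- function(group_noise) {
    scale(sqrt(shared) * common +
            sqrt(1 - shared) * rnorm(n) * group_noise)[, 1]
  }
  m <- cbind(
    sapply(seq_len(n_a), function(i) mk(1)),
    sapply(seq_len(n_b), function(i) mk(1))
  )
  colnames(m) <- c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b)))
  rownames(m) <- sprintf("c%04d", seq_len(n))
  m
}

test_that("profile rows are the constructs active in every sample", {
  s <- small_sim()
  act <- computeActivity(s$counts)
  m <- profileMatrix(act)
  z <- SummarizedExperiment::assay(act, "txZ")
  expect_identical(rownames(m), rownames(z)[stats::complete.cases(z)])
  expect_false(anyNA(m))
})

test_that("pairwise correlations behave at the extremes and stay PSD", {
  set.seed(801)
  base <- matrix(rnorm(300), 100, 3,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  m <- cbind(base, s1dup = base[, "s1"], s1neg = -base[, "s1"])
  r <- pairwiseCorrelation(m)
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(r["s1", "s1dup"], 1)
  expect_equal(r["s1", "s1neg"], -1)
  expect_identical(r, t(r))
  expect_gte(min(eigen(r, symmetric = TRUE)$values), -1e-8)
  # constant columns are refused by name
  bad <- cbind(base, flat = rep(1, 100))
  expect_error(pairwiseCorrelation(bad), "flat")
})

test_that("two species sharing half their activity variance correlate
          near sqrt(0.5)", {
  rs <- vapply(1:20, function(i) {
    m <- sim_profiles(n = 2000, shared = 0.5, n_a = 1, n_b = 1, seed = i)
    pairwiseCorrelation(m)[1, 2]
  }, 0)
  expect_lt(abs(mean(rs) - 0.5), 0.05)  # r ~ shared variance here
})

test_that("PCA is complete, orthogonal, and deterministic in sign", {
  m <- sim_profiles(n = 300, seed = 5)
  p <- pcaProfiles(m)
  expect_equal(sum(p$varianceExplained), 1, tolerance = 1e-9)
  # scores reproduce pairwise distances of the centered data
  ctr <- scale(t(m), center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(p$scores)), as.matrix(dist(ctr)),
               tolerance = 1e-8)
  # identical samples project to the same point
  m2 <- cbind(m, A1copy = m[, "A1"])
  p2 <- pcaProfiles(m2)
  expect_equal(p2$scores["A1", ], p2$scores["A1copy", ], tolerance = 1e-8)
  expect_error(pcaProfiles(m, nComponents = 100), "nComponents")
})

test_that("hierarchical clustering joins the identical pair first and
          is ultrametric on 3 leaves", {
  set.seed(802)
  v <- rnorm(200)
  m <- cbind(x = v, y = v + rnorm(200, 0, 0.01), z = -v)
  hc <- hierarchicalCluster(m)$hclust
  # first merge must be the near-identical pair {x, y}
  expect_setequal(hc$labels[-hc$merge[1, ]], c("x", "y"))
  # ultrametricity on 3 leaves: both cross-pair cophenetic distances equal
  coph <- as.matrix(stats::cophenetic(hc))
  expect_equal(coph["x", "z"], coph["y", "z"], tolerance = 1e-12)
  # and the joint height matches the average of the two correlations
  r <- pairwiseCorrelation(m)
  expect_equal(coph["x", "z"],
               mean(c(1 - r["x", "z"], 1 - r["y", "z"])),
               tolerance = 1e-12)
  nw <- hierarchicalCluster(m)$newick
  expect_match(nw, "^\\(")
  tree <- ape::read.tree(text = nw)
  expect_setequal(tree$tip.label, c("x", "y", "z"))
})

test_that("a planted two-block design is recovered exactly (Rand index
          1)", {
  m <- sim_profiles(n = 1000, shared = 0.1, n_a = 4, n_b = 4, seed = 9)
  # make the two blocks internally coherent and mutually distinct
  set.seed(10)
  blockA <- rnorm(1000); blockB <- rnorm(1000)
  for (i in 1:4) m[, i] <- scale(blockA + rnorm(1000, 0, 0.3))[, 1]
  for (i in 5:8) m[, i] <- scale(blockB + rnorm(1000, 0, 0.3))[, 1]
  hc <- hierarchicalCluster(m)$hclust
  cut <- stats::cutree(hc, k = 2)
  truth <- rep(1:2, each = 4)
  # Rand index against the planted partition
  pairs <- utils::combn(8, 2)
  same_cut <- cut[pairs[1, ]] == cut[pairs[2, ]]
  same_truth <- truth[pairs[1, ]] == truth[pairs[2, ]]
  rand <- mean(same_cut == same_truth)
  expect_equal(rand, 1.0)
})

test_that("species selectivity uses a strict 10-fold rule on the raw
          ratio scale", {
  mk_act <- function(txA, txB) {
    tx <- cbind(s1 = txA, s2 = txB)
    rownames(tx) <- paste0("c", seq_along(txA))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(txRaw = tx, txLog10 = log10(tx), txZ = tx * 0,
                    passFilter = tx > -1, inactive = tx == 0,
                    dnaCount = tx * 0 + 100, rnaCount = tx),
      colData = S4Vectors::DataFrame(sample = c("s1", "s2"),
                                     row.names = c("s1", "s2")))
    methods::new("ActivitySet", se)
  }
  act <- mk_act(c(100, 100, 5), c(5, 10, 100))
  sel <- speciesSelective(act, fold = 10)
  expect_identical(sel$s1, "c1")      # 100/5 = 20 > 10
  # c2: 100/10 = 10 exactly -> NOT selective (strict >)
  expect_false("c2" %in% sel$s1)
  expect_identical(sel$s2, "c3")
})

test_that("hybrid profiles correlate monotonically with the majority
          species", {
  set.seed(803)
  n <- 1000
  a <- rnorm(n); b <- rnorm(n)
  weights <- c(0.2, 0.5, 0.8)
  r_with_a <- vapply(weights, function(wgt) {
    hybrid <- wgt * a + (1 - wgt) * b + rnorm(n, 0, 0.1)
    cor(hybrid, a)
  }, 0)
  expect_true(all(diff(r_with_a) > 0))
})

test_that("identical pools show zero depletion and planted losses are
          flagged with their motif", {
  set.seed(804)
  n <- 400
  seqs <- rand_dna(n, 80, gc = 0.45)
  names(seqs) <- sprintf("c%04d", 1:n)
  carries <- grepl("CC[ACGT]GG", seqs)
  expect_gt(sum(carries), 20)
  abund <- rep(1 / n, n)
  din <- as.integer(rmultinom(1, 3e5, abund))
  names(din) <- names(seqs)
  # identical pools: nothing depleted
  d0 <- detectDepletion(din, din, seqs)
  expect_identical(sum(d0$perConstruct$depleted), 0L)
  # output pool with motif carriers cut 20x
  w <- abund; w[carries] <- w[carries] / 20
  dout <- as.integer(rmultinom(1, 3e5, w / sum(w)))
  names(dout) <- names(seqs)
  rep <- detectDepletion(din, dout, seqs)
  flagged <- rep$perConstruct$depleted
  expect_gte(sum(flagged & carries) / sum(carries), 0.95)
  expect_identical(rep$enrichedKmers$kmer[1], "CCNGG")
})

test_that("depletion control of false positives respects alpha", {
  set.seed(805)
  n <- 300
  fp <- vapply(1:60, function(i) {
    abund <- rgamma(n, 10); abund <- abund / sum(abund)
    din <- as.integer(rmultinom(1, 1e5, abund))
    dout <- as.integer(rmultinom(1, 1e5, abund))
    names(din) <- names(dout) <- sprintf("c%03d", 1:n)
    mean(detectDepletion(din, dout)$perConstruct$depleted)
  }, 0)
  expect_lte(mean(fp), 0.05)
})

test_that("depletion q-values are monotone with their p-values", {
  set.seed(806)
  n <- 100
  abund <- rgamma(n, 5); abund <- abund / sum(abund)
  din <- as.integer(rmultinom(1, 5e4, abund))
  w <- abund; w[1:20] <- w[1:20] / 10
  dout <- as.integer(rmultinom(1, 5e4, w / sum(w)))
  names(din) <- names(dout) <- sprintf("c%03d", 1:n)
  pc <- detectDepletion(din, dout)$perConstruct
  o <- order(pc$p)
  expect_true(all(diff(pc$q[o]) >= -1e-12))
})
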