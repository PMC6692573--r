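test_that("counts tabulate per cell with a complete construct row set", {
  lib <- tiny_library()
  rt <- reads_table(c("pA", "pA", "pA", "pB"), kind = "DNA")
  ct <- tabulateCounts(rt, lib)
  m <- SummarizedExperiment::assay(ct)
  expect_identical(nrow(m), 3L)
  expect_identical(unname(m["pA", 1]), 3L)
  expect_identical(unname(m["pB", 1]), 1L)
  expect_identical(unname(m["pC", 1]), 0L)
  # empty stream still yields the full row set
  empty <- reads_table(character(0), kind = "DNA")
  ct0 <- tabulateCounts(empty, lib)
  expect_identical(dim(SummarizedExperiment::assay(ct0)), c(3L, 1L))
  expect_true(all(SummarizedExperiment::assay(ct0) == 0L))
})

test_that("duplicate (sample, replicate, kind) inputs are rejected", {
  lib <- tiny_library()
  rt <- reads_table("pA", kind = "DNA")
  expect_error(tabulateCounts(list(rt, rt), lib), "duplicate")
})

test_that("simulator truth counts equal the tabulated counts exactly", {
  s <- small_sim()
  m <- SummarizedExperiment::assay(s$counts)
  cd <- SummarizedExperiment::colData(s$counts)
  for (r in 1:2) {
    dcol <- which(cd$kind == "DNA" & cd$replicate == paste0("rep", r))
    rcol <- which(cd$kind == "RNA" & cd$replicate == paste0("rep", r))
    expect_identical(unname(m[, dcol]),
                     unname(s$sim$dnaCounts[rownames(m), r]))
    expect_identical(unname(m[, rcol]),
                     unname(s$sim$rnaCounts[rownames(m), r]))
  }
})

## hand-built count table: one sample, two replicates per kind
toy_counts <- function(dna, rna, lib = NULL) {
  ids <- names(dna)
  if (is.null(lib))
    lib <- ReporterLibrary(ids, rand_dna(length(ids), 30),
                           vapply(seq_along(ids), function(i)
                             paste(rep(c("A", "C", "G", "T")[
                               (i %/% c(16, 4, 1)) %% 4 + 1], 2),
                               collapse = ""), ""))
  rt <- list(
    reads_table(rep(ids, dna), kind = "DNA", replicate = "rep1"),
    reads_table(rep(ids, rna), kind = "RNA", replicate = "rep1",
                pos = -10L)
  )
  tabulateCounts(rt, lib)
}

test_that("the two-construct activity ratio and Z-scores are exact", {
  ct <- toy_counts(dna = c(A = 10L, B = 10L), rna = c(A = 100L, B = 10L))
  act <- computeActivity(ct, dnaMinReads = 10L)
  tx <- SummarizedExperiment::assay(act, "txRaw")[, 1]
  # rel_RNA/rel_DNA: A = (100/110)/(10/20), B = (10/110)/(10/20)
  expect_equal(unname(tx["A"] / tx["B"]), 10)
  z <- SummarizedExperiment::assay(act, "txZ")[, 1]
  expect_equal(unname(z["A"]), 1)   # two-point population Z is forced +-1
  expect_equal(unname(z["B"]), -1)
})

test_that("the 15-DNA-read abundance cutoff is strict", {
  ct <- toy_counts(dna = c(A = 14L, B = 200L, C = 15L),
                   rna = c(A = 50L, B = 50L, C = 50L))
  act <- computeActivity(ct, dnaMinReads = 15L)
  pass <- SummarizedExperiment::assay(act, "passFilter")[, 1]
  expect_false(unname(pass["A"]))   # 14 < 15
  expect_true(unname(pass["C"]))    # 15 >= 15
  expect_true(is.na(SummarizedExperiment::assay(act, "txLog10")["A", 1]))
})

test_that("Z-scores have mean 0 and population SD 1 over passing
          constructs", {
  s <- small_sim()
  act <- computeActivity(s$counts)
  z <- SummarizedExperiment::assay(act, "txZ")[, 1]
  z <- z[!is.na(z)]
  expect_gt(length(z), 50)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
})

test_that("activity Z-scores are invariant to count rescaling", {
  s <- small_sim()
  m <- SummarizedExperiment::assay(s$counts)
  cd <- SummarizedExperiment::colData(s$counts)
  m2 <- m
  m2[, cd$kind == "RNA"] <- m2[, cd$kind == "RNA"] * 7L
  ct2 <- methods::new("ReporterCounts",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = m2), colData = cd))
  z1 <- SummarizedExperiment::assay(computeActivity(s$counts), "txZ")
  z2 <- SummarizedExperiment::assay(computeActivity(ct2), "txZ")
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("dropping sub-cutoff constructs preserves the activity ranking
          of the rest", {
  s <- small_sim()
  act <- computeActivity(s$counts, dnaMinReads = 15L)
  tx_all <- SummarizedExperiment::assay(
    computeActivity(s$counts, dnaMinReads = 0L), "txRaw")[, 1]
  tx <- SummarizedExperiment::assay(act, "txRaw")[, 1]
  pass <- SummarizedExperiment::assay(act, "passFilter")[, 1]
  keep <- names(tx)[pass & !is.na(tx)]
  expect_identical(order(tx[keep]), order(tx_all[keep]))
})

test_that("zero-RNA constructs are inactive, not fabricated", {
  ct <- toy_counts(dna = c(A = 100L, B = 100L, C = 100L),
                   rna = c(A = 90L, B = 0L, C = 10L))
  act <- computeActivity(ct, dnaMinReads = 15L)
  expect_true(SummarizedExperiment::assay(act, "inactive")["B", 1])
  expect_true(is.na(SummarizedExperiment::assay(act, "txLog10")["B", 1]))
  # with a pseudocount, B gets a finite activity instead
  act2 <- computeActivity(ct, dnaMinReads = 15L, pseudocount = 0.5)
  expect_false(is.na(SummarizedExperiment::assay(act2, "txLog10")["B", 1]))
})

test_that("all-zero DNA is an error", {
  ct <- toy_counts(dna = c(A = 0L, B = 0L), rna = c(A = 5L, B = 5L))
  expect_error(computeActivity(ct), "all-zero DNA")
})

test_that("replicate concordance is 1 against itself and -1 against a
          negation", {
  s <- small_sim()
  act <- computeActivity(s$counts)
  cc <- replicateConcordance(act, act)
  expect_equal(cc$r, 1)
  neg <- act
  SummarizedExperiment::assay(neg, "txLog10") <-
    -SummarizedExperiment::assay(act, "txLog10")
  cc2 <- replicateConcordance(act, neg)
  expect_equal(cc2$r, -1)
})

test_that("independent replicates of the same sample concord at depth", {
  s <- small_sim()
  m <- SummarizedExperiment::assay(s$counts)
  cd <- SummarizedExperiment::colData(s$counts)
  split_act <- lapply(1:2, function(r) {
    sel <- cd$replicate == paste0("rep", r)
    ct <- methods::new("ReporterCounts",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m[, sel, drop = FALSE]),
        colData = cd[sel, ]))
    computeActivity(ct)
  })
  cc <- replicateConcordance(split_act[[1]], split_act[[2]])
  expect_gte(cc$r, 0.95)
  expect_gt(cc$n, 50)
})
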