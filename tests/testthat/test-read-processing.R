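test_that("pair merging finds exact overlaps and rejects ambiguity", {
  # r2 is given in sequencing orientation (reverse complement of the
  # fragment's right end)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(mergePairs("AAAATTTT", rc("TTTTGGGG"), minOverlap = 4),
                   "AAAATTTTGGGG")
  # identical coverage: merge returns the read itself
  r <- "ACGGTTCAGGTCCA"
  expect_identical(mergePairs(r, rc(r), minOverlap = 4), r)
  # no acceptable overlap
  expect_identical(mergePairs("AAAAAAAA", rc("GGGGGGGG"), minOverlap = 4),
                   NA_character_)
})

test_that("random fragments are reconstructed from error-free pairs", {
  set.seed(301)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  n_ok <- 0L
  for (i in 1:500) {
    frag <- rand_dna(1, 60)
    r1 <- substr(frag, 1, 40)
    r2 <- rc(substr(frag, 21, 60))   # 20 nt overlap
    out <- mergePairs(r1, r2, minOverlap = 15)
    if (identical(out, frag)) n_ok <- n_ok + 1L
  }
  # the fragment is the oracle; rare ambiguous overlaps may reject
  expect_gte(n_ok, 495L)
})

test_that("quality strings resolve overlap disagreements", {
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  frag <- "ACGGTTCAGGTCCAAGGTCA"
  r1 <- substr(frag, 1, 14)
  r1_err <- paste0(substr(r1, 1, 13), "G")  # error at last base (A -> G)
  r2 <- rc(substr(frag, 7, 20))
  q_low <- rep(2L, 14); q_high <- rep(40L, 14)
  out <- mergePairs(r1_err, r2, minOverlap = 6, maxMismatchFrac = 0.2,
                    q1 = q_low, q2 = q_high)
  expect_identical(out, frag)
})

test_that("adaptor trimming removes adaptor plus random bases", {
  spec <- AdaptorSpec("AGATCGGAAGAGC", 2L)
  payload <- "ACGTACGTACGTACGT"
  expect_identical(trimAdaptor(paste0(payload, "CT", spec$adaptorSeq), spec),
                   payload)
  # no adaptor -> reject
  expect_identical(trimAdaptor(paste0(payload, "CTAAAAAAAAAAAAA"), spec),
                   NA_character_)
  # too short -> reject
  expect_identical(trimAdaptor("ACGT", spec), NA_character_)
})

test_that("mismatched adaptors are found by scanning, matching a Hamming
          oracle", {
  set.seed(302)
  spec <- AdaptorSpec("AGATCGGAAGAGC", 2L)
  for (i in 1:50) {
    payload <- rand_dna(1, 30)
    ad <- spec$adaptorSeq
    p <- sample(nchar(ad), 1)
    substr(ad, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(ad, p, p))[1L]
    read <- paste0(payload, "GG", ad)
    expect_identical(trimAdaptor(read, spec, maxMismatches = 0L),
                     NA_character_)
    # oracle: scan every offset counting mismatches against the adaptor
    v <- utf8ToInt(read); a <- utf8ToInt(spec$adaptorSeq)
    offs <- which(vapply(seq_len(length(v) - length(a) + 1L), function(o) {
      sum(v[o:(o + length(a) - 1L)] != a) <= 1L
    }, TRUE))
    expect_identical(max(offs), nchar(payload) + 3L)
    expect_identical(trimAdaptor(read, spec, maxMismatches = 1L), payload)
  }
})

test_that("reads demultiplex by barcode with 5'-position recovery", {
  lib <- tiny_library()
  # an RNA read whose 5' segment is the last 45 nt of pA's regulatory
  # sequence maps to position -45
  read <- render_rna_read(lib, "pA", -45L)
  out <- assignReads(read, lib, kind = "RNA")
  expect_identical(out$construct_id, "pA")
  expect_identical(out$five_prime_pos, -45L)
  expect_true(out$pass_qc)
  # unknown barcode -> UNASSIGNED
  bad <- paste0(substr(read, 1, nchar(read) - 8), "TTTTTTTA")
  out2 <- assignReads(bad, lib, kind = "RNA")
  expect_identical(out2$construct_id, "UNASSIGNED")
  expect_false(out2$pass_qc)
  # DNA reads never carry a 5' position
  out3 <- assignReads(read, lib, kind = "DNA")
  expect_true(is.na(out3$five_prime_pos))
})

test_that("a corrupt regulatory segment fails QC but keeps its barcode", {
  lib <- tiny_library()
  read <- render_rna_read(lib, "pA", -20L)
  # two mismatches in the segment: beyond the 1-mismatch tolerance
  v <- strsplit(read, "")[[1L]]
  v[1:2] <- ifelse(v[1:2] == "A", "C", "A")
  out <- assignReads(paste(v, collapse = ""), lib, kind = "RNA")
  expect_identical(out$construct_id, "pA")
  expect_false(out$pass_qc)
  expect_true(is.na(out$five_prime_pos))
})

test_that("read accounting is conserved: assigned + unassigned + rejected
          = total", {
  s <- small_sim()
  for (rt in s$reads) {
    qc <- attr(rt, "qc")
    expect_identical(unname(qc["assigned"] + qc["unassigned"] +
                              qc["rejected"]),
                     unname(qc["total"]))
  }
})

test_that("error-free simulated reads assign perfectly with exact 5'
          positions", {
  s <- small_sim()
  rna <- s$reads[[3]]
  qc <- attr(rna, "qc")
  expect_identical(unname(qc["unassigned"]), 0L)
  expect_identical(unname(qc["rejected"]), 0L)
  expect_true(all(rna$pass_qc))
  # per-read truth: the simulator's per-position tallies match exactly
  got <- rna[, .N, by = c("construct_id", "five_prime_pos")]
  truth <- s$sim$rnaTss[replicate == "rep1"]
  m <- merge(got, truth[, .(construct_id, five_prime_pos, count)],
             by = c("construct_id", "five_prime_pos"), all = TRUE)
  expect_true(all(!is.na(m$N)) && all(!is.na(m$count)))
  expect_identical(m$N, m$count)
})

test_that("Hamming-1 rescue requires separation and then recovers
          mutated barcodes", {
  lib <- tiny_library()   # pairwise barcode Hamming >= 3 by construction
  expect_gte(barcodeMinHamming(lib), 3)
  read <- render_rna_read(lib, "pB", -30L)
  v <- strsplit(read, "")[[1L]]
  v[length(v)] <- "A"   # mutate last barcode base (T -> A)
  mutated <- paste(v, collapse = "")
  expect_identical(assignReads(mutated, lib, kind = "RNA")$construct_id,
                   "UNASSIGNED")
  out <- assignReads(mutated, lib, kind = "RNA", hamming1Rescue = TRUE)
  expect_identical(out$construct_id, "pB")
})
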