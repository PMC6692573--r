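## Shared fixtures, built in code at test time.

## A tiny hand-checkable library.
tiny_library <- function() {
  ReporterLibrary(
    construct_id = c("pA", "pB", "pC"),
    reg_seq = c(
      "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
      "TTGACAGGCTAGCTAGGCTAGCTATAATGCGCACGTACGTACGTACGT",
      "GGGGCCCCGGGGCCCCGGGGCCCCGGGGCCCCGGGGCCCCGGGGCCCC"
    ),
    barcode = c("AAAACCCC", "GGGGTTTT", "ACGTACGT"),
    reporter_context = "TAAGGA",
    name = "tiny"
  )
}

## Random DNA string(s).
rand_dna <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  }, "")
}

## Render an RNA read for a given construct: reg_seq suffix from `pos`
## (negative) + context + barcode [+ random bases + adaptor].
render_rna_read <- function(lib, id, pos, adaptor = NULL) {
  df <- lib@constructs
  i <- match(id, df$construct_id)
  L <- nchar(df$reg_seq[i])
  payload <- paste0(substr(df$reg_seq[i], L + pos + 1L, L),
                    df$reporter_context[i], df$barcode[i])
  if (is.null(adaptor)) return(payload)
  paste0(payload,
         paste(sample(c("A", "C", "G", "T"), adaptor$nRandom, TRUE),
               collapse = ""),
         adaptor$adaptorSeq)
}

## Build a processed-read data.table directly (bypassing FASTQ IO) from a
## vector of construct ids and, for RNA, 5'-end positions.
reads_table <- function(ids, kind = "DNA", pos = NA_integer_,
                        replicate = "rep1", sample = "s1") {
  out <- data.table::data.table(
    construct_id = ids, kind = kind, sample = sample, replicate = replicate,
    five_prime_pos = as.integer(pos), pass_qc = TRUE
  )
  data.table::setattr(out, "filekey",
                      data.frame(sample = sample, replicate = replicate,
                                 kind = kind))
  out
}

## A small simulated dataset shared by several tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gl <- generateLibrary(150, seed = 42, motifPlantFrac = 0.6)
      truth <- assignTruth(gl$library, gl$truth,
                           beta = c(0.6, 0.9, 0.1, 0.3, -0.2, 0.2,
                                    0.15, -0.8),
                           sigma = 0.2, seed = 43)
      dir <- file.path(tempdir(), "txtlseq-small-sim")
      sim <- simulateReads(gl$library, truth, depthDna = 2e5,
                           depthRna = 2e5, dir = dir, seed = 44)
      spec <- AdaptorSpec("AGATCGGAAGAGC", 2L)
      reads <- c(
        lapply(1:2, function(r)
          processReads(sim$dnaFiles[r], gl$library, spec, kind = "DNA",
                       replicate = paste0("rep", r))),
        lapply(1:2, function(r)
          processReads(sim$rnaFiles[r], gl$library, spec, kind = "RNA",
                       replicate = paste0("rep", r))))
      cache <<- list(lib = gl$library, truth = truth, sim = sim,
                     reads = reads,
                     counts = tabulateCounts(reads, gl$library))
    }
    cache
  }
})
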