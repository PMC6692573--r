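#' Generate a synthetic designed reporter library with planted promoters
#'
#' Draws random regulatory sequences at a target GC content and plants a
#' sigma70-style promoter in a configurable fraction of constructs: a
#' TTGACA-like -35 and TATAAT-like -10 hexamer separated by a spacer drawn
#' from 15-19 bp, with the transcription start site 7 bp downstream of the
#' -10 start. Each planted element copies the consensus base with a
#' per-construct strength probability (the rest are random), so planted
#' promoters span a range of motif strengths. Every construct (planted or
#' not) is assigned a ground-truth TSS. Barcodes are generated with
#' pairwise Hamming distance at least 3.
#'
#' @param n number of constructs.
#' @param regLen regulatory sequence length (default 165 nt).
#' @param barcodeLen barcode length (default 12 nt).
#' @param motifPlantFrac fraction of constructs receiving a planted promoter
#'   (default 0.5).
#' @param gc GC content of the random background (default 0.5).
#' @param reporterContext constant context joining the regulatory sequence
#'   to the reporter (default a 10-nt RBS-like spacer).
#' @param tssRange range (negative positions) the truth TSS is drawn from.
#' @param strengthRange per-construct consensus-copy probability range for
#'   planted elements.
#' @param seed RNG seed; output is identical across runs for a fixed seed.
#' @return list with \code{library} (a \linkS4class{ReporterLibrary}) and
#'   \code{truth} (data.frame: construct_id, true_tss, planted, strength,
#'   spacer, minus10_start, minus35_start in ATG coordinates).
#' @export
generateLibrary <- function(n, regLen = 165L, barcodeLen = 12L,
                            motifPlantFrac = 0.5, gc = 0.5,
                            reporterContext = "TAAGGAGGTT",
                            tssRange = c(-70L, -55L),
                            strengthRange = c(0.6, 1),
                            seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rand_seq <- function(len, m) {
    matrix(sample(DNA_BASES, len * m, replace = TRUE, prob = base_probs),
           nrow = m)
  }
  ## barcodes: greedy accept at pairwise Hamming >= 3
  if (4^barcodeLen < n * 10)
    stop("barcode space too small for n constructs", call. = FALSE)
  acc <- matrix(0L, 0L, barcodeLen)
  tries <- 0L
  while (nrow(acc) < n) {
    tries <- tries + 1L
    if (tries > n * 200L) stop("barcode space exhausted", call. = FALSE)
    cand <- sample.int(4L, barcodeLen, replace = TRUE)
    if (nrow(acc) == 0L ||
        min(rowSums(acc != matrix(cand, nrow(acc), barcodeLen,
                                  byrow = TRUE))) >= 3L)
      acc <- rbind(acc, cand)
  }
  bcs <- apply(acc, 1L, function(r) paste(DNA_BASES[r], collapse = ""))

  seq_mat <- rand_seq(regLen, n)
  tss <- sample(seq(tssRange[1L], tssRange[2L]), n, replace = TRUE)
  planted <- stats::runif(n) < motifPlantFrac
  strength <- stats::runif(n, strengthRange[1L], strengthRange[2L])
  spacer <- sample(15:19, n, replace = TRUE)
  m10_start <- tss - 7L                      # TSS sits 7 bp downstream
  m35_start <- m10_start - spacer - 6L
  plant <- function(row, consensus, start_pos, s) {
    idx <- .pos_to_idx(start_pos, regLen)
    bases <- strsplit(consensus, "")[[1L]]
    for (j in seq_along(bases)) {
      if (stats::runif(1) < s) row[idx + j - 1L] <- bases[j]
    }
    row
  }
  for (i in which(planted)) {
    seq_mat[i, ] <- plant(seq_mat[i, ], "TTGACA", m35_start[i], strength[i])
    seq_mat[i, ] <- plant(seq_mat[i, ], "TATAAT", m10_start[i], strength[i])
  }
  seqs <- apply(seq_mat, 1L, paste, collapse = "")
  ids <- sprintf("c%04d", seq_len(n))
  lib <- ReporterLibrary(ids, seqs, bcs, reporterContext,
                         name = sprintf("sim_n%d_seed%d", n, seed))
  truth <- data.frame(
    construct_id = ids, true_tss = as.integer(tss), planted = planted,
    strength = strength, spacer = as.integer(spacer),
    minus10_start = as.integer(m10_start),
    minus35_start = as.integer(m35_start)
  )
  list(library = lib, truth = truth)
}

#' Reference sigma70 position weight matrices
#'
#' Fixed consensus-derived matrices (TTGACA / TATAAT, plus a purine-rich
#' initiation-region matrix) used to compute ground-truth features when
#' simulating activities, and available as a scanning fallback when no
#' data-driven discovery is possible.
#'
#' @param matchProb consensus base probability (default 0.85).
#' @return list of \linkS4class{PWMatrix}: \code{pwm35}, \code{pwm10},
#'   \code{pwmTss}.
#' @export
sigma70Pwms <- function(matchProb = 0.85) {
  list(pwm35 = consensusPwm("TTGACA", matchProb),
       pwm10 = consensusPwm("TATAAT", matchProb),
       pwmTss = consensusPwm("AGGAGA", 0.5))
}

#' TssCallSet from ground-truth TSS positions
#'
#' Wraps a simulation truth table as a \linkS4class{TssCallSet} (every truth
#' TSS becomes a primary call), so feature extraction can run on ground
#' truth without read-level TSS calling.
#'
#' @param truth truth data.frame from \code{\link{generateLibrary}}.
#' @return a \linkS4class{TssCallSet}.
#' @export
truthTssCalls <- function(truth) {
  methods::new("TssCallSet",
    calls = S4Vectors::DataFrame(
      construct_id = truth$construct_id,
      primary_tss = as.integer(truth$true_tss),
      primary_fraction = rep(1, nrow(truth)),
      primary_count = rep(NA_integer_, nrow(truth)),
      total_reads = rep(NA_integer_, nrow(truth)),
      secondaries = rep("", nrow(truth))
    ),
    clusters = list())
}

#' Assign ground-truth activities as a linear function of features
#'
#' Computes the eight promoter features from the truth TSS annotations
#' (using fixed reference matrices), standardizes them across the library,
#' and sets true log10 activity = X beta + Gaussian noise. A matrix beta
#' (8 x samples) yields per-species truths for cross-sample simulations.
#'
#' @param lib a \linkS4class{ReporterLibrary} from
#'   \code{\link{generateLibrary}}.
#' @param truth its truth data.frame.
#' @param beta length-8 coefficient vector, or 8 x samples matrix.
#' @param sigma Gaussian noise SD (log10 units); must be >= 0.
#' @param seed RNG seed.
#' @param pwms reference matrices (default \code{\link{sigma70Pwms}()}).
#' @return \code{truth} with added columns \code{true_log10_activity}
#'   (vector beta) or \code{true_log10_activity.<sample>} (matrix beta);
#'   the standardized feature matrix is attached as attribute
#'   \code{"features"}.
#' @export
assignTruth <- function(lib, truth, beta, sigma = 0.3, seed = 1L,
                        pwms = sigma70Pwms()) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  calls <- truthTssCalls(truth)
  X <- buildFeatureMatrix(lib, calls, pwms)
  if (!setequal(rownames(X), truth$construct_id))
    stop("feature extraction dropped constructs; widen tssRange so every ",
         "truth TSS has a full promoter window", call. = FALSE)
  X <- X[truth$construct_id, , drop = FALSE]
  Xs <- scale(X)
  Xs[, apply(X, 2L, stats::sd) == 0] <- 0
  B <- if (is.matrix(beta)) beta else matrix(beta, ncol = 1L,
                                             dimnames = list(NULL, "s1"))
  if (nrow(B) != ncol(X)) stop("beta must have 8 rows", call. = FALSE)
  act <- Xs %*% B + matrix(stats::rnorm(nrow(X) * ncol(B), 0, sigma),
                           nrow(X), ncol(B))
  if (ncol(B) == 1L) {
    truth$true_log10_activity <- drop(act)
  } else {
    for (s in colnames(B))
      truth[[paste0("true_log10_activity.", s)]] <- act[, s]
  }
  attr(truth, "features") <- Xs
  truth
}

#' Simulate sequencing reads for a library with known truth
#'
#' Emulates the assay's sequencing output. Input DNA abundances are
#' Dirichlet-perturbed (gamma draws, concentration \code{dirichletShape});
#' an optional restriction-style depletion divides the abundance of
#' constructs whose regulatory sequence contains a (degenerate) motif.
#' Per replicate, DNA counts are multinomial at \code{depthDna}; RNA counts
#' are multinomial with weights proportional to DNA abundance times
#' 10^(true log10 activity). Each RNA read's 5' end is the truth TSS plus
#' rounded Gaussian jitter (truncated to the regulatory sequence); reads
#' are rendered as 5' segment + context + barcode, with the adaptor's
#' random bases and adaptor sequence appended. DNA reads carry the full
#' construct. Qualities are constant; reads are error-free unless
#' \code{errorRate > 0}.
#'
#' @param lib a \linkS4class{ReporterLibrary}.
#' @param truth truth data.frame from \code{\link{assignTruth}} (needs
#'   \code{true_log10_activity}; pass \code{activityColumn} to select a
#'   per-sample column).
#' @param depthDna,depthRna reads per replicate per kind.
#' @param tssJitterSd SD of the discretized Gaussian 5'-end jitter
#'   (default 0.5, about 92\% of reads exactly on the TSS).
#' @param adaptor an \code{\link{AdaptorSpec}}.
#' @param replicates number of replicates per kind (default 2).
#' @param depletion optional \code{list(motif = "CCNGG", factor = 20)}.
#' @param errorRate per-base substitution rate (default 0).
#' @param dir output directory for FASTQ files.
#' @param sample sample label used in file names.
#' @param dirichletShape abundance inhomogeneity (default 10).
#' @param activityColumn truth column with log10 activities.
#' @param seed RNG seed; byte-identical FASTQ for a fixed seed.
#' @return list with \code{dnaFiles}, \code{rnaFiles} (paths, one per
#'   replicate), \code{dnaCounts}, \code{rnaCounts} (constructs x
#'   replicates truth matrices), \code{rnaTss} (data.table: construct_id,
#'   replicate, five_prime_pos, count) and \code{abundance} (the realized
#'   input DNA abundances after any depletion).
#' @export
simulateReads <- function(lib, truth, depthDna = 1e5, depthRna = 1e5,
                          tssJitterSd = 0.5,
                          adaptor = AdaptorSpec("AGATCGGAAGAGC", 2L),
                          replicates = 2L, depletion = NULL,
                          errorRate = 0, dir = tempdir(), sample = "s1",
                          dirichletShape = 10,
                          activityColumn = "true_log10_activity",
                          seed = 1L) {
  stopifnot(depthDna >= 0, depthRna >= 0)
  if (!is.null(depletion) && depletion$factor <= 0)
    stop("depletion factor must be > 0", call. = FALSE)
  if (!activityColumn %in% colnames(truth))
    stop("truth lacks column ", activityColumn, call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- lib@constructs
  ids <- df$construct_id
  n <- length(ids)
  L <- nchar(df$reg_seq[1L])
  stopifnot(identical(truth$construct_id, ids))

  abund <- stats::rgamma(n, shape = dirichletShape)
  abund <- abund / sum(abund)
  if (!is.null(depletion)) {
    pat <- chartr("N", ".", toupper(depletion$motif))
    hit <- grepl(pat, df$reg_seq)
    abund[hit] <- abund[hit] / depletion$factor
    abund <- abund / sum(abund)
  }
  rna_w <- abund * 10^truth[[activityColumn]]
  rna_w <- rna_w / sum(rna_w)

  full_seq <- paste0(df$reg_seq, df$reporter_context, df$barcode)
  tail_seq <- paste0(df$reporter_context, df$barcode)
  rand_tail <- function(m) {
    if (adaptor$nRandom == 0L) return(rep("", m))
    do.call(paste0, replicate(adaptor$nRandom,
                              sample(DNA_BASES, m, replace = TRUE),
                              simplify = FALSE))
  }
  add_errors <- function(reads) {
    if (errorRate <= 0) return(reads)
    vapply(reads, function(s) {
      v <- strsplit(s, "")[[1L]]
      mut <- which(stats::runif(length(v)) < errorRate)
      if (length(mut) > 0L)
        v[mut] <- vapply(v[mut], function(b)
          sample(setdiff(DNA_BASES, b), 1L), "")
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  write_fastq <- function(reads, path, prefix) {
    m <- length(reads)
    if (m == 0L) { file.create(path); return(invisible(path)) }
    lines <- c(rbind(sprintf("@%s_%07d", prefix, seq_len(m)),
                     reads, "+",
                     strrep("I", nchar(reads))))
    writeLines(lines, path)
    invisible(path)
  }

  dna_counts <- matrix(0L, n, replicates,
                       dimnames = list(ids, paste0("rep", seq_len(replicates))))
  rna_counts <- dna_counts
  rna_tss_list <- list()
  dna_files <- character(replicates)
  rna_files <- character(replicates)
  for (r in seq_len(replicates)) {
    dc <- as.integer(stats::rmultinom(1L, depthDna, abund))
    rc <- as.integer(stats::rmultinom(1L, depthRna, rna_w))
    dna_counts[, r] <- dc
    rna_counts[, r] <- rc
    ## DNA reads: full construct
    dna_reads <- rep(full_seq, dc)
    if (length(dna_reads) > 0L)
      dna_reads <- paste0(add_errors(dna_reads),
                          rand_tail(length(dna_reads)), adaptor$adaptorSeq)
    dna_files[r] <- file.path(dir, sprintf("%s_DNA_rep%d.fastq", sample, r))
    write_fastq(dna_reads, dna_files[r], sprintf("%s_DNA_rep%d", sample, r))
    ## RNA reads: 5' segment from jittered TSS
    tss_rep <- rep(truth$true_tss, rc)
    cid_rep <- rep.int(seq_len(n), rc)
    jit <- as.integer(round(stats::rnorm(length(tss_rep), 0, tssJitterSd)))
    pos <- pmin(pmax(tss_rep + jit, -L), -1L)
    seg <- substr(df$reg_seq[cid_rep], L + pos + 1L, L)
    rna_reads <- if (length(seg) > 0L)
      paste0(add_errors(paste0(seg, tail_seq[cid_rep])),
             rand_tail(length(seg)), adaptor$adaptorSeq)
    else character(0)
    rna_files[r] <- file.path(dir, sprintf("%s_RNA_rep%d.fastq", sample, r))
    write_fastq(rna_reads, rna_files[r], sprintf("%s_RNA_rep%d", sample, r))
    if (length(pos) > 0L) {
      tt <- data.table::data.table(construct_id = ids[cid_rep],
                                   replicate = paste0("rep", r),
                                   five_prime_pos = pos)
      five_prime_pos <- construct_id <- NULL
      rna_tss_list[[r]] <- tt[, .N, by = c("construct_id", "replicate",
                                           "five_prime_pos")]
    }
  }
  rna_tss <- if (length(rna_tss_list) > 0L)
    data.table::rbindlist(rna_tss_list)
  else data.table::data.table(construct_id = character(0),
                              replicate = character(0),
                              five_prime_pos = integer(0), N = integer(0))
  data.table::setnames(rna_tss, "N", "count")
  list(dnaFiles = dna_files, rnaFiles = rna_files,
       dnaCounts = dna_counts, rnaCounts = rna_counts,
       rnaTss = rna_tss, abundance = abund)
}
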