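#' Default end-to-end pipeline configuration
#'
#' All tunable parameters with their default values: a 15-read DNA
#' abundance cutoff; TSS clustering seeded at 16 clusters with a 10 bp
#' merge distance, 1\% prune fraction, 70\%/200-read primary rule and 10\%
#' secondary rule; a 45 bp promoter scan window with a 17 +/- 2 bp spacer;
#' a 50 nt folding window and 8 bp TSS-region window; motif discovery on
#' the top 10\% most active promoters; and 10\%/90\% train/test
#' cross-validation with 10 repeats.
#'
#' @return named list of parameters.
#' @export
defaultConfig <- function() {
  list(
    dnaMinReads = 15L, pseudocount = 0,
    countsFrom = "barcode",
    adaptorSeq = "AGATCGGAAGAGC", nRandom = 2L, adaptorMaxMismatches = 0L,
    hamming1Rescue = FALSE,
    kSeed = 16L, mergeDist = 10L, minFrac = 0.01,
    primaryFrac = 0.70, primaryMinCount = 200L, secondaryFrac = 0.10,
    window = 45L, optimalSpacer = 17L, maxDev = 2L,
    motifWidth = 6L, topFrac = 0.10,
    foldWindow = 50L, tssRegionWidth = 8L, foldBackend = "nussinov",
    trainFrac = 0.10, cvRepeats = 10L,
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Merges user overrides into \code{\link{defaultConfig}}; unknown keys and
#' out-of-range values are errors naming the offending key.
#'
#' @param config named list of overrides (may be empty).
#' @return the merged, validated configuration list.
#' @export
validateConfig <- function(config = list()) {
  base <- defaultConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(base, config)
  chk <- function(ok, key, why)
    if (!ok) stop("config key ", key, ": ", why, call. = FALSE)
  chk(cfg$dnaMinReads >= 0, "dnaMinReads", "must be >= 0")
  chk(cfg$pseudocount >= 0, "pseudocount", "must be >= 0")
  chk(cfg$countsFrom %in% c("barcode", "match"), "countsFrom",
      "must be 'barcode' or 'match'")
  chk(.is_dna(toupper(cfg$adaptorSeq)), "adaptorSeq", "must be A/C/G/T")
  chk(cfg$nRandom >= 0, "nRandom", "must be >= 0")
  chk(cfg$kSeed >= 1, "kSeed", "must be >= 1")
  chk(cfg$mergeDist >= 0, "mergeDist", "must be >= 0")
  chk(cfg$minFrac >= 0 && cfg$minFrac < 1, "minFrac", "must be in [0, 1)")
  chk(cfg$primaryFrac > 0 && cfg$primaryFrac <= 1, "primaryFrac",
      "must be in (0, 1]")
  chk(cfg$primaryMinCount >= 0, "primaryMinCount", "must be >= 0")
  chk(cfg$secondaryFrac >= 0 && cfg$secondaryFrac < 1, "secondaryFrac",
      "must be in [0, 1)")
  chk(cfg$window >= 12, "window", "must cover both hexamers")
  chk(cfg$maxDev >= 0, "maxDev", "must be >= 0")
  chk(cfg$topFrac > 0 && cfg$topFrac <= 1, "topFrac", "must be in (0, 1]")
  chk(cfg$foldWindow >= 1, "foldWindow", "must be >= 1")
  chk(cfg$trainFrac > 0 && cfg$trainFrac < 1, "trainFrac",
      "must be in (0, 1)")
  chk(cfg$cvRepeats >= 1, "cvRepeats", "must be >= 1")
  chk(cfg$foldBackend %in% c("nussinov", "external"), "foldBackend",
      "must be 'nussinov' or 'external'")
  cfg
}

#' Run the full quantification pipeline on one sample
#'
#' Executes read processing, counting, activity estimation, TSS calling,
#' motif discovery, feature extraction, and cross-validated linear modeling
#' for one sample, writing every result table plus a reproducibility
#' manifest (input hashes, seed, configuration echo) to \code{outDir}. Any
#' stage error aborts with the stage name; tables written by earlier stages
#' are preserved.
#'
#' @param lib a \linkS4class{ReporterLibrary} or a path to a library TSV.
#' @param dnaFastq,rnaFastq character vectors of merged FASTQ paths, one
#'   per replicate.
#' @param outDir output directory.
#' @param sample sample label.
#' @param config configuration overrides (see \code{\link{validateConfig}}).
#' @return (invisibly) list with \code{counts}, \code{activity},
#'   \code{tss}, \code{pwms}, \code{features}, \code{model}, \code{cv}
#'   and the output \code{paths}.
#' @export
runPipeline <- function(lib, dnaFastq, rnaFastq, outDir, sample = "s1",
                        config = list()) {
  cfg <- validateConfig(config)
  if (is.character(lib)) lib <- loadLibrary(lib, format = "tsv")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spec <- AdaptorSpec(cfg$adaptorSeq, cfg$nRandom)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()

  reads <- stage("process", {
    c(
      lapply(seq_along(dnaFastq), function(r)
        processReads(dnaFastq[r], lib, spec, kind = "DNA",
                     replicate = paste0("rep", r), sample = sample,
                     maxMismatches = cfg$adaptorMaxMismatches,
                     hamming1Rescue = cfg$hamming1Rescue)),
      lapply(seq_along(rnaFastq), function(r)
        processReads(rnaFastq[r], lib, spec, kind = "RNA",
                     replicate = paste0("rep", r), sample = sample,
                     maxMismatches = cfg$adaptorMaxMismatches,
                     hamming1Rescue = cfg$hamming1Rescue))
    )
  })
  counts <- stage("quantify", tabulateCounts(reads, lib,
                                             countsFrom = cfg$countsFrom))
  paths$counts <- file.path(outDir, paste0(sample, "_counts.tsv"))
  utils::write.table(
    data.frame(construct_id = rownames(SummarizedExperiment::assay(counts)),
               SummarizedExperiment::assay(counts), check.names = FALSE),
    paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)

  activity <- stage("quantify",
                    computeActivity(counts, dnaMinReads = cfg$dnaMinReads,
                                    pseudocount = cfg$pseudocount))
  act_df <- data.frame(
    construct_id = rownames(SummarizedExperiment::assay(activity)),
    tx_raw = SummarizedExperiment::assay(activity, "txRaw")[, 1L],
    tx_log10 = SummarizedExperiment::assay(activity, "txLog10")[, 1L],
    tx_z = SummarizedExperiment::assay(activity, "txZ")[, 1L],
    pass_filter = SummarizedExperiment::assay(activity, "passFilter")[, 1L])
  paths$activity <- file.path(outDir, paste0(sample, "_activity.tsv"))
  utils::write.table(act_df, paths$activity, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  all_reads <- data.table::rbindlist(reads)
  tss <- stage("tss", callTssAll(all_reads, lib, kSeed = cfg$kSeed,
                                 mergeDist = cfg$mergeDist,
                                 minFrac = cfg$minFrac,
                                 primaryFrac = cfg$primaryFrac,
                                 primaryMinCount = cfg$primaryMinCount,
                                 secondaryFrac = cfg$secondaryFrac))
  paths$tss <- file.path(outDir, paste0(sample, "_tss.tsv"))
  utils::write.table(as.data.frame(tss@calls), paths$tss, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pwms <- stage("features", discoverPromoterPwms(
    lib, activity, tss, sample = 1L, topFrac = cfg$topFrac,
    width = cfg$motifWidth, window = cfg$window,
    tssRegionWidth = cfg$tssRegionWidth))
  features <- stage("features", buildFeatureMatrix(
    lib, tss, pwms, activities = activity, sample = 1L,
    optimalSpacer = cfg$optimalSpacer, maxDev = cfg$maxDev,
    window = cfg$window, foldWindow = cfg$foldWindow,
    tssRegionWidth = cfg$tssRegionWidth, foldBackend = cfg$foldBackend))
  paths$features <- file.path(outDir, paste0(sample, "_features.tsv"))
  utils::write.table(
    data.frame(construct_id = rownames(features), features),
    paths$features, sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("pwm35", "pwm10", "pwmTss")) {
    paths[[nm]] <- file.path(outDir, paste0(sample, "_", nm, ".tsv"))
    writePwm(pwms[[nm]], paths[[nm]])
  }

  model_out <- stage("model", {
    z <- SummarizedExperiment::assay(activity, "txZ")[rownames(features), 1L]
    lg <- SummarizedExperiment::assay(activity,
                                      "txLog10")[rownames(features), 1L]
    cv <- crossValidate(features, z, trainFrac = cfg$trainFrac,
                        repeats = cfg$cvRepeats, seed = cfg$seed,
                        log10Center = mean(lg), log10Scale = stats::sd(lg))
    mod <- fitOls(features, z, log10Center = mean(lg),
                  log10Scale = stats::sd(lg))
    list(model = mod, cv = cv)
  })
  paths$model <- file.path(outDir, paste0(sample, "_model.json"))
  writeModel(model_out$model, paths$model)
  paths$cv <- file.path(outDir, paste0(sample, "_cv.tsv"))
  utils::write.table(model_out$cv, paths$cv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    package = "TXTLseq",
    version = as.character(utils::packageVersion("TXTLseq")),
    sample = sample,
    config = cfg,
    inputs = as.list(tools::md5sum(c(dnaFastq, rnaFastq))),
    qc = lapply(reads, function(r) as.list(attr(r, "qc")))
  )
  paths$manifest <- file.path(outDir, paste0(sample, "_manifest.json"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(counts = counts, activity = activity, tss = tss,
                 pwms = pwms, features = features,
                 model = model_out$model, cv = model_out$cv, paths = paths))
}
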