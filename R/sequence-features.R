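#' Spacer length penalty
#'
#' Sigma70 promoters are most active with 17 bp between the -35 and -10
#' hexamers; deviations of up to \code{maxDev} bp are penalized linearly
#' (-1 per bp of deviation) and larger deviations are disallowed.
#'
#' @param spacerLen observed spacer length(s), bp.
#' @param optimal optimal spacer (default 17).
#' @param maxDev maximum tolerated deviation (default 2).
#' @return numeric penalty in \{0, -1, ..., -maxDev\}; NA where the spacer
#'   is outside the tolerated range.
#' @export
spacerPenalty <- function(spacerLen, optimal = 17L, maxDev = 2L) {
  d <- abs(as.numeric(spacerLen) - optimal)
  ifelse(d <= maxDev, -d, NA_real_)
}

#' Annotate the sigma70 promoter of a regulatory sequence
#'
#' Joint scan for the -35 and -10 hexamers within the 45 bp immediately
#' upstream of the primary TSS: all placements with both elements inside
#' the window and a spacer of \code{optimal +- maxDev} bp are scored as
#' pwm35 + pwm10 log-odds (bits) plus the spacer penalty, and the best
#' placement is returned. Positions are reported in bp from the reporter
#' ATG (negative).
#'
#' @param regSeq regulatory sequence.
#' @param primaryTssPos primary TSS position (negative, bp from ATG), or NA.
#' @param pwm10,pwm35 \linkS4class{PWMatrix} objects for the two elements.
#' @param optimalSpacer optimal spacer length (default 17).
#' @param maxDev spacer tolerance (default 2).
#' @param window scan window upstream of the TSS, bp (default 45).
#' @return list with \code{valid}; when valid: \code{minus35} and
#'   \code{minus10} (each \code{start}, \code{end}, \code{score} in bits),
#'   \code{spacer_len}, \code{spacer_penalty}, \code{spacer_seq},
#'   \code{truncated} (TRUE when less than \code{window} bp was available).
#' @export
annotatePromoter <- function(regSeq, primaryTssPos, pwm10, pwm35,
                             optimalSpacer = 17L, maxDev = 2L, window = 45L) {
  invalid <- list(valid = FALSE, minus35 = NULL, minus10 = NULL,
                  spacer_len = NA_integer_, spacer_penalty = NA_real_,
                  spacer_seq = NA_character_, truncated = NA)
  if (is.na(primaryTssPos)) return(invalid)
  regSeq <- toupper(regSeq)
  L <- nchar(regSeq)
  tss_idx <- .pos_to_idx(primaryTssPos, L)   # 1-based index of the TSS base
  win_hi <- tss_idx - 1L                     # last upstream base
  win_lo <- max(1L, tss_idx - window)
  truncated <- (tss_idx - window) < 1L
  w10 <- pwmWidth(pwm10); w35 <- pwmWidth(pwm35)
  if (win_hi - win_lo + 1L < w10 + w35 + (optimalSpacer - maxDev))
    return(invalid)
  lo10 <- log2(pwm10@probs / pwm10@background)
  lo35 <- log2(pwm35@probs / pwm35@background)
  v <- match(strsplit(regSeq, "")[[1L]], DNA_BASES)
  score_at <- function(lo, start, w) {
    idx <- v[start:(start + w - 1L)]
    sum(lo[cbind(idx, seq_len(w))])
  }
  best <- NULL; best_score <- -Inf
  spacers <- seq(optimalSpacer - maxDev, optimalSpacer + maxDev)
  for (sp in spacers) {
    pen <- -as.numeric(abs(sp - optimalSpacer))
    ## -35 start s35; -10 start = s35 + w35 + sp
    s35_max <- win_hi - (w35 + sp + w10) + 1L
    if (s35_max < win_lo) next
    for (s35 in win_lo:s35_max) {
      s10 <- s35 + w35 + sp
      sc <- score_at(lo35, s35, w35) + score_at(lo10, s10, w10) + pen
      if (sc > best_score) {
        best_score <- sc
        best <- list(s35 = s35, s10 = s10, sp = sp, pen = pen,
                     sc35 = score_at(lo35, s35, w35),
                     sc10 = score_at(lo10, s10, w10))
      }
    }
  }
  if (is.null(best)) return(invalid)
  list(
    valid = TRUE,
    minus35 = list(start = .idx_to_pos(best$s35, L),
                   end = .idx_to_pos(best$s35 + w35 - 1L, L),
                   score = best$sc35),
    minus10 = list(start = .idx_to_pos(best$s10, L),
                   end = .idx_to_pos(best$s10 + w10 - 1L, L),
                   score = best$sc10),
    spacer_len = best$sp,
    spacer_penalty = best$pen,
    spacer_seq = substr(regSeq, best$s35 + w35, best$s10 - 1L),
    truncated = truncated
  )
}

#' Discover the -10, -35 and TSS-region matrices from called promoters
#'
#' Selects the top \code{topFrac} of constructs by activity among those with
#' a primary TSS, then runs \code{\link{discoverPwm}} on three windows
#' relative to each primary TSS: a distal window for the -35 element
#' (45 to 24 bp upstream), a proximal window for the -10 element (the 15 bp
#' immediately upstream), and the \code{tssRegionWidth} bp of downstream
#' sequence starting at the TSS.
#'
#' @param lib a \linkS4class{ReporterLibrary}.
#' @param activities an \linkS4class{ActivitySet}.
#' @param tssCalls a \linkS4class{TssCallSet}.
#' @param sample sample (column) of \code{activities} to rank by.
#' @param topFrac fraction of most-active promoters used (default 0.10).
#' @param width motif width (default 6).
#' @param window upstream promoter window, bp (default 45).
#' @param tssRegionWidth downstream window, bp (default 8).
#' @param minSeqs minimum usable promoters (default 20).
#' @return list with \linkS4class{PWMatrix} entries \code{pwm35},
#'   \code{pwm10}, \code{pwmTss} and the selected \code{construct_ids}.
#' @export
discoverPromoterPwms <- function(lib, activities, tssCalls, sample = 1L,
                                 topFrac = 0.10, width = 6L, window = 45L,
                                 tssRegionWidth = 8L, minSeqs = 20L) {
  tss <- primaryTss(tssCalls)
  z <- SummarizedExperiment::assay(activities, "txZ")[, sample]
  ok <- names(tss)[!is.na(tss) & !is.na(z[names(tss)])]
  if (length(ok) < minSeqs)
    stop("fewer than ", minSeqs, " constructs with a primary TSS and ",
         "defined activity", call. = FALSE)
  n_top <- max(minSeqs, ceiling(topFrac * length(ok)))
  top <- ok[order(z[ok], decreasing = TRUE)][seq_len(min(n_top, length(ok)))]
  reg <- stats::setNames(lib@constructs$reg_seq, lib@constructs$construct_id)
  ctx <- stats::setNames(lib@constructs$reporter_context,
                         lib@constructs$construct_id)
  win35 <- character(0); win10 <- character(0); winTss <- character(0)
  for (id in top) {
    s <- reg[[id]]; L <- nchar(s)
    ti <- .pos_to_idx(tss[[id]], L)
    lo <- ti - window
    if (lo >= 1L) {
      up <- substr(s, lo, ti - 1L)           # the 45 bp preceding the TSS
      win35 <- c(win35, substr(up, 1L, window - 23L))   # distal segment
      win10 <- c(win10, substr(up, window - 14L, window)) # proximal 15 bp
    }
    down <- substr(paste0(s, ctx[[id]]), ti, ti + tssRegionWidth - 1L)
    if (nchar(down) == tssRegionWidth) winTss <- c(winTss, down)
  }
  list(
    pwm35 = discoverPwm(win35, width = width, minSeqs = minSeqs),
    pwm10 = discoverPwm(win10, width = width, minSeqs = minSeqs),
    pwmTss = discoverPwm(winTss, width = min(width, tssRegionWidth),
                         minSeqs = minSeqs),
    construct_ids = top
  )
}

#' Promoter sequence features for activity modeling
#'
#' Computes the eight features used to model transcriptional activity, for
#' every construct with a primary TSS and a valid promoter annotation:
#' \describe{
#'   \item{f1_minus35_score}{-35 element log-odds match, bits}
#'   \item{f2_minus10_score}{-10 element log-odds match, bits}
#'   \item{f3_interaction}{product of the standardized f1 and f2}
#'   \item{f4_spacer_penalty}{\code{\link{spacerPenalty}} of the annotated
#'     spacer}
#'   \item{f5_spacer_gc}{GC fraction of the spacer sequence}
#'   \item{f6_tss_region_score}{log-odds match of the 8 bp downstream of the
#'     TSS against the TSS-region matrix, bits}
#'   \item{f7_utr_dG}{\code{\link{fold5prime}} pseudo-energy of the first
#'     50 nt downstream of the TSS}
#'   \item{f8_gc_content}{GC fraction of the full regulatory sequence}
#' }
#'
#' @param lib a \linkS4class{ReporterLibrary}.
#' @param tssCalls a \linkS4class{TssCallSet}.
#' @param pwms list with \code{pwm35}, \code{pwm10}, \code{pwmTss} (as from
#'   \code{\link{discoverPromoterPwms}}).
#' @param activities optional \linkS4class{ActivitySet}; when given, the
#'   per-feature Pearson correlation with \code{txZ} is attached as
#'   attribute \code{"featureCorrelations"} and rows are restricted to
#'   constructs with defined activity.
#' @param sample sample of \code{activities} used for the correlations.
#' @param optimalSpacer,maxDev,window promoter-scan geometry (see
#'   \code{\link{annotatePromoter}}).
#' @param foldWindow transcript 5'-end window for folding, nt (default 50).
#' @param tssRegionWidth downstream composition window, bp (default 8).
#' @param foldBackend,folder see \code{\link{fold5prime}}.
#' @return numeric matrix (constructs x 8 features), complete rows only.
#' @export
buildFeatureMatrix <- function(lib, tssCalls, pwms, activities = NULL,
                               sample = 1L, optimalSpacer = 17L, maxDev = 2L,
                               window = 45L, foldWindow = 50L,
                               tssRegionWidth = 8L,
                               foldBackend = "nussinov", folder = NULL) {
  tss <- primaryTss(tssCalls)
  ids <- names(tss)[!is.na(tss)]
  if (!is.null(activities)) {
    z <- SummarizedExperiment::assay(activities, "txZ")[, sample]
    ids <- ids[!is.na(z[ids])]
  }
  if (length(ids) == 0L)
    stop("no constructs with a primary TSS (and defined activity)",
         call. = FALSE)
  reg <- stats::setNames(lib@constructs$reg_seq, lib@constructs$construct_id)
  ctx <- stats::setNames(lib@constructs$reporter_context,
                         lib@constructs$construct_id)
  feat_names <- c("f1_minus35_score", "f2_minus10_score", "f3_interaction",
                  "f4_spacer_penalty", "f5_spacer_gc", "f6_tss_region_score",
                  "f7_utr_dG", "f8_gc_content")
  m <- matrix(NA_real_, length(ids), 8L, dimnames = list(ids, feat_names))
  for (id in ids) {
    s <- reg[[id]]; L <- nchar(s)
    ann <- annotatePromoter(s, tss[[id]], pwms$pwm10, pwms$pwm35,
                            optimalSpacer = optimalSpacer, maxDev = maxDev,
                            window = window)
    if (!ann$valid) next
    ti <- .pos_to_idx(tss[[id]], L)
    full <- paste0(s, ctx[[id]])
    down_tss <- substr(full, ti, ti + tssRegionWidth - 1L)
    down_fold <- substr(full, ti, min(nchar(full), ti + foldWindow - 1L))
    f6 <- if (nchar(down_tss) >= pwmWidth(pwms$pwmTss))
      scorePwm(pwms$pwmTss, down_tss)$score else NA_real_
    m[id, ] <- c(ann$minus35$score, ann$minus10$score, NA_real_,
                 ann$spacer_penalty, gcFraction(ann$spacer_seq), f6,
                 fold5prime(down_fold, backend = foldBackend,
                            folder = folder),
                 gcFraction(s))
  }
  ## interaction of standardized motif scores
  std <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(x))
    else (x - mean(x, na.rm = TRUE)) / s
  }
  m[, "f3_interaction"] <- std(m[, "f1_minus35_score"]) *
    std(m[, "f2_minus10_score"])
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no complete feature rows", call. = FALSE)
  if (!is.null(activities)) {
    zz <- z[rownames(m)]
    attr(m, "featureCorrelations") <-
      apply(m, 2L, function(col) {
        if (stats::sd(col) == 0) NA_real_ else .pearson(col, zz)
      })
  }
  m
}
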