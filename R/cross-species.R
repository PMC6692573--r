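#' Activity profile matrix over universally active constructs
#'
#' Rows are the constructs active in every included sample — passing the
#' DNA-abundance filter with defined (nonzero-RNA) activity — and values are
#' activity Z-scores. This is the input to the comparative analytics
#' (correlation, PCA, clustering).
#'
#' @param activities an \linkS4class{ActivitySet}.
#' @param samples samples to include (default: all).
#' @return numeric matrix constructs x samples, no missing values.
#' @export
profileMatrix <- function(activities, samples = NULL) {
  z <- SummarizedExperiment::assay(activities, "txZ")
  if (!is.null(samples)) z <- z[, samples, drop = FALSE]
  keep <- stats::complete.cases(z)
  m <- z[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no universally active constructs", call. = FALSE)
  m
}

#' Pairwise Pearson correlation of activity profiles
#'
#' @param m a profile matrix (see \code{\link{profileMatrix}}).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwiseCorrelation <- function(m) {
  if (nrow(m) < 3L) stop("need at least 3 constructs", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column: ", paste(colnames(m)[sds == 0], collapse = ", "),
         call. = FALSE)
  stats::cor(m)
}

#' Principal component analysis of sample activity profiles
#'
#' Samples are the observations (rows of the transposed profile matrix);
#' constructs are the variables, centered before the singular value
#' decomposition. Component signs are fixed deterministically by forcing
#' each component's largest-magnitude loading positive.
#'
#' @param m a profile matrix (constructs x samples).
#' @param nComponents number of components (default: all).
#' @return list with \code{scores} (samples x components),
#'   \code{loadings}, \code{varianceExplained} (fractions).
#' @export
pcaProfiles <- function(m, nComponents = NULL) {
  obs <- t(m)                      # samples as observations
  if (nrow(obs) < 2L) stop("need at least 2 samples", call. = FALSE)
  maxc <- min(dim(obs)) - 0L
  if (is.null(nComponents)) nComponents <- min(nrow(obs) - 1L, ncol(obs))
  if (nComponents > maxc)
    stop("nComponents exceeds min(samples, constructs)", call. = FALSE)
  ctr <- scale(obs, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  total_var <- sum(sv$d^2)
  k <- min(nComponents, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (flip < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(obs)
  colnames(scores) <- paste0("PC", seq_len(k))
  dimnames(loadings) <- list(colnames(obs), colnames(scores))
  list(scores = scores, loadings = loadings,
       varianceExplained = (sv$d^2 / total_var)[seq_len(k)])
}

#' Average-linkage hierarchical clustering of activity profiles
#'
#' Clusters samples (or constructs) on correlation distance (1 - Pearson r)
#' with average linkage and returns the tree in newick format. hclust's
#' agglomeration is deterministic; leaf labels keep their input order.
#'
#' @param m a profile matrix (constructs x samples).
#' @param axis cluster \code{"samples"} (default) or \code{"constructs"}.
#' @return list with \code{hclust} (the tree) and \code{newick} (string).
#' @export
hierarchicalCluster <- function(m, axis = c("samples", "constructs")) {
  axis <- match.arg(axis)
  x <- if (axis == "samples") m else t(m)
  if (ncol(x) < 2L) stop("need at least 2 leaves", call. = FALSE)
  r <- pairwiseCorrelation(x)
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  nw <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = nw)
}

#' Species-selective constructs
#'
#' A construct is selective for a sample when its raw activity there exceeds
#' \code{fold} times its strongest activity in any other sample (strictly;
#' computed on the linear ratio scale). Constructs inactive everywhere are
#' skipped; an undefined activity in another sample counts as zero there.
#'
#' @param activities an \linkS4class{ActivitySet} with at least 2 samples.
#' @param fold selectivity threshold (default 10).
#' @return named list: per sample, the selective construct ids.
#' @export
speciesSelective <- function(activities, fold = 10) {
  tx <- SummarizedExperiment::assay(activities, "txRaw")
  pass <- SummarizedExperiment::assay(activities, "passFilter")
  if (ncol(tx) < 2L) stop("need at least 2 samples", call. = FALSE)
  tx[!pass | is.na(tx)] <- 0
  active_any <- rowSums(tx > 0) > 0
  out <- stats::setNames(vector("list", ncol(tx)), colnames(tx))
  for (s in seq_len(ncol(tx))) {
    others <- apply(tx[, -s, drop = FALSE], 1L, max)
    sel <- active_any & tx[, s] > 0 & tx[, s] > fold * others
    out[[s]] <- rownames(tx)[sel]
  }
  out
}
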