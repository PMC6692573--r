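#' Fit an ordinary least squares model of transcriptional activity
#'
#' Regresses Z-scored log10 activity on standardized promoter features.
#' Features are centered and scaled (constant columns are left unscaled and
#' receive a zero coefficient); the fit uses a QR solve of the least squares
#' problem, falling back to a tiny ridge penalty (lambda = 1e-8) with a
#' warning when the design is rank-deficient.
#'
#' @param X numeric feature matrix (rows = constructs).
#' @param y response (Z-scored log10 activity), same length as rows of X.
#' @param log10Center,log10Scale mean/SD of log10 activity over the training
#'   constructs; stored so predictions can be mapped back to the log10 scale
#'   (see \code{\link{predictLog10}}).
#' @param trainFraction bookkeeping: fraction of the dataset this fit used.
#' @return a \linkS4class{PromoterModel}.
#' @export
fitOls <- function(X, y, log10Center = 0, log10Scale = 1,
                   trainFraction = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("rows(X) != length(y)", call. = FALSE)
  if (nrow(X) < 10L) stop("need at least 10 rows", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  D <- cbind(`(Intercept)` = 1, Xs)
  fit <- stats::lm.fit(D, y)
  if (fit$rank < ncol(D)) {
    warning("rank-deficient design; using ridge fallback (lambda = 1e-8)")
    lambda <- 1e-8
    A <- crossprod(D) + diag(lambda, ncol(D))
    beta <- solve(A, crossprod(D, y))[, 1L]
  } else {
    beta <- fit$coefficients
  }
  pred <- drop(D %*% beta)
  r_train <- if (stats::sd(pred) > 0 && stats::sd(y) > 0)
    .pearson(pred, y) else NA_real_
  methods::new("PromoterModel",
               coefficients = beta[-1L], intercept = unname(beta[1L]),
               featureCenter = ctr, featureScale = scl,
               log10Center = log10Center, log10Scale = log10Scale,
               trainFraction = trainFraction, rTrain = r_train)
}

#' Predict activity Z-scores for new constructs
#'
#' @param object a \linkS4class{PromoterModel}.
#' @param newdata feature matrix with the model's feature columns.
#' @return numeric vector of predictions on the Z scale.
#' @export
setMethod("predict", "PromoterModel", function(object, newdata) {
  X <- as.matrix(newdata)
  cn <- names(object@coefficients)
  if (!is.null(colnames(X)) && all(cn %in% colnames(X))) {
    X <- X[, cn, drop = FALSE]
  } else if (ncol(X) != length(cn)) {
    stop("newdata does not carry the model's feature columns", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, object@featureCenter), 2L,
              object@featureScale, "/")
  drop(Xs %*% object@coefficients) + object@intercept
})

#' Map model predictions back to the log10 activity scale
#'
#' Inverse of the training-set Z-score transform:
#' log10 = z * trainSD + trainMean.
#'
#' @param model a \linkS4class{PromoterModel}.
#' @param newdata feature matrix.
#' @return predictions in log10 activity units.
#' @export
predictLog10 <- function(model, newdata) {
  predict(model, newdata) * model@log10Scale + model@log10Center
}

#' Fraction of predictions within one log10 unit of observation
#'
#' @param pred,obs matched vectors on the log10 activity scale.
#' @return fraction in [0, 1].
#' @export
fracWithinOneLog <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  mean(abs(pred - obs) <= 1)
}

#' Repeated random-subsampling cross-validation
#'
#' Repeatedly splits the data into a training fraction (default 10\%) and
#' held-out test fraction (90\%), fits \code{\link{fitOls}} on the training
#' split and evaluates the Pearson correlation between predicted and
#' observed activity on the held-out constructs. Fully reproducible under
#' \code{seed}.
#'
#' @param X feature matrix.
#' @param y response vector (Z-scored log10 activity).
#' @param trainFrac training fraction in (0, 1) (default 0.10).
#' @param repeats number of random splits (default 10).
#' @param seed RNG seed.
#' @param log10Center,log10Scale passed through to \code{\link{fitOls}} so
#'   each repeat can report the within-one-log fraction on the log10 scale.
#' @return data.frame with one row per repeat: \code{r_test},
#'   \code{frac_within_1log}, \code{n_train}, \code{n_test}.
#' @export
crossValidate <- function(X, y, trainFrac = 0.10, repeats = 10L, seed = 1L,
                          log10Center = 0, log10Scale = 1) {
  if (!(trainFrac > 0 && trainFrac < 1))
    stop("trainFrac must be in (0, 1)", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  n_train <- floor(n * trainFrac)
  if (n_train < 10L)
    stop("training split smaller than 10 rows", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    idx <- sample.int(n, n_train)
    mod <- fitOls(X[idx, , drop = FALSE], y[idx],
                  log10Center = log10Center, log10Scale = log10Scale,
                  trainFraction = trainFrac)
    pred <- predict(mod, X[-idx, , drop = FALSE])
    obs <- y[-idx]
    r <- if (stats::sd(pred) > 0 && stats::sd(obs) > 0)
      .pearson(pred, obs) else NA_real_
    fw <- fracWithinOneLog(pred * log10Scale + log10Center,
                           obs * log10Scale + log10Center)
    out[[i]] <- data.frame(r_test = r, frac_within_1log = fw,
                           n_train = n_train, n_test = n - n_train)
  }
  do.call(rbind, out)
}

#' Serialize a fitted model to JSON
#'
#' @param model a \linkS4class{PromoterModel}.
#' @param path output path.
#' @return \code{path} (write) or a \linkS4class{PromoterModel} (read).
#' @export
writeModel <- function(model, path) {
  jsonlite::write_json(list(
    coefficients = as.list(model@coefficients),
    intercept = model@intercept,
    featureCenter = as.list(model@featureCenter),
    featureScale = as.list(model@featureScale),
    log10Center = model@log10Center, log10Scale = model@log10Scale,
    trainFraction = model@trainFraction,
    rTrain = model@rTrain, rTest = model@rTest,
    fracWithin1Log = model@fracWithin1Log
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("PromoterModel",
               coefficients = unlist(j$coefficients),
               intercept = j$intercept,
               featureCenter = unlist(j$featureCenter),
               featureScale = unlist(j$featureScale),
               log10Center = j$log10Center, log10Scale = j$log10Scale,
               trainFraction = j$trainFraction,
               rTrain = if (is.null(j$rTrain)) NA_real_ else j$rTrain,
               rTest = if (is.null(j$rTest)) NA_real_ else j$rTest,
               fracWithin1Log = if (is.null(j$fracWithin1Log)) NA_real_
                                else j$fracWithin1Log)
}
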