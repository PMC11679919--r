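# Cross-validation-averaged SVM-RFE: linear soft-margin fits, per-fold
# squared-weight ranking scores averaged over 10 folds, one feature deleted
# per round, and accuracy-trajectory subset selection.

# Lean libsvm fit used in the RFE inner loop. Returns the (unoriented)
# primal weight vector and what is needed to predict held-out labels from
# decision values directly (libsvm orients positive decisions toward the
# first training label, m$labels[1]).
.fitLinearRaw <- function(x, y, C) {
  m <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
  w <- as.numeric(crossprod(m$coefs, m$SV))
  list(w = w, rho = m$rho, labels = m$labels, levels = m$levels)
}

.predictLinearRaw <- function(fit, xTest) {
  dec <- as.numeric(xTest %*% fit$w) - fit$rho
  fit$levels[ifelse(dec > 0, fit$labels[1], fit$labels[2])]
}

#' Train a soft-margin linear SVM
#'
#' Solves the soft-margin dual (via libsvm) and recovers the primal weight
#' vector \code{w = sum_k alpha_k y_k x_k} and bias \code{b}, oriented so
#' the decision function \code{D(x) = w . x + b} is positive for the +1
#' class.
#'
#' @param X observations x features numeric matrix.
#' @param y labels: numeric -1/+1 or a two-level factor (the second level is
#'   treated as +1).
#' @param C box constraint (> 0).
#' @return a \linkS4class{LinearSVMModel}.
#' @export
trainLinearSVM <- function(X, y, C = 1) {
  X <- as.matrix(X)
  if (C <= 0) stop("C must be positive")
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2L) stop("y must contain exactly two classes")
    yNum <- ifelse(y == levels(y)[2], 1, -1)
  } else {
    yNum <- as.numeric(y)
    if (!all(yNum %in% c(-1, 1))) stop("numeric y must be -1/+1")
    if (length(unique(yNum)) != 2L) stop("y must contain exactly two classes")
  }
  yf <- factor(yNum, levels = c(-1, 1))
  m <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE,
                  tolerance = 1e-8)
  w <- as.numeric(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # orient so positive decision values predict +1
  dv <- attr(predict(m, X[1:2, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  posSide <- strsplit(colnames(dv), "/")[[1]][1]
  if (posSide == "-1") {
    w <- -w; b <- -b
  }
  alphas <- numeric(nrow(X))
  alphas[m$index] <- abs(as.numeric(m$coefs))
  names(w) <- colnames(X)
  new("LinearSVMModel", w = w, b = b, alphas = alphas,
      supportIndices = as.integer(m$index), cost = C)
}

#' @describeIn trainLinearSVM decision values \code{w . x + b} for new data.
#' @param object a \linkS4class{LinearSVMModel}.
#' @param newdata observations x features matrix.
#' @export
setMethod("predict", "LinearSVMModel", function(object, newdata) {
  as.numeric(as.matrix(newdata) %*% object@w + object@b)
})

# One stratified CV pass on a feature subset: per fold, fit on the training
# part, square the weights (ranking criterion), predict the held-out part.
# Returns the fold-averaged per-feature scores and the pooled CV accuracy.
.cvPass <- function(X, y, C, fold) {
  nFolds <- max(fold)
  W2 <- matrix(0, nFolds, ncol(X))
  correct <- 0L
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    fit <- .fitLinearRaw(X[tr, , drop = FALSE], y[tr], C)
    W2[f, ] <- fit$w^2
    pred <- .predictLinearRaw(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == as.character(y[!tr]))
  }
  list(scores = colMeans(W2), accuracy = correct / length(y))
}

#' CV-averaged ranking scores
#'
#' For stratified fold j, a linear SVM fit on the training portion yields
#' weights \code{w_ij}; the per-fold ranking criterion is \code{c_ij =
#' w_ij^2} and the returned score is its fold average
#' \code{a_i = sum_j c_ij / nFolds}.
#'
#' @param X observations x features matrix.
#' @param y two-class labels (factor or -1/+1).
#' @param C box constraint for the fold fits.
#' @param nFolds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return named numeric vector of per-feature scores.
#' @export
cvAverageScores <- function(X, y, C = 1, nFolds = 10, seed = 1) {
  X <- as.matrix(X)
  yf <- .asClassFactor(y)
  fold <- stratifiedFolds(yf, nFolds, seed)
  out <- .cvPass(X, yf, C, fold)$scores
  names(out) <- colnames(X)
  out
}

.asClassFactor <- function(y) {
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2L) stop("y must contain exactly two classes")
    return(droplevels(y))
  }
  yNum <- as.numeric(y)
  if (length(unique(yNum)) != 2L) stop("y must contain exactly two classes")
  factor(yNum)
}

#' Recursive feature elimination with CV-averaged ranking
#'
#' Per round, the CV-averaged squared-weight score \code{a_i} of every
#' surviving feature is computed and the single feature with the smallest
#' score is deleted (ties: earliest feature in input order); the 10-fold CV
#' accuracy of the survivors is recorded after each deletion. After the full
#' traversal the retained subset is the survivor set at the maximum of the
#' accuracy trajectory, preferring the earliest (largest-subset) round on
#' ties. Fold assignment is stratified, fixed once per call, and seeded.
#'
#' @param x a \linkS4class{FeatureMatrix}, or an observations x features
#'   matrix.
#' @param y ignored when \code{x} is a FeatureMatrix (labels come from it);
#'   otherwise two-class labels.
#' @param C box constraint for all fits (default 1).
#' @param nFolds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @return an \linkS4class{RFEResult}.
#' @export
rfeSelect <- function(x, y = NULL, C = 1, nFolds = 10, seed = 1) {
  if (is(x, "FeatureMatrix")) {
    X <- featureValues(x)
    yf <- factor(featureLabels(x), levels = c("rest", "stimulus"))
  } else {
    X <- as.matrix(x)
    yf <- .asClassFactor(y)
  }
  if (ncol(X) < 2L) stop("at least 2 features required")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  colVar <- apply(X, 2, var)
  if (all(colVar == 0)) stop("degenerate matrix: all feature columns constant")

  featureIds <- colnames(X)
  fold <- stratifiedFolds(yf, nFolds, seed)
  n0 <- length(featureIds)
  surv <- featureIds
  deleted <- character(n0 - 1L)
  trajectory <- numeric(n0 - 1L)
  scoresPerRound <- vector("list", n0 - 1L)
  passScores <- vector("list", n0)  # scores on survivors after k deletions

  pass <- .cvPass(X[, surv, drop = FALSE], yf, C, fold)
  names(pass$scores) <- surv
  passScores[[1L]] <- pass$scores

  for (k in seq_len(n0 - 1L)) {
    scores <- passScores[[k]]
    scoresPerRound[[k]] <- scores
    # smallest score; ties broken by input order
    del <- surv[order(scores, match(surv, featureIds))[1L]]
    deleted[k] <- del
    surv <- setdiff(surv, del)
    pass <- .cvPass(X[, surv, drop = FALSE], yf, C, fold)
    names(pass$scores) <- surv
    passScores[[k + 1L]] <- pass$scores
    trajectory[k] <- pass$accuracy
  }

  kStar <- which.max(trajectory)  # earliest maximum = largest subset
  selected <- setdiff(featureIds, deleted[seq_len(kStar)])
  selScores <- sort(passScores[[kStar + 1L]], decreasing = TRUE)
  selScores <- selScores[names(selScores) %in% selected]

  new("RFEResult",
    featureIds = featureIds,
    eliminationOrder = deleted[seq_len(kStar)],
    fullEliminationOrder = deleted,
    avgScoresPerRound = scoresPerRound,
    accuracyTrajectory = trajectory,
    selectedFeatureIds = names(selScores),
    selectedScores = selScores)
}

#' Write an RFE audit table
#'
#' One row per deletion round: the deleted feature, its score, and the CV
#' accuracy of the survivors after the deletion.
#'
#' @param result an \linkS4class{RFEResult}.
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
writeRfeAudit <- function(result, path) {
  rounds <- seq_along(result@fullEliminationOrder)
  tab <- data.frame(
    round = rounds,
    deleted_feature = result@fullEliminationOrder,
    score = vapply(rounds, function(k)
      result@avgScoresPerRound[[k]][[result@fullEliminationOrder[k]]], 0),
    cv_accuracy = result@accuracyTrajectory
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
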