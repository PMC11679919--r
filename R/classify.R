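# Cost-sensitive RBF-SVM grid search and metric reporting.

#' Construct a classifier configuration
#'
#' @param cGrid candidate box constraints; default c(0.25, 0.5, 1, 2, 4).
#' @param gammaGrid candidate RBF widths; default c(0.5, 1, 2, 4, 8, 15).
#' @param costFalseNegative penalty for predicting the negative class when
#'   the truth is positive (default 2: missing a patient is the costlier
#'   error).
#' @param costFalsePositive penalty for the converse (default 1).
#' @param nFolds CV folds (default 10).
#' @param seed fold seed.
#' @return a \linkS4class{ClassifierConfig}.
#' @export
classifierConfig <- function(cGrid = c(0.25, 0.5, 1, 2, 4),
                             gammaGrid = c(0.5, 1, 2, 4, 8, 15),
                             costFalseNegative = 2, costFalsePositive = 1,
                             nFolds = 10, seed = 1) {
  new("ClassifierConfig", cGrid = cGrid, gammaGrid = gammaGrid,
      costFalseNegative = costFalseNegative,
      costFalsePositive = costFalsePositive,
      nFolds = as.integer(nFolds), seed = as.integer(seed))
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall and F-score with a fixed positive class.
#' A zero denominator (no predicted positives, or no true positives at all)
#' yields 0 for the affected metric, with a warning.
#'
#' @param yTrue,yPred label vectors of equal length.
#' @param positiveClass the label counted as positive.
#' @return list with accuracy, precision, recall, fScore and the TP/FP/FN/TN
#'   counts.
#' @export
evaluateMetrics <- function(yTrue, yPred, positiveClass) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  tp <- sum(yTrue == positiveClass & yPred == positiveClass)
  fp <- sum(yTrue != positiveClass & yPred == positiveClass)
  fn <- sum(yTrue == positiveClass & yPred != positiveClass)
  tn <- sum(yTrue != positiveClass & yPred != positiveClass)
  accuracy <- (tp + tn) / length(yTrue)
  if (tp + fp == 0) { warning("no predicted positives; precision set to 0"); precision <- 0 }
  else precision <- tp / (tp + fp)
  if (tp + fn == 0) { warning("no true positives; recall set to 0"); recall <- 0 }
  else recall <- tp / (tp + fn)
  fScore <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(accuracy = accuracy, precision = precision, recall = recall,
       fScore = fScore, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Cost-sensitive RBF-SVM grid search
#'
#' Stratified k-fold cross-validation over every (C, gamma) pair of the
#' grids, with class-dependent misclassification penalties entering the
#' soft-margin loss as per-class weights on C (the positive class is
#' weighted by \code{costFalseNegative}, the negative class by
#' \code{costFalsePositive}). The selected pair minimizes the mean CV
#' misclassification cost
#' \code{(FN * costFN + FP * costFP) / n} — so cost sensitivity affects
#' model selection as well as fitting — with ties broken by higher recall,
#' then smaller C, then smaller gamma. Metrics are CV-pooled over the
#' held-out folds of the selected pair.
#'
#' @param X observations x features matrix.
#' @param y two-class labels.
#' @param config a \linkS4class{ClassifierConfig}.
#' @param positiveClass label treated as positive (default "patient", or the
#'   second factor level when absent).
#' @return a \linkS4class{ClassificationReport}.
#' @export
gridSearchCslSvm <- function(X, y, config = classifierConfig(),
                             positiveClass = NULL) {
  X <- as.matrix(X)
  yf <- .asClassFactor(y)
  if (is.null(positiveClass))
    positiveClass <- if ("patient" %in% levels(yf)) "patient" else levels(yf)[2]
  if (!positiveClass %in% levels(yf)) stop("positiveClass not present in y")
  negativeClass <- setdiff(levels(yf), positiveClass)

  fold <- stratifiedFolds(yf, config@nFolds, config@seed)
  # per-class penalties enter as weights on C; normalized by the smaller
  # cost so only the cost RATIO matters and equal costs reduce exactly to
  # the standard (unweighted) SVM
  costs <- c(config@costFalseNegative, config@costFalsePositive)
  weights <- costs / min(costs)
  names(weights) <- c(positiveClass, negativeClass)

  grid <- expand.grid(C = config@cGrid, gamma = config@gammaGrid)
  results <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pred <- factor(rep(NA_character_, length(yf)), levels = levels(yf))
    for (f in seq_len(config@nFolds)) {
      tr <- fold != f
      if (all(tr)) next  # fold received no samples (n < nFolds per class)
      m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      cost = grid$C[g], gamma = grid$gamma[g],
                      class.weights = weights, scale = FALSE)
      pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
    }
    fnCount <- sum(yf == positiveClass & pred != positiveClass)
    fpCount <- sum(yf != positiveClass & pred == positiveClass)
    cost <- (fnCount * config@costFalseNegative +
             fpCount * config@costFalsePositive) / length(yf)
    recall <- suppressWarnings(
      evaluateMetrics(yf, pred, positiveClass)$recall)
    results[[g]] <- list(pred = pred, cost = cost, recall = recall)
  }

  costs <- vapply(results, `[[`, 0, "cost")
  recalls <- vapply(results, `[[`, 0, "recall")
  best <- order(costs, -recalls, grid$C, grid$gamma)[1L]
  predBest <- results[[best]]$pred

  met <- suppressWarnings(evaluateMetrics(yf, predBest, positiveClass))
  perFold <- do.call(rbind, lapply(seq_len(config@nFolds), function(f) {
    mf <- suppressWarnings(
      evaluateMetrics(yf[fold == f], predBest[fold == f], positiveClass))
    data.frame(fold = f, n = sum(fold == f), accuracy = mf$accuracy,
               precision = mf$precision, recall = mf$recall,
               fScore = mf$fScore)
  }))

  new("ClassificationReport",
    accuracy = met$accuracy, precision = met$precision, recall = met$recall,
    fScore = met$fScore, bestC = grid$C[best], bestGamma = grid$gamma[best],
    perFoldMetrics = perFold, positiveClass = positiveClass)
}

#' Per-subject features under an atlas
#'
#' For each region touched by the atlas (in increasing region-id order), the
#' mean series over that region's atlas voxels is reduced to one number:
#' its ALFF over the map's band (\code{mode = "region_alff"}, the default,
#' consistent with the resting-state emphasis of the group stage) or its
#' time mean (\code{mode = "voxel_mean"}).
#'
#' @param record a \linkS4class{SubjectRecord}.
#' @param atlas an \linkS4class{EmotionAtlas}.
#' @param parcellation the \linkS4class{Parcellation} of the record; must
#'   match the atlas grid.
#' @param mode feature reduction, "region_alff" or "voxel_mean".
#' @param bandHz ALFF band (default 0.01-0.08 Hz).
#' @return named numeric feature vector, one entry per touched region.
#' @export
atlasSubjectFeatures <- function(record, atlas, parcellation,
                                 mode = c("region_alff", "voxel_mean"),
                                 bandHz = c(0.01, 0.08)) {
  mode <- match.arg(mode)
  dims <- dim(labelVolume(parcellation))
  if (!identical(dims, dim(labelVolume(atlas@parcellation))))
    stop("atlas and parcellation grids differ")
  if (!identical(dims, dim(record@series)[1:3]))
    stop("record grid does not match the parcellation")

  prov <- atlasProvenance(atlas)
  flat <- flattenSeries(record@series)
  regions <- sort(unique(prov$hostRegion))
  out <- vapply(regions, function(r) {
    vx <- as.matrix(prov[prov$hostRegion == r, c("i", "j", "k")])
    lin <- ijkToLinear(vx, dims)
    s <- colMeans(flat[lin, , drop = FALSE])
    if (mode == "region_alff") computeAlff(s, record@trS, bandHz)
    else mean(s)
  }, 0)
  names(out) <- paste0("region_", regions)
  out
}

#' Cohort feature matrix under an atlas
#'
#' @param cohort list of \linkS4class{SubjectRecord}.
#' @param atlas an \linkS4class{EmotionAtlas} (or a list of atlases whose
#'   feature vectors are concatenated, e.g. positive + negative).
#' @param parcellation a \linkS4class{Parcellation}.
#' @inheritParams atlasSubjectFeatures
#' @return list with \code{X} (subjects x features) and \code{y} (group
#'   factor).
#' @export
cohortAtlasFeatures <- function(cohort, atlas, parcellation,
                                mode = "region_alff", bandHz = c(0.01, 0.08)) {
  atlases <- if (is(atlas, "EmotionAtlas")) list(atlas) else atlas
  X <- t(vapply(cohort, function(s) {
    unlist(lapply(seq_along(atlases), function(a) {
      v <- atlasSubjectFeatures(s, atlases[[a]], parcellation, mode, bandHz)
      names(v) <- paste0("a", a, "_", names(v))
      v
    }))
  }, numeric(sum(vapply(atlases, nRegionsTouched, 1L)))))
  rownames(X) <- vapply(cohort, subjectId, "")
  y <- factor(vapply(cohort, subjectGroup, ""))
  list(X = X, y = y)
}
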