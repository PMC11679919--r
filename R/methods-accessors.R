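# Accessor and show methods.

#' @rdname Parcellation-class
#' @aliases labelVolume,Parcellation-method
setMethod("labelVolume", "Parcellation", function(x) x@labelVolume)

#' @rdname Parcellation-class
setMethod("voxelSize", "Parcellation", function(x) x@voxelSizeMm)

#' @rdname Parcellation-class
setMethod("originMm", "Parcellation", function(x) x@originMm)

#' @rdname Parcellation-class
setMethod("regionIds", "Parcellation", function(x) x@regionIds)

#' @rdname Parcellation-class
setMethod("nRegions", "Parcellation", function(x) length(x@regionIds))

#' @rdname Parcellation-class
setMethod("regionVoxels", "Parcellation", function(x, region) {
  if (!region %in% x@regionIds) stop("unknown region id: ", region)
  which(x@labelVolume == region, arr.ind = TRUE)
})

setMethod("show", "Parcellation", function(object) {
  d <- dim(object@labelVolume)
  cat("Parcellation:", paste(d, collapse = " x "), "grid,",
      length(object@regionIds), "regions,",
      sum(object@labelVolume > 0), "foreground voxels\n")
  cat("  voxel size:", paste(object@voxelSizeMm, collapse = " x "), "mm\n")
})

# world-mm coordinate of 1-based voxel indices
voxelToWorld <- function(parcellation, ijk) {
  sweep(sweep(ijk - 1, 2, voxelSize(parcellation), "*"), 2,
        originMm(parcellation), "+")
}

#' @rdname SubjectRecord-class
setMethod("seriesData", "SubjectRecord", function(x) x@series)

#' @rdname SubjectRecord-class
setMethod("subjectId", "SubjectRecord", function(x) x@subjectId)

#' @rdname SubjectRecord-class
setMethod("subjectGroup", "SubjectRecord", function(x) x@group)

setMethod("show", "SubjectRecord", function(object) {
  d <- dim(object@series)
  cat("SubjectRecord", object@subjectId, sprintf("(%s, %s, %.0f y):", object@group,
      object@sex, object@age),
      paste(d[1:3], collapse = " x "), "grid,", d[4], "volumes @ TR",
      object@trS, "s\n")
})

#' @rdname TaskBlock-class
setMethod("stimulusVolumes", "TaskBlock", function(x) x@stimulusVolumes)

#' @rdname TaskBlock-class
setMethod("recoveryVolumes", "TaskBlock", function(x) x@recoveryVolumes)

#' @rdname TaskBlock-class
setMethod("blockCategory", "TaskBlock", function(x) x@category)

setMethod("show", "TaskBlock", function(object) {
  cat("TaskBlock:", object@subjectId, object@category, "block",
      object@blockIndex, "\n  stimulus volumes:",
      paste(object@stimulusIndices, collapse = ","), " recovery volumes:",
      paste(object@recoveryIndices, collapse = ","), "\n")
})

#' @rdname FeatureMatrix-class
setMethod("featureLabels", "FeatureMatrix", function(x)
  as.character(SummarizedExperiment::colData(x)$label))

#' @rdname FeatureMatrix-class
setMethod("featureLevel", "FeatureMatrix", function(x)
  S4Vectors::metadata(x)$level)

#' @rdname FeatureMatrix-class
setMethod("featureValues", "FeatureMatrix", function(x)
  t(SummarizedExperiment::assay(x, "activation")))

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix (", S4Vectors::metadata(object)$level, " level): ",
      ncol(object), " observations x ", nrow(object), " features, category ",
      S4Vectors::metadata(object)$category %||% "?", "\n", sep = "")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname RFEResult-class
setMethod("selectedFeatureIds", "RFEResult", function(x) x@selectedFeatureIds)

#' @rdname RFEResult-class
setMethod("eliminationOrder", "RFEResult", function(x) x@eliminationOrder)

#' @rdname RFEResult-class
setMethod("accuracyTrajectory", "RFEResult", function(x) x@accuracyTrajectory)

setMethod("show", "RFEResult", function(object) {
  cat("RFEResult:", length(object@featureIds), "features ->",
      length(object@selectedFeatureIds), "selected; peak CV accuracy",
      sprintf("%.3f", max(object@accuracyTrajectory)), "\n")
})

#' @rdname EmotionAtlas-class
setMethod("subroiVoxels", "EmotionAtlas", function(x) x@subroiVoxels)

#' @rdname EmotionAtlas-class
setMethod("externalVoxels", "EmotionAtlas", function(x) x@externalVoxels)

#' @rdname EmotionAtlas-class
setMethod("atlasPolarity", "EmotionAtlas", function(x) x@polarity)

#' @rdname EmotionAtlas-class
setMethod("nRegionsTouched", "EmotionAtlas", function(x) {
  length(unique(c(as.integer(names(x@subroiVoxels)), x@externalHosts)))
})

#' @rdname EmotionAtlas-class
setMethod("atlasVoxels", "EmotionAtlas", function(x) {
  vx <- do.call(rbind, c(unname(x@subroiVoxels), list(x@externalVoxels)))
  colnames(vx) <- c("i", "j", "k")
  vx
})

#' @rdname EmotionAtlas-class
setMethod("atlasMask", "EmotionAtlas", function(x) {
  m <- array(0L, dim(labelVolume(x@parcellation)))
  vx <- atlasVoxels(x)
  if (nrow(vx)) m[vx] <- 1L
  m
})

setMethod("show", "EmotionAtlas", function(object) {
  nSub <- sum(vapply(object@subroiVoxels, nrow, 1L))
  cat("EmotionAtlas (", object@polarity, "): ", nSub,
      " sub-ROI voxels in ", length(object@subroiVoxels), " regions + ",
      nrow(object@externalVoxels), " external voxels; ",
      nRegionsTouched(object), " regions touched\n", sep = "")
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf(
    "ClassificationReport (positive = %s): accuracy %.3f, precision %.3f, recall %.3f, F %.3f\n",
    object@positiveClass, object@accuracy, object@precision, object@recall,
    object@fScore))
  cat("  selected C =", object@bestC, ", gamma =", object@bestGamma, "\n")
})

#' @rdname ALFFMap-class
setMethod("alffValues", "ALFFMap", function(x) x@values)

setMethod("show", "ALFFMap", function(object) {
  cat("ALFFMap:", paste(dim(object@values), collapse = " x "),
      "grid, band", paste(object@bandHz, collapse = "-"), "Hz @ TR",
      object@trS, "s\n")
})

#' @rdname GroupComparison-class
setMethod("clusterTable", "GroupComparison", function(x) x@clusters)

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison: q =", object@qThreshold, "(BH-FDR), covariates:",
      paste(object@covariates, collapse = ", "), "\n  ",
      nrow(object@clusters), "significant clusters,",
      sum(object@clusters$nVoxels), "voxels\n")
})
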