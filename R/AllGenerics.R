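#' @rdname Parcellation-class
#' @param object,x an object.
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))

#' @rdname Parcellation-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname Parcellation-class
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))

#' @rdname Parcellation-class
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname Parcellation-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname Parcellation-class
#' @param region integer region id.
#' @export
setGeneric("regionVoxels", function(x, region) standardGeneric("regionVoxels"))

#' @rdname SubjectRecord-class
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @rdname SubjectRecord-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname SubjectRecord-class
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))

#' @rdname TaskBlock-class
#' @export
setGeneric("stimulusVolumes", function(x) standardGeneric("stimulusVolumes"))

#' @rdname TaskBlock-class
#' @export
setGeneric("recoveryVolumes", function(x) standardGeneric("recoveryVolumes"))

#' @rdname TaskBlock-class
#' @export
setGeneric("blockCategory", function(x) standardGeneric("blockCategory"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureLevel", function(x) standardGeneric("featureLevel"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname RFEResult-class
#' @export
setGeneric("selectedFeatureIds", function(x) standardGeneric("selectedFeatureIds"))

#' @rdname RFEResult-class
#' @export
setGeneric("eliminationOrder", function(x) standardGeneric("eliminationOrder"))

#' @rdname RFEResult-class
#' @export
setGeneric("accuracyTrajectory", function(x) standardGeneric("accuracyTrajectory"))

#' @rdname EmotionAtlas-class
#' @export
setGeneric("subroiVoxels", function(x) standardGeneric("subroiVoxels"))

#' @rdname EmotionAtlas-class
#' @export
setGeneric("externalVoxels", function(x) standardGeneric("externalVoxels"))

#' @rdname EmotionAtlas-class
#' @export
setGeneric("atlasPolarity", function(x) standardGeneric("atlasPolarity"))

#' @rdname EmotionAtlas-class
#' @export
setGeneric("nRegionsTouched", function(x) standardGeneric("nRegionsTouched"))

#' @rdname EmotionAtlas-class
#' @export
setGeneric("atlasVoxels", function(x) standardGeneric("atlasVoxels"))

#' @rdname EmotionAtlas-class
#' @export
setGeneric("atlasMask", function(x) standardGeneric("atlasMask"))

#' @rdname ALFFMap-class
#' @export
setGeneric("alffValues", function(x) standardGeneric("alffValues"))

#' @rdname GroupComparison-class
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
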