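#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor fft lm.fit mvfft p.adjust pt rnorm runif sd var
#' @importFrom utils head write.table read.delim
NULL

#' Parcellation of a voxel grid into labeled regions
#'
#' A 3D integer label volume together with its voxel geometry. Label 0 is
#' background; labels \code{1..R} are spatially contiguous regions. World
#' coordinates of voxel (i,j,k) (1-based) are
#' \code{originMm + (c(i,j,k) - 1) * voxelSizeMm}.
#'
#' @slot labelVolume 3D integer array of region labels (0 = background).
#' @slot voxelSizeMm numeric(3), physical voxel edge lengths in mm.
#' @slot originMm numeric(3), world coordinate of voxel (1,1,1) in mm.
#' @slot regionIds integer vector of the R region labels present.
#'
#' @exportClass Parcellation
setClass("Parcellation",
  representation(
    labelVolume = "array",
    voxelSizeMm = "numeric",
    originMm = "numeric",
    regionIds = "integer"
  )
)

setValidity("Parcellation", function(object) {
  msg <- NULL
  if (length(dim(object@labelVolume)) != 3L)
    msg <- c(msg, "labelVolume must be a 3D array")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be 3 positive numbers")
  if (length(object@originMm) != 3L)
    msg <- c(msg, "originMm must have length 3")
  labs <- object@labelVolume
  if (any(labs < 0) || any(labs != round(labs)))
    msg <- c(msg, "labels must be non-negative integers")
  if (length(object@regionIds) < 1L)
    msg <- c(msg, "at least one region required")
  present <- sort(unique(as.integer(labs[labs > 0])))
  if (!setequal(present, object@regionIds))
    msg <- c(msg, "every region id must occupy at least one voxel and vice versa")
  if (is.null(msg)) TRUE else msg
})

#' Block-design task paradigm
#'
#' Ordered rest/stimulus segments of a task run. The default instance is a
#' 20 s rest lead-in followed by six 40 s cycles (20 s emotional-picture
#' stimulation alternating positive/negative, each followed by 20 s rest),
#' i.e. 240 s of formal experiment at TR = 2 s.
#'
#' @slot trS repetition time in seconds.
#' @slot leadInS initial rest duration in seconds.
#' @slot segments data.frame with columns \code{condition}
#'   (one of "rest", "positive", "negative") and \code{durationS}.
#'
#' @exportClass TaskParadigm
setClass("TaskParadigm",
  representation(
    trS = "numeric",
    leadInS = "numeric",
    segments = "data.frame"
  )
)

setValidity("TaskParadigm", function(object) {
  msg <- NULL
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  seg <- object@segments
  if (!all(c("condition", "durationS") %in% names(seg)))
    msg <- c(msg, "segments needs columns condition, durationS")
  else {
    if (!all(seg$condition %in% c("rest", "positive", "negative")))
      msg <- c(msg, "segment conditions must be rest/positive/negative")
    durs <- c(object@leadInS, seg$durationS)
    if (any(durs <= 0) || any(abs(durs / object@trS - round(durs / object@trS)) > 1e-9))
      msg <- c(msg, "all durations must be positive integer multiples of trS")
  }
  if (is.null(msg)) TRUE else msg
})

#' Ground truth for the synthetic generators
#'
#' Encodes what the synthetic task and resting-state generators implant, so
#' downstream recovery can be scored: which regions (and what fraction of
#' their voxels) carry the stimulus-locked effect per emotion category, the
#' effect size and hemodynamic onset lag, and the band-limited sinusoids
#' implanted per group in the resting cohort.
#'
#' @slot activeRegionIds named list with elements \code{positive} and
#'   \code{negative}: integer region ids carrying the stimulus effect.
#' @slot activeVoxelFraction fraction (0, 1] of each active region's voxels
#'   carrying the effect (voxels are taken deterministically in linear-index
#'   order so truth is recoverable).
#' @slot effectSize stimulus-window BOLD increment, arbitrary units.
#' @slot hemodynamicDelayS onset lag of the effect in seconds.
#' @slot alffClusters list of implants for the resting cohort; each element a
#'   list with \code{group} ("patient"/"control"), \code{voxels} (n x 3
#'   integer matrix of 1-based i,j,k), \code{amplitude}, \code{freqHz}.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    activeRegionIds = "list",
    activeVoxelFraction = "numeric",
    effectSize = "numeric",
    hemodynamicDelayS = "numeric",
    alffClusters = "list"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- NULL
  if (!all(c("positive", "negative") %in% names(object@activeRegionIds)))
    msg <- c(msg, "activeRegionIds needs elements 'positive' and 'negative'")
  f <- object@activeVoxelFraction
  if (length(f) != 1L || f <= 0 || f > 1)
    msg <- c(msg, "activeVoxelFraction must be in (0, 1]")
  for (cl in object@alffClusters) {
    if (!all(c("group", "voxels", "amplitude", "freqHz") %in% names(cl)))
      msg <- c(msg, "each alff cluster needs group, voxels, amplitude, freqHz")
    else {
      if (!cl$group %in% c("patient", "control"))
        msg <- c(msg, "cluster group must be 'patient' or 'control'")
      if (cl$freqHz <= 0)
        msg <- c(msg, "cluster frequency must be positive")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' One subject's 4D fMRI run with phenotype
#'
#' @slot subjectId character scalar.
#' @slot group one of "task", "patient", "control".
#' @slot age years.
#' @slot sex "M" or "F".
#' @slot series 4D numeric array (3 spatial axes x time).
#' @slot trS repetition time in seconds.
#'
#' @exportClass SubjectRecord
setClass("SubjectRecord",
  representation(
    subjectId = "character",
    group = "character",
    age = "numeric",
    sex = "character",
    series = "array",
    trS = "numeric"
  )
)

setValidity("SubjectRecord", function(object) {
  msg <- NULL
  if (length(dim(object@series)) != 4L)
    msg <- c(msg, "series must be a 4D array")
  if (!object@group %in% c("task", "patient", "control"))
    msg <- c(msg, "group must be task/patient/control")
  if (!object@sex %in% c("M", "F")) msg <- c(msg, "sex must be 'M' or 'F'")
  if (object@age <= 0) msg <- c(msg, "age must be positive")
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  if (is.null(msg)) TRUE else msg
})

#' One task block: stimulus window plus recovery window
#'
#' A 40 s stimulus+rest cycle yields one block: the five volumes acquired
#' 10-18 s after stimulus onset (stimulus state, where the delayed BOLD
#' response is fully developed) and the five volumes 30-38 s after onset
#' (recovery to baseline).
#'
#' @slot subjectId character scalar.
#' @slot category "positive" or "negative".
#' @slot blockIndex integer index of the block within its subject/category.
#' @slot stimulusVolumes 4D array, 5 volumes of stimulus state.
#' @slot recoveryVolumes 4D array, 5 volumes of recovery state.
#' @slot stimulusIndices integer(5), volume indices in the source run.
#' @slot recoveryIndices integer(5), volume indices in the source run.
#'
#' @exportClass TaskBlock
setClass("TaskBlock",
  representation(
    subjectId = "character",
    category = "character",
    blockIndex = "integer",
    stimulusVolumes = "array",
    recoveryVolumes = "array",
    stimulusIndices = "integer",
    recoveryIndices = "integer"
  )
)

setValidity("TaskBlock", function(object) {
  msg <- NULL
  if (!object@category %in% c("positive", "negative"))
    msg <- c(msg, "category must be 'positive' or 'negative'")
  ds <- dim(object@stimulusVolumes); dr <- dim(object@recoveryVolumes)
  if (length(ds) != 4L || ds[4] != 5L) msg <- c(msg, "stimulusVolumes must hold 5 volumes")
  if (length(dr) != 4L || dr[4] != 5L) msg <- c(msg, "recoveryVolumes must hold 5 volumes")
  if (length(object@stimulusIndices) == 5L && length(object@recoveryIndices) == 5L &&
      max(object@stimulusIndices) >= min(object@recoveryIndices))
    msg <- c(msg, "stimulus window must precede recovery window")
  if (is.null(msg)) TRUE else msg
})

#' Observation x feature matrix for selection
#'
#' Extends \linkS4class{SummarizedExperiment}: the single assay
#' \code{"activation"} holds features (regions or voxels) as rows and
#' block-state observations as columns; \code{colData} carries the per
#' observation state label ("stimulus"/"rest"), subject and block index.
#' All entries lie in [0, 1] by construction (min-max normalized window
#' means) and the label classes are balanced: each block contributes one
#' stimulus and one rest observation.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  contains = "SummarizedExperiment"
)

setValidity("FeatureMatrix", function(object) {
  msg <- NULL
  if (!"activation" %in% SummarizedExperiment::assayNames(object))
    return("assay 'activation' required")
  a <- SummarizedExperiment::assay(object, "activation")
  if (any(a < -1e-12 | a > 1 + 1e-12))
    msg <- c(msg, "all entries must lie in [0, 1]")
  cd <- SummarizedExperiment::colData(object)
  if (!"label" %in% names(cd))
    msg <- c(msg, "colData needs a 'label' column")
  else {
    tab <- table(cd$label)
    if (!setequal(names(tab), c("stimulus", "rest")) || tab[["stimulus"]] != tab[["rest"]])
      msg <- c(msg, "labels must be balanced stimulus/rest")
  }
  if (!identical(S4Vectors::metadata(object)$level %in% c("roi", "voxel"), TRUE))
    msg <- c(msg, "metadata 'level' must be 'roi' or 'voxel'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Fitted soft-margin linear SVM
#'
#' Wraps the libsvm solution of the soft-margin dual with the primal weight
#' vector recovered as \code{w = sum_k alpha_k y_k x_k} and bias \code{b};
#' the decision function is \code{D(x) = w . x + b}, oriented so positive
#' decision values predict the +1 class.
#'
#' @slot w numeric per-feature weight vector.
#' @slot b numeric bias.
#' @slot alphas numeric per-sample dual coefficients in [0, C].
#' @slot supportIndices integer indices of samples with alpha > 0.
#' @slot cost box constraint C used for the fit.
#'
#' @exportClass LinearSVMModel
setClass("LinearSVMModel",
  representation(
    w = "numeric",
    b = "numeric",
    alphas = "numeric",
    supportIndices = "integer",
    cost = "numeric"
  )
)

#' Result of CV-averaged SVM-RFE
#'
#' @slot featureIds character: initial feature ids, in input order.
#' @slot eliminationOrder character: features deleted, in deletion order,
#'   up to the selected round (so that
#'   \code{length(eliminationOrder) + length(selectedFeatureIds)} equals the
#'   initial feature count).
#' @slot fullEliminationOrder character: the complete deletion sequence of
#'   the traversal (audit).
#' @slot avgScoresPerRound list: per deletion round, the named vector of
#'   CV-averaged ranking scores of the surviving features at that round.
#' @slot accuracyTrajectory numeric: 10-fold CV accuracy of the survivors
#'   after each deletion (length = initial feature count - 1).
#' @slot selectedFeatureIds character: survivors at the trajectory maximum
#'   (earliest maximum, i.e. the largest subset among ties).
#' @slot selectedScores named numeric: CV-averaged scores of the selected
#'   features, computed on the selected subset itself.
#'
#' @exportClass RFEResult
setClass("RFEResult",
  representation(
    featureIds = "character",
    eliminationOrder = "character",
    fullEliminationOrder = "character",
    avgScoresPerRound = "list",
    accuracyTrajectory = "numeric",
    selectedFeatureIds = "character",
    selectedScores = "numeric"
  )
)

setValidity("RFEResult", function(object) {
  msg <- NULL
  n0 <- length(object@featureIds)
  if (length(object@eliminationOrder) + length(object@selectedFeatureIds) != n0)
    msg <- c(msg, "elimination order and selected set must partition the features")
  if (length(object@accuracyTrajectory) != n0 - 1L)
    msg <- c(msg, "accuracy trajectory must have one entry per deletion round")
  if (is.null(msg)) TRUE else msg
})

#' Voxel-level emotion atlas
#'
#' Characteristic sub-ROI voxels (survivors of voxel-level SVM-RFE inside
#' each characteristic region) plus external voxels recruited from
#' non-characteristic regions by functional connectivity, with region
#' provenance. Exportable as a binary NIfTI mask.
#'
#' @slot polarity "positive" or "negative".
#' @slot subroiVoxels named list: region id -> n x 3 integer matrix of
#'   voxel (i,j,k) coordinates of that region's characteristic sub-ROI.
#' @slot externalVoxels n x 3 integer matrix of recruited external voxels.
#' @slot externalHosts integer vector: host region of each external voxel.
#' @slot parcellation the \linkS4class{Parcellation} the atlas lives on.
#'
#' @exportClass EmotionAtlas
setClass("EmotionAtlas",
  representation(
    polarity = "character",
    subroiVoxels = "list",
    externalVoxels = "matrix",
    externalHosts = "integer",
    parcellation = "Parcellation"
  )
)

setValidity("EmotionAtlas", function(object) {
  msg <- NULL
  if (!object@polarity %in% c("positive", "negative"))
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  if (nrow(object@externalVoxels) != length(object@externalHosts))
    msg <- c(msg, "one host region per external voxel required")
  labs <- object@parcellation@labelVolume
  hosts <- as.integer(names(object@subroiVoxels))
  for (h in seq_along(object@subroiVoxels)) {
    vx <- object@subroiVoxels[[h]]
    if (nrow(vx) && any(labs[vx] != hosts[h]))
      msg <- c(msg, "sub-ROI voxels must lie inside their host region")
  }
  if (nrow(object@externalVoxels)) {
    extLab <- labs[object@externalVoxels]
    if (any(extLab %in% hosts))
      msg <- c(msg, "external voxels must not lie in characteristic regions")
  }
  if (is.null(msg)) TRUE else msg
})

#' Configuration for cost-sensitive RBF-SVM grid search
#'
#' Defaults follow the printed grids: C in {0.25, 0.5, 1, 2, 4} and gamma in
#' {0.5, 1, 2, 4, 8, 15}, 10-fold stratified CV. Cost sensitivity enters as
#' class-dependent penalties on the soft-margin loss: missing a patient
#' (false negative) costs more than a false alarm by default, because
#' misdiagnosing depression as healthy carries the greater clinical risk.
#'
#' @slot cGrid numeric candidate box constraints.
#' @slot gammaGrid numeric candidate RBF widths.
#' @slot costFalseNegative penalty for predicting the negative class when
#'   truth is positive (default 2).
#' @slot costFalsePositive penalty for the converse (default 1).
#' @slot nFolds integer number of CV folds.
#' @slot seed integer fold seed.
#'
#' @exportClass ClassifierConfig
setClass("ClassifierConfig",
  representation(
    cGrid = "numeric",
    gammaGrid = "numeric",
    costFalseNegative = "numeric",
    costFalsePositive = "numeric",
    nFolds = "integer",
    seed = "integer"
  )
)

setValidity("ClassifierConfig", function(object) {
  msg <- NULL
  if (length(object@cGrid) < 1L || length(object@gammaGrid) < 1L)
    msg <- c(msg, "grids must be non-empty")
  if (object@costFalseNegative <= 0 || object@costFalsePositive <= 0)
    msg <- c(msg, "costs must be positive")
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be at least 2")
  if (is.null(msg)) TRUE else msg
})

#' Classification report
#'
#' CV-pooled accuracy, precision, recall and F-score (positive class fixed
#' by the caller, "patient" in the resting-state stage), the selected grid
#' pair, and per-fold metrics.
#'
#' @slot accuracy,precision,recall,fScore proportions in [0, 1].
#' @slot bestC,bestGamma selected grid values.
#' @slot perFoldMetrics data.frame of per-fold counts and metrics.
#' @slot positiveClass label treated as positive.
#'
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(
    accuracy = "numeric",
    precision = "numeric",
    recall = "numeric",
    fScore = "numeric",
    bestC = "numeric",
    bestGamma = "numeric",
    perFoldMetrics = "data.frame",
    positiveClass = "character"
  )
)

setValidity("ClassificationReport", function(object) {
  m <- c(object@accuracy, object@precision, object@recall, object@fScore)
  msg <- NULL
  if (any(m < -1e-12 | m > 1 + 1e-12)) msg <- c(msg, "metrics must lie in [0, 1]")
  p <- object@precision; r <- object@recall; f <- object@fScore
  fExp <- if (p + r > 0) 2 * p * r / (p + r) else 0
  if (abs(f - fExp) > 1e-12) msg <- c(msg, "F-score must be the harmonic mean of precision and recall")
  if (is.null(msg)) TRUE else msg
})

#' Voxelwise ALFF map
#'
#' @slot values 3D non-negative array aligned to the parcellation grid.
#' @slot bandHz numeric(2) low/high band edges in Hz.
#' @slot trS sampling interval in seconds.
#'
#' @exportClass ALFFMap
setClass("ALFFMap",
  representation(
    values = "array",
    bandHz = "numeric",
    trS = "numeric"
  )
)

setValidity("ALFFMap", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be a 3D array")
  if (any(object@values < 0, na.rm = TRUE)) msg <- c(msg, "ALFF values must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Two-group voxelwise comparison
#'
#' Covariate-adjusted two-sample t statistics and p values per voxel, the
#' BH-FDR threshold applied, and the connected clusters of surviving voxels.
#'
#' @slot tMap,pMap 3D arrays (NA outside the tested voxels).
#' @slot qThreshold FDR level.
#' @slot covariates character: nuisance covariates removed.
#' @slot clusters data.frame: one row per cluster (nVoxels, sizeMm3, peak
#'   voxel and world coordinates, peakIntensity, memberRegions).
#'
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    tMap = "array",
    pMap = "array",
    qThreshold = "numeric",
    covariates = "character",
    clusters = "data.frame"
  )
)
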