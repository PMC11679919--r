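# Feature collection: min-max normalized window means at region or voxel
# level, assembled into balanced stimulus/rest observation matrices.

#' Min-max normalize a window
#'
#' \code{(x - min) / (max - min)} elementwise; a constant window maps to all
#' zeros (the convention that keeps every feature entry inside [0, 1]).
#'
#' @param window numeric vector (one 5-volume window).
#' @return normalized vector of the same length.
#' @export
minmaxNormalize <- function(window) {
  if (length(window) == 0L) stop("empty window")
  rng <- range(window)
  if (rng[1] == rng[2]) return(rep(0, length(window)))
  (window - rng[1]) / (rng[2] - rng[1])
}

# rows of `m` (features x block time points) min-max normalized over the
# whole block, then averaged over the columns of one state window
normalizedWindowMeans <- function(m, stateCols) {
  rr <- rowRange(m)
  span <- rr$max - rr$min
  out <- rowMeans(m[, stateCols, drop = FALSE] - rr$min) / span
  out[span == 0] <- 0
  out
}

# region-mean time series for a window array; returns R x T matrix in
# regionIds order
regionMeanSeries <- function(windowArray, parcellation) {
  flat <- flattenSeries(windowArray)
  labs <- as.vector(labelVolume(parcellation))
  fg <- labs > 0
  sums <- rowsum(flat[fg, , drop = FALSE], labs[fg])
  counts <- as.vector(table(labs[fg]))
  m <- sums / counts
  m[as.character(regionIds(parcellation)), , drop = FALSE]
}

#' Per-block state features
#'
#' Normalization is per region (or per voxel) per task block, over the
#' block's combined 10-point series: the five stimulus-window and five
#' recovery-window values are min-max normalized jointly, then the five
#' values of the requested state are averaged. Normalizing across both
#' windows preserves the stimulus-rest level contrast inside [0, 1]
#' (normalizing each window on its own would erase a constant elevation).
#' At \code{level = "roi"} the region's voxel-mean series is used (F = R);
#' at \code{level = "voxel"} each voxel of the scope regions is treated
#' individually (F = number of voxels in scope).
#'
#' @param block a \linkS4class{TaskBlock}.
#' @param parcellation a \linkS4class{Parcellation}.
#' @param state "stimulus" or "rest" (the recovery window).
#' @param level "roi" or "voxel".
#' @param voxelScope integer region ids delimiting the voxel-level feature
#'   space; required when \code{level = "voxel"}.
#' @return named numeric feature vector.
#' @export
blockStateFeatures <- function(block, parcellation, state = c("stimulus", "rest"),
                               level = c("roi", "voxel"), voxelScope = NULL) {
  state <- match.arg(state)
  level <- match.arg(level)
  stateCols <- if (state == "stimulus") 1:5 else 6:10
  if (level == "roi") {
    m <- cbind(regionMeanSeries(block@stimulusVolumes, parcellation),
               regionMeanSeries(block@recoveryVolumes, parcellation))
    out <- normalizedWindowMeans(m, stateCols)
    names(out) <- paste0("region_", regionIds(parcellation))
    return(out)
  }
  if (is.null(voxelScope) || length(voxelScope) == 0L)
    stop("voxel-level features need a non-empty voxelScope")
  if (!all(voxelScope %in% regionIds(parcellation)))
    stop("unknown region id in voxelScope")
  vx <- scopeVoxels(parcellation, voxelScope)
  m <- cbind(flattenSeries(block@stimulusVolumes)[vx$lin, , drop = FALSE],
             flattenSeries(block@recoveryVolumes)[vx$lin, , drop = FALSE])
  out <- normalizedWindowMeans(m, stateCols)
  names(out) <- vx$ids
  out
}

# voxel coordinates, linear indices and feature ids of a region scope, in a
# fixed (linear-index) order
scopeVoxels <- function(parcellation, voxelScope) {
  labs <- labelVolume(parcellation)
  lin <- which(array(labs %in% voxelScope, dim(labs)))
  ijk <- linearToIjk(lin, dim(labs))
  list(lin = lin, ijk = ijk,
       ids = sprintf("v_%d_%d_%d", ijk[, 1], ijk[, 2], ijk[, 3]))
}

#' Assemble the observation x feature matrix of one category
#'
#' One stimulus-state and one rest-state observation per block: 63 blocks of
#' a category yield a 126-observation matrix (126 x 246 at region level
#' under a 246-region template).
#'
#' @param blocks list of \linkS4class{TaskBlock}, all of one category.
#' @param parcellation a \linkS4class{Parcellation}.
#' @param category "positive" or "negative"; blocks are checked against it.
#' @param level "roi" or "voxel".
#' @param voxelScope region ids for voxel-level features.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
assembleFeatureMatrix <- function(blocks, parcellation,
                                  category = c("positive", "negative"),
                                  level = c("roi", "voxel"),
                                  voxelScope = NULL) {
  category <- match.arg(category)
  level <- match.arg(level)
  if (length(blocks) == 0L) stop("no blocks supplied")
  cats <- vapply(blocks, blockCategory, "")
  if (!all(cats == category))
    stop("blocks of mixed or wrong category; expected all '", category, "'")

  feats <- lapply(blocks, function(b) {
    list(stim = blockStateFeatures(b, parcellation, "stimulus", level, voxelScope),
         rest = blockStateFeatures(b, parcellation, "rest", level, voxelScope))
  })
  stim <- do.call(cbind, lapply(feats, `[[`, "stim"))
  rest <- do.call(cbind, lapply(feats, `[[`, "rest"))
  assayMat <- cbind(stim, rest)
  labels <- rep(c("stimulus", "rest"), each = length(blocks))
  subjects <- vapply(blocks, function(b) b@subjectId, "")
  blockIdx <- vapply(blocks, function(b) b@blockIndex, 1L)
  colnames(assayMat) <- paste0(rep(c("stim_", "rest_"), each = length(blocks)),
                               rep(subjects, 2), "_b", rep(blockIdx, 2))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activation = assayMat),
    colData = S4Vectors::DataFrame(
      label = labels, subject = rep(subjects, 2), block = rep(blockIdx, 2)),
    metadata = list(level = level, category = category,
                    voxelScope = voxelScope)
  )
  new("FeatureMatrix", se)
}

#' Write/read a FeatureMatrix as TSV with a JSON sidecar
#'
#' The TSV holds observations as rows and features as columns; the sidecar
#' records labels, level, category and feature ids.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param path TSV path; the sidecar is written at \code{<path>.json}.
#' @return (write) the path, invisibly; (read) a \linkS4class{FeatureMatrix}.
#' @export
writeFeatureMatrix <- function(fm, path) {
  m <- featureValues(fm)
  write.table(data.frame(observation = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(labels = featureLabels(fm), level = featureLevel(fm),
         category = S4Vectors::metadata(fm)$category,
         feature_ids = colnames(m)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @param path TSV path written by \code{writeFeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activation = t(m)),
    colData = S4Vectors::DataFrame(label = side$labels),
    metadata = list(level = side$level, category = side$category)
  )
  new("FeatureMatrix", se)
}
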