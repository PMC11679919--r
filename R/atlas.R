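# Atlas construction: region-level selection, voxel-level selection inside
# the characteristic regions, correlation-based recruitment of external
# voxels, and mask assembly with provenance.

#' Select characteristic regions
#'
#' Runs CV-averaged SVM-RFE on a region-level feature matrix and returns the
#' retained region ids, ordered by their final-round average ranking score
#' in decreasing importance.
#'
#' @param fm a region-level \linkS4class{FeatureMatrix}.
#' @param C box constraint for the RFE fits.
#' @param seed fold seed.
#' @param nFolds CV folds (default 10).
#' @return list with \code{regionIds} (integer, importance-ordered) and the
#'   underlying \code{rfe} result.
#' @export
selectCharacteristicRois <- function(fm, C = 1, seed = 1, nFolds = 10) {
  if (!identical(featureLevel(fm), "roi"))
    stop("fm must be a region-level FeatureMatrix")
  rfe <- rfeSelect(fm, C = C, nFolds = nFolds, seed = seed)
  ids <- as.integer(sub("^region_", "", selectedFeatureIds(rfe)))
  list(regionIds = ids, rfe = rfe)
}

#' Select characteristic sub-ROIs
#'
#' For each characteristic region independently, builds the voxel-level
#' feature matrix over that region's voxels and runs SVM-RFE; the surviving
#' voxels are the region's characteristic sub-ROI. Regions with fewer than
#' two voxels cannot be eliminated from and are retained wholesale with a
#' warning.
#'
#' @param blocks list of \linkS4class{TaskBlock} of one category.
#' @param parcellation a \linkS4class{Parcellation}.
#' @param characteristicRois integer region ids from
#'   \code{\link{selectCharacteristicRois}}.
#' @param C box constraint.
#' @param seed fold seed.
#' @param nFolds CV folds.
#' @param category block category; defaults to the category of the blocks.
#' @return list with \code{subrois} (named list region id -> n x 3 voxel
#'   coordinate matrix) and \code{rfes} (per-region RFE results; NULL for
#'   wholesale-retained regions).
#' @export
selectCharacteristicSubrois <- function(blocks, parcellation,
                                        characteristicRois, C = 1, seed = 1,
                                        nFolds = 10, category = NULL) {
  if (length(characteristicRois) == 0L)
    stop("characteristicRois must be non-empty")
  if (is.null(category)) category <- blockCategory(blocks[[1]])
  subrois <- list()
  rfes <- list()
  for (r in characteristicRois) {
    key <- as.character(r)
    vx <- regionVoxels(parcellation, r)
    if (nrow(vx) < 2L) {
      warning("region ", r, " has < 2 voxels; retained wholesale")
      lin <- ijkToLinear(vx, dim(labelVolume(parcellation)))
      subrois[[key]] <- vx[order(lin), , drop = FALSE]
      rfes[key] <- list(NULL)
      next
    }
    fm <- assembleFeatureMatrix(blocks, parcellation, category,
                                level = "voxel", voxelScope = r)
    rfe <- rfeSelect(fm, C = C, nFolds = nFolds, seed = seed)
    ids <- selectedFeatureIds(rfe)
    coords <- do.call(rbind, lapply(strsplit(sub("^v_", "", ids), "_"),
                                    function(p) as.integer(p)))
    colnames(coords) <- c("i", "j", "k")
    subrois[[key]] <- coords
    rfes[[key]] <- rfe
  }
  list(subrois = subrois, rfes = rfes)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric series of equal length (>= 3), neither constant.
#' @return correlation in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("at least 3 points required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant series")
  cor(x, y)
}

# concatenated per-voxel block time courses: stimulus then recovery windows,
# in block order. Returns voxels x time matrix over the whole grid.
concatenateBlockSeries <- function(blocks) {
  parts <- lapply(blocks, function(b)
    cbind(flattenSeries(b@stimulusVolumes), flattenSeries(b@recoveryVolumes)))
  do.call(cbind, parts)
}

#' Recruit external voxels by functional connectivity
#'
#' For every characteristic sub-ROI, a reference series is formed as the
#' mean over its voxels of the concatenated block time courses. Every voxel
#' of the non-characteristic regions is a candidate and is retained iff its
#' Pearson correlation with any reference exceeds the threshold strictly
#' (r > 0.95 by default; a candidate at exactly the threshold is dropped).
#'
#' @param blocks list of \linkS4class{TaskBlock} of one category.
#' @param parcellation a \linkS4class{Parcellation}.
#' @param subrois named list region id -> voxel coordinate matrix.
#' @param threshold correlation threshold (default 0.95).
#' @return list with \code{voxels} (n x 3 matrix), \code{hosts} (integer
#'   host region per voxel) and \code{bestR} (max correlation per voxel).
#' @export
fcExternalVoxels <- function(blocks, parcellation, subrois, threshold = 0.95) {
  if (length(subrois) == 0L) stop("subrois must be non-empty")
  dims <- dim(labelVolume(parcellation))
  series <- concatenateBlockSeries(blocks)
  charRegions <- as.integer(names(subrois))

  refs <- vapply(subrois, function(vx) {
    lin <- ijkToLinear(vx, dims)
    colMeans(series[lin, , drop = FALSE])
  }, numeric(ncol(series)))  # time x K

  labs <- as.vector(labelVolume(parcellation))
  candLin <- which(labs > 0 & !(labs %in% charRegions))
  empty <- list(voxels = matrix(integer(), 0, 3, dimnames = list(NULL, c("i", "j", "k"))),
                hosts = integer(), bestR = numeric())
  if (length(candLin) == 0L) return(empty)

  cand <- series[candLin, , drop = FALSE]
  candSd <- apply(cand, 1, sd)
  refSd <- apply(refs, 2, sd)
  usable <- candSd > 0
  ok <- which(usable)
  bestR <- rep(NA_real_, length(candLin))
  if (length(ok) && any(refSd > 0)) {
    cc <- cor(t(cand[ok, , drop = FALSE]), refs[, refSd > 0, drop = FALSE])
    bestR[ok] <- apply(cc, 1, max)
  }
  keep <- which(!is.na(bestR) & bestR > threshold)
  if (length(keep) == 0L) return(empty)
  vx <- linearToIjk(candLin[keep], dims)
  list(voxels = vx, hosts = as.integer(labs[candLin[keep]]),
       bestR = bestR[keep])
}

#' Assemble an emotion atlas
#'
#' Union of the characteristic sub-ROI voxels and the recruited external
#' voxels, with disjointness enforced: an external voxel lying inside a
#' characteristic region is an invariant violation.
#'
#' @param subrois named list region id -> voxel coordinate matrix.
#' @param externals result of \code{\link{fcExternalVoxels}} (or a list with
#'   \code{voxels} and \code{hosts}).
#' @param parcellation a \linkS4class{Parcellation}.
#' @param polarity "positive" or "negative".
#' @return an \linkS4class{EmotionAtlas}.
#' @export
assembleAtlas <- function(subrois, externals, parcellation,
                          polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  labs <- labelVolume(parcellation)
  charRegions <- as.integer(names(subrois))
  extVox <- externals$voxels
  if (is.null(extVox)) extVox <- matrix(integer(), 0, 3)
  if (nrow(extVox) && any(labs[extVox] %in% charRegions))
    stop("external voxels overlap characteristic regions")
  subrois <- lapply(subrois, function(vx) {
    vx <- as.matrix(vx); colnames(vx) <- c("i", "j", "k"); vx
  })
  new("EmotionAtlas", polarity = polarity, subroiVoxels = subrois,
      externalVoxels = extVox,
      externalHosts = as.integer(externals$hosts %||% integer()),
      parcellation = parcellation)
}

#' Atlas provenance table
#'
#' @param atlas an \linkS4class{EmotionAtlas}.
#' @return data.frame with voxel coordinates, host region and origin
#'   ("subroi" or "external").
#' @export
atlasProvenance <- function(atlas) {
  subs <- do.call(rbind, lapply(names(atlas@subroiVoxels), function(r) {
    vx <- atlas@subroiVoxels[[r]]
    if (!nrow(vx)) return(NULL)
    data.frame(i = vx[, 1], j = vx[, 2], k = vx[, 3],
               hostRegion = as.integer(r), origin = "subroi")
  }))
  ext <- if (nrow(atlas@externalVoxels))
    data.frame(i = atlas@externalVoxels[, 1], j = atlas@externalVoxels[, 2],
               k = atlas@externalVoxels[, 3], hostRegion = atlas@externalHosts,
               origin = "external")
  else NULL
  out <- rbind(subs, ext)
  rownames(out) <- NULL
  out
}
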