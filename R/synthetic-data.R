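# Synthetic-data generators: seeded parcellations, paradigm-conforming task
# runs, and two-group resting cohorts with implanted band-limited effects.

#' Construct a task paradigm
#'
#' @param trS repetition time in seconds.
#' @param leadInS initial rest duration in seconds.
#' @param segments data.frame with columns \code{condition} and
#'   \code{durationS}.
#' @return a \linkS4class{TaskParadigm}.
#' @export
taskParadigm <- function(trS = 2, leadInS = 20, segments) {
  new("TaskParadigm", trS = trS, leadInS = leadInS, segments = segments)
}

#' Default emotional-stimulation paradigm
#'
#' 20 s rest lead-in, then six 40 s cycles alternating 20 s of emotional
#' picture stimulation (positive, negative, positive, ...) with 20 s of rest,
#' at TR = 2 s: 240 s of formal experiment, 260 s (130 volumes) in total.
#'
#' @return a \linkS4class{TaskParadigm}.
#' @export
defaultTaskParadigm <- function() {
  conds <- rep(c("positive", "rest", "negative", "rest"), 3)
  taskParadigm(
    trS = 2, leadInS = 20,
    segments = data.frame(condition = conds, durationS = 20)
  )
}

#' Construct generator ground truth
#'
#' @param activePositive,activeNegative integer region ids carrying the
#'   stimulus-locked effect for each category.
#' @param activeVoxelFraction fraction of each active region's voxels that
#'   carry the effect (taken in linear-index order, so the implanted voxel
#'   set is recoverable; see \code{\link{activeVoxels}}).
#' @param effectSize stimulus-window signal increment (arbitrary BOLD units).
#' @param hemodynamicDelayS onset lag of the effect; default 10 s, the
#'   midpoint of the 8-12 s BOLD lag that motivates the 11-20 s extraction
#'   window.
#' @param alffClusters list of implants for the resting stage; each element a
#'   list(group, voxels, amplitude, freqHz).
#' @return a \linkS4class{GroundTruth}.
#' @export
groundTruth <- function(activePositive = integer(), activeNegative = integer(),
                        activeVoxelFraction = 0.5, effectSize = 3,
                        hemodynamicDelayS = 10, alffClusters = list()) {
  new("GroundTruth",
    activeRegionIds = list(positive = as.integer(activePositive),
                           negative = as.integer(activeNegative)),
    activeVoxelFraction = activeVoxelFraction,
    effectSize = effectSize,
    hemodynamicDelayS = hemodynamicDelayS,
    alffClusters = alffClusters)
}

#' The implanted voxel set of an active region
#'
#' Deterministic resolution of \code{activeVoxelFraction}: the first
#' \code{ceiling(fraction * n)} voxels of the region in linear-index order.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param parcellation a \linkS4class{Parcellation}.
#' @param category "positive" or "negative".
#' @return n x 3 integer matrix of voxel (i,j,k) coordinates.
#' @export
activeVoxels <- function(truth, parcellation, category = "positive") {
  regs <- truth@activeRegionIds[[category]]
  out <- lapply(regs, function(r) {
    vx <- regionVoxels(parcellation, r)
    n <- ceiling(truth@activeVoxelFraction * nrow(vx))
    lin <- ijkToLinear(vx, dim(labelVolume(parcellation)))
    vx[order(lin)[seq_len(n)], , drop = FALSE]
  })
  res <- do.call(rbind, c(out, list(matrix(integer(), 0, 3))))
  colnames(res) <- c("i", "j", "k")
  res
}

#' Generate a contiguous random parcellation
#'
#' The foreground is an ellipsoidal "brain" mask inscribed in the grid.
#' Regions are grown from seeded centroids by multi-source breadth-first
#' search over 6-neighbour adjacency, so every region is spatially
#' contiguous, regions partition the foreground exactly, and the result is
#' deterministic for a fixed seed.
#'
#' @param gridShape integer(3) grid dimensions.
#' @param nRegions number of regions (R = 246 emulates a whole-brain
#'   template; tests use desk-scale values).
#' @param seed integer seed.
#' @param voxelSizeMm numeric(3) voxel edge lengths, default 3 mm isotropic.
#' @param originMm numeric(3) world coordinate of voxel (1,1,1).
#' @return a \linkS4class{Parcellation}.
#' @export
makeParcellation <- function(gridShape, nRegions, seed = 1,
                             voxelSizeMm = c(3, 3, 3),
                             originMm = c(0, 0, 0)) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 3L), nRegions >= 1)
  ctr <- (gridShape + 1) / 2
  ax <- gridShape / 2
  idx <- as.matrix(expand.grid(i = seq_len(gridShape[1]),
                               j = seq_len(gridShape[2]),
                               k = seq_len(gridShape[3])))
  inside <- ((idx[, 1] - ctr[1]) / ax[1])^2 +
            ((idx[, 2] - ctr[2]) / ax[2])^2 +
            ((idx[, 3] - ctr[3]) / ax[3])^2 <= 1
  fg <- which(inside)
  if (nRegions > length(fg))
    stop("nRegions exceeds the number of foreground voxels (", length(fg), ")")

  labels <- integer(prod(gridShape))
  seeds <- withLocalSeed(seed, fg[sample.int(length(fg), nRegions)])
  labels[seeds] <- seq_len(nRegions)

  # multi-source BFS over the 6-neighbourhood, FIFO order
  nvox <- prod(gridShape)
  strides <- c(1L, gridShape[1], gridShape[1] * gridShape[2])
  queue <- integer(length(fg))
  queue[seq_len(nRegions)] <- seeds
  headPos <- 1L; tailPos <- nRegions
  fgMask <- logical(nvox); fgMask[fg] <- TRUE
  ijk <- idx
  while (headPos <= tailPos) {
    v <- queue[headPos]; headPos <- headPos + 1L
    lab <- labels[v]
    for (axis in 1:3) {
      for (dlt in c(-1L, 1L)) {
        if (ijk[v, axis] + dlt < 1L || ijk[v, axis] + dlt > gridShape[axis]) next
        nb <- v + dlt * strides[axis]
        if (fgMask[nb] && labels[nb] == 0L) {
          labels[nb] <- lab
          tailPos <- tailPos + 1L
          queue[tailPos] <- nb
        }
      }
    }
  }
  vol <- array(labels, gridShape)
  new("Parcellation", labelVolume = vol, voxelSizeMm = voxelSizeMm,
      originMm = originMm, regionIds = seq_len(nRegions))
}

# absolute onset times (s) of volumes 1..T
volumeOnsets <- function(paradigm, nVolumes) {
  (seq_len(nVolumes) - 1) * paradigm@trS
}

# total run duration (s) including lead-in
paradigmDuration <- function(paradigm) {
  paradigm@leadInS + sum(paradigm@segments$durationS)
}

# per-condition active windows [start, end) in absolute run time, after
# shifting by the hemodynamic delay
conditionWindows <- function(paradigm, category, delayS) {
  seg <- paradigm@segments
  starts <- paradigm@leadInS + cumsum(c(0, head(seg$durationS, -1)))
  sel <- seg$condition == category
  cbind(start = starts[sel] + delayS, end = starts[sel] + seg$durationS[sel] + delayS)
}

#' Simulate one block-design task subject
#'
#' Signal model: \code{baseline + effectSize * delayed-boxcar + noise}. In
#' every implanted active voxel of a category, the signal is raised by
#' \code{effectSize} while run time lies within
#' \code{[stimulus onset + delay, stimulus end + delay)}; i.i.d. Gaussian
#' noise of sd \code{noiseSd} is added everywhere (foreground and
#' background). With the default 10 s delay the five stimulus-window volumes
#' (onsets 10-18 s after stimulus onset) are fully active and the five
#' recovery-window volumes (onsets 30-38 s) fully inactive, so window-mean
#' differencing recovers \code{effectSize} exactly at zero noise.
#'
#' @param paradigm a \linkS4class{TaskParadigm}.
#' @param parcellation a \linkS4class{Parcellation}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param baseline baseline signal level.
#' @param noiseSd Gaussian noise sd (>= 0).
#' @param seed integer seed.
#' @param subjectId subject identifier.
#' @return a \linkS4class{SubjectRecord} with group "task".
#' @export
simulateTaskSubject <- function(paradigm, parcellation, truth, baseline = 100,
                                noiseSd = 1, seed = 1, subjectId = "sub01") {
  stopifnot(noiseSd >= 0)
  dims <- dim(labelVolume(parcellation))
  nVol <- as.integer(round(paradigmDuration(paradigm) / paradigm@trS))
  onsets <- volumeOnsets(paradigm, nVol)
  series <- array(baseline, c(dims, nVol))
  flat <- matrix(baseline, prod(dims), nVol)

  for (category in c("positive", "negative")) {
    act <- activeVoxels(truth, parcellation, category)
    if (!nrow(act)) next
    lin <- ijkToLinear(act, dims)
    win <- conditionWindows(paradigm, category, truth@hemodynamicDelayS)
    activeVol <- rep(FALSE, nVol)
    for (r in seq_len(nrow(win)))
      activeVol <- activeVol | (onsets >= win[r, 1] & onsets < win[r, 2])
    flat[lin, activeVol] <- flat[lin, activeVol] + truth@effectSize
  }
  if (noiseSd > 0) {
    noise <- withLocalSeed(seed, rnorm(length(flat), sd = noiseSd))
    flat <- flat + noise
  }
  series <- array(flat, c(dims, nVol))
  new("SubjectRecord", subjectId = subjectId, group = "task", age = 24,
      sex = "M", series = series, trS = paradigm@trS)
}

#' Simulate a two-group resting-state cohort
#'
#' Each subject's series is white Gaussian noise around \code{baseline};
#' in every implanted cluster of the subject's group, a sinusoid of the
#' stated amplitude and frequency (random phase per subject) is added, so
#' the group difference is band-limited and recoverable by ALFF. Ages are
#' drawn from the cohort demographics (patients 33.0 +/- 9.5 y, controls
#' 34.2 +/- 8.5 y) and sexes assigned at the cohort ratios (patients
#' 10 M : 36 F, controls 6 M : 14 F), matching the depression study cohort
#' of 46 patients and 20 controls.
#'
#' @param nPatients,nControls group sizes (defaults 46 and 20).
#' @param parcellation a \linkS4class{Parcellation}.
#' @param truth a \linkS4class{GroundTruth} (its \code{alffClusters} are the
#'   implants).
#' @param durationS run length in seconds; must be a multiple of \code{trS}.
#' @param trS repetition time, default 2 s.
#' @param baseline baseline signal level.
#' @param noiseSd Gaussian noise sd.
#' @param seed integer seed.
#' @return list of \linkS4class{SubjectRecord} (patients first).
#' @export
simulateRestCohort <- function(nPatients = 46, nControls = 20, parcellation,
                               truth, durationS = 300, trS = 2,
                               baseline = 100, noiseSd = 1, seed = 1) {
  if (nPatients < 1 || nControls < 1) stop("group sizes must be positive")
  if (abs(durationS / trS - round(durationS / trS)) > 1e-9)
    stop("durationS must be a multiple of trS")
  dims <- dim(labelVolume(parcellation))
  nVol <- as.integer(round(durationS / trS))
  tSec <- (seq_len(nVol) - 1) * trS

  demo <- list(
    patient = list(n = nPatients, ageMean = 33.0, ageSd = 9.5, maleFrac = 10 / 46),
    control = list(n = nControls, ageMean = 34.2, ageSd = 8.5, maleFrac = 6 / 20)
  )
  withLocalSeed(seed, {
    out <- vector("list", nPatients + nControls)
    pos <- 0L
    for (grp in c("patient", "control")) {
      d <- demo[[grp]]
      ages <- pmax(18, rnorm(d$n, d$ageMean, d$ageSd))
      nM <- round(d$maleFrac * d$n)
      sexes <- sample(c(rep("M", nM), rep("F", d$n - nM)))
      clusters <- Filter(function(cl) cl$group == grp, truth@alffClusters)
      for (s in seq_len(d$n)) {
        pos <- pos + 1L
        flat <- matrix(rnorm(prod(dims) * nVol, mean = baseline, sd = noiseSd),
                       prod(dims), nVol)
        for (cl in clusters) {
          phase <- runif(1, 0, 2 * pi)
          wave <- cl$amplitude * sin(2 * pi * cl$freqHz * tSec + phase)
          lin <- ijkToLinear(cl$voxels, dims)
          flat[lin, ] <- flat[lin, ] + rep(wave, each = length(lin))
        }
        out[[pos]] <- new("SubjectRecord",
          subjectId = sprintf("%s%02d", substr(grp, 1, 3), s),
          group = grp, age = ages[s], sex = sexes[s],
          series = array(flat, c(dims, nVol)), trS = trS)
      }
    }
    out
  })
}

#' Cohort manifest table
#'
#' @param cohort list of \linkS4class{SubjectRecord}.
#' @return data.frame with subject_id, group, age, sex.
#' @export
cohortManifest <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, function(s) s@subjectId, ""),
    group = vapply(cohort, function(s) s@group, ""),
    age = vapply(cohort, function(s) s@age, 0),
    sex = vapply(cohort, function(s) s@sex, "")
  )
}
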