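# ALFF maps and the covariate-adjusted voxelwise two-group comparison with
# BH-FDR control and cluster reporting.

# residuals after removing a linear trend (intercept + slope) column-wise;
# x is a time x series matrix
.detrendColumns <- function(x) {
  n <- nrow(x)
  D <- cbind(1, seq_len(n))
  x - D %*% solve(crossprod(D), crossprod(D, x))
}

#' Amplitude of low-frequency fluctuations of one series
#'
#' The series is linearly detrended, Fourier transformed, and the per-bin
#' amplitude taken as the square root of the periodogram power
#' (\code{2 |X_k| / n} for positive-frequency bins); ALFF is the mean
#' amplitude over the bins whose frequency lies inside \code{[low, high]}
#' (0.01-0.08 Hz by default). ALFF is absolutely homogeneous:
#' \code{ALFF(c x) = |c| ALFF(x)} after detrending.
#'
#' @param series numeric time course.
#' @param trS sampling interval in seconds.
#' @param bandHz numeric(2) band edges in Hz, inside (0, Nyquist].
#' @return non-negative scalar.
#' @export
computeAlff <- function(series, trS, bandHz = c(0.01, 0.08)) {
  n <- length(series)
  if (n < 4L) stop("series too short")
  nyq <- 1 / (2 * trS)
  if (!(bandHz[1] > 0 && bandHz[1] < bandHz[2] && bandHz[2] <= nyq + 1e-12))
    stop("band must lie inside (0, Nyquist]")
  bins <- .bandBins(n, trS, bandHz)
  if (length(bins) == 0L)
    stop("no frequency bins inside the band; series too short for the band")
  x <- .detrendColumns(matrix(series, ncol = 1))
  amp <- 2 * Mod(fft(x[, 1])) / n
  mean(amp[bins + 1L])
}

# positive-frequency DFT bin indices (1-based k, frequency k/(n trS)) inside
# the band
.bandBins <- function(n, trS, bandHz) {
  k <- seq_len(floor(n / 2))
  freq <- k / (n * trS)
  k[freq >= bandHz[1] - 1e-12 & freq <= bandHz[2] + 1e-12]
}

#' Voxelwise ALFF map of a subject
#'
#' @param record a \linkS4class{SubjectRecord}.
#' @param bandHz numeric(2) band edges.
#' @param parcellation optional \linkS4class{Parcellation}; when given, only
#'   foreground voxels are computed and background is set to 0.
#' @return an \linkS4class{ALFFMap}.
#' @export
alffMap <- function(record, bandHz = c(0.01, 0.08), parcellation = NULL) {
  series <- record@series
  d <- dim(series)
  flat <- flattenSeries(series)
  if (!is.null(parcellation)) {
    if (!identical(dim(labelVolume(parcellation)), d[1:3]))
      stop("parcellation grid does not match the record")
    fg <- which(as.vector(labelVolume(parcellation)) > 0)
  } else fg <- seq_len(nrow(flat))
  n <- d[4]
  bins <- .bandBins(n, record@trS, bandHz)
  if (length(bins) == 0L) stop("no frequency bins inside the band")
  x <- .detrendColumns(t(flat[fg, , drop = FALSE]))
  amp <- 2 * Mod(mvfft(x)) / n
  vals <- colMeans(amp[bins + 1L, , drop = FALSE])
  out <- numeric(nrow(flat))
  out[fg] <- vals
  new("ALFFMap", values = array(out, d[1:3]), bandHz = bandHz,
      trS = record@trS)
}

#' Remove age and sex by ordinary least squares
#'
#' Regresses the per-subject values at one voxel on an intercept, age, and a
#' sex indicator, returning the residuals. Used across pooled subjects ahead
#' of the two-sample test so group signal is preserved (group is not in the
#' nuisance design).
#'
#' @param values numeric per-subject values.
#' @param age numeric per-subject ages.
#' @param sex per-subject sex ("M"/"F" or any two-level coding).
#' @return numeric residuals.
#' @export
regressOutCovariates <- function(values, age, sex) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 subjects (intercept + 2 covariates + 1)")
  D <- cbind(1, age, as.numeric(factor(sex)) - 1)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("collinear covariate design (rank deficient)")
  as.numeric(qr.resid(qrD, values))
}

#' Voxelwise covariate-adjusted two-sample t-test
#'
#' Per voxel, age and sex are regressed out across the pooled subjects and a
#' pooled-variance two-sample t statistic computed on the residuals,
#' oriented A - B (positive t = first group higher). Two-sided p values use
#' \code{nA + nB - 2 - (number of covariates)} degrees of freedom. Voxels
#' with zero pooled variance are masked out (NA) with a warning.
#'
#' @param mapsA,mapsB lists of \linkS4class{ALFFMap} (or 3D arrays), one per
#'   subject of each group.
#' @param age,sex pooled covariates, ordered as \code{c(A subjects, B
#'   subjects)}; omit both for an unadjusted test.
#' @param mask optional logical/0-1 3D array restricting the tested voxels.
#' @return list with \code{tMap}, \code{pMap} (3D arrays, NA outside tested
#'   voxels) and \code{df}.
#' @export
voxelwiseTtest <- function(mapsA, mapsB, age = NULL, sex = NULL, mask = NULL) {
  getVals <- function(m) if (is(m, "ALFFMap")) alffValues(m) else m
  A <- lapply(mapsA, getVals)
  B <- lapply(mapsB, getVals)
  nA <- length(A); nB <- length(B)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
  dims <- dim(A[[1]])
  X <- t(vapply(c(A, B), as.vector, numeric(prod(dims))))  # subjects x voxels

  vox <- seq_len(ncol(X))
  if (!is.null(mask)) vox <- which(as.vector(mask) > 0)
  X <- X[, vox, drop = FALSE]

  nCov <- 0L
  if (!is.null(age) || !is.null(sex)) {
    if (is.null(age) || is.null(sex)) stop("supply both age and sex, or neither")
    D <- cbind(1, age, as.numeric(factor(sex)) - 1)
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) stop("collinear covariate design")
    X <- qr.resid(qrD, X)
    nCov <- 2L
  }

  gA <- seq_len(nA)
  mA <- colMeans(X[gA, , drop = FALSE])
  mB <- colMeans(X[-gA, , drop = FALSE])
  ssA <- colSums(sweep(X[gA, , drop = FALSE], 2, mA)^2)
  ssB <- colSums(sweep(X[-gA, , drop = FALSE], 2, mB)^2)
  df <- nA + nB - 2L - nCov
  sp2 <- (ssA + ssB) / (nA + nB - 2L)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tv <- rep(NA_real_, length(se))
  zero <- se == 0
  if (any(zero & (mA != mB))) warning(sum(zero), " voxels with zero pooled variance masked out")
  tv[!zero] <- (mA - mB)[!zero] / se[!zero]
  tv[zero & (mA == mB)] <- 0
  pv <- 2 * pt(-abs(tv), df)

  tMap <- array(NA_real_, dims); pMap <- array(NA_real_, dims)
  tMap[vox] <- tv; pMap[vox] <- pv
  list(tMap = tMap, pMap = pMap, df = df)
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up FDR control: with ordered p-values p(1) <= ... <= p(m), reject
#' the k smallest where k is the largest i with p(i) <= q i / m.
#'
#' @param pValues numeric p values in [0, 1] (NA allowed, never rejected).
#' @param q FDR level (default 0.01).
#' @return logical rejection mask of the same shape.
#' @export
fdrBh <- function(pValues, q = 0.01) {
  if (length(pValues) == 0L) return(logical(0))
  adj <- p.adjust(pValues, method = "BH")
  out <- !is.na(adj) & adj <= q
  if (!is.null(dim(pValues))) dim(out) <- dim(pValues)
  out
}

#' Extract significant clusters
#'
#' Connected components of the rejection mask (26-neighbourhood by default),
#' reported with voxel count, physical size (voxel count x voxel volume),
#' the peak voxel (maximal |t|, sign preserved), its world coordinate, and
#' the parcellation regions intersected.
#'
#' @param mask logical/0-1 3D array of surviving voxels.
#' @param tMap 3D array of t statistics aligned with the mask.
#' @param parcellation a \linkS4class{Parcellation} (voxel geometry and
#'   region labels).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return data.frame: one row per cluster with nVoxels, sizeMm3, peak
#'   voxel indices, peak world coordinates, peakIntensity, memberRegions.
#' @export
extractClusters <- function(mask, tMap, parcellation, connectivity = 26) {
  dims <- dim(mask)
  if (!identical(dims, dim(tMap))) stop("mask and tMap shapes differ")
  off <- connectivityOffsets(connectivity)
  labels <- .labelComponents(mask, off)
  ncl <- max(labels)
  empty <- data.frame(cluster = integer(), nVoxels = integer(),
                      sizeMm3 = numeric(), peakI = integer(), peakJ = integer(),
                      peakK = integer(), peakXmm = numeric(), peakYmm = numeric(),
                      peakZmm = numeric(), peakIntensity = numeric(),
                      memberRegions = character())
  if (ncl == 0L) return(empty)
  voxVol <- prod(voxelSize(parcellation))
  labs <- labelVolume(parcellation)
  rows <- lapply(seq_len(ncl), function(cl) {
    lin <- which(labels == cl)
    ijk <- linearToIjk(lin, dims)
    tv <- tMap[lin]
    peak <- which.max(abs(tv))
    world <- voxelToWorld(parcellation, ijk[peak, , drop = FALSE])
    regs <- sort(unique(labs[lin]))
    regs <- regs[regs > 0]
    data.frame(cluster = cl, nVoxels = length(lin),
               sizeMm3 = length(lin) * voxVol,
               peakI = ijk[peak, 1], peakJ = ijk[peak, 2], peakK = ijk[peak, 3],
               peakXmm = world[1], peakYmm = world[2], peakZmm = world[3],
               peakIntensity = tv[peak],
               memberRegions = paste(regs, collapse = ","))
  })
  out <- do.call(rbind, rows)
  # report in descending cluster size, stable within size by first voxel
  out <- out[order(-out$nVoxels, out$cluster), ]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# iterative BFS component labeling of a 3D mask
.labelComponents <- function(mask, offsets) {
  dims <- dim(mask)
  m <- as.vector(mask) > 0
  m[is.na(m)] <- FALSE
  labels <- integer(length(m))
  nextLab <- 0L
  queue <- integer(sum(m))
  for (start in which(m)) {
    if (labels[start] > 0L) next
    nextLab <- nextLab + 1L
    labels[start] <- nextLab
    queue[1L] <- start
    headPos <- 1L; tailPos <- 1L
    while (headPos <= tailPos) {
      v <- queue[headPos]; headPos <- headPos + 1L
      ijk <- linearToIjk(v, dims)
      for (o in seq_len(nrow(offsets))) {
        ni <- ijk[1] + offsets[o, 1]; nj <- ijk[2] + offsets[o, 2]
        nk <- ijk[3] + offsets[o, 3]
        if (ni < 1L || nj < 1L || nk < 1L ||
            ni > dims[1] || nj > dims[2] || nk > dims[3]) next
        nb <- ni + (nj - 1L) * dims[1] + (nk - 1L) * dims[1] * dims[2]
        if (m[nb] && labels[nb] == 0L) {
          labels[nb] <- nextLab
          tailPos <- tailPos + 1L
          queue[tailPos] <- nb
        }
      }
    }
  }
  array(labels, dims)
}

#' Full two-group comparison
#'
#' Convenience wrapper: voxelwise covariate-adjusted t-test, BH-FDR at
#' \code{q}, cluster extraction.
#'
#' @inheritParams voxelwiseTtest
#' @param parcellation a \linkS4class{Parcellation}.
#' @param q FDR level (default 0.01).
#' @param connectivity cluster connectivity (default 26).
#' @return a \linkS4class{GroupComparison}.
#' @export
groupComparison <- function(mapsA, mapsB, parcellation, age = NULL,
                            sex = NULL, mask = NULL, q = 0.01,
                            connectivity = 26) {
  tt <- voxelwiseTtest(mapsA, mapsB, age = age, sex = sex, mask = mask)
  rej <- array(FALSE, dim(tt$pMap))
  tested <- !is.na(tt$pMap)
  rej[tested] <- fdrBh(tt$pMap[tested], q)
  clusters <- extractClusters(rej, tt$tMap, parcellation, connectivity)
  new("GroupComparison", tMap = tt$tMap, pMap = tt$pMap, qThreshold = q,
      covariates = if (is.null(age)) character() else c("age", "sex"),
      clusters = clusters)
}
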