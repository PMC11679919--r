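# Segmentation of task runs into per-category blocks, and frequency-domain
# band-pass filtering.

#' Split a task run into task blocks
#'
#' Each 40 s stimulus+rest cycle yields one \linkS4class{TaskBlock}. After
#' discarding the lead-in volumes, the five volumes with onsets 10-18 s
#' after the cycle's stimulus onset are extracted as the stimulus state
#' (the delayed BOLD response is fully developed there) and the five with
#' onsets 30-38 s as the recovery state. Volume k (0-based within the run)
#' is assigned onset time \code{k * trS}.
#'
#' @param record a \linkS4class{SubjectRecord}.
#' @param paradigm the \linkS4class{TaskParadigm} of the run.
#' @param dropLeadIn discard the initial stabilization volumes before volume
#'   bookkeeping (default TRUE). The returned window indices are then
#'   relative to the trimmed run; the extraction windows themselves always
#'   lie inside the formal experiment, so only the numbering changes.
#' @param dropVolumes how many initial volumes the stabilization rule
#'   discards (default 5, i.e. the first 10 s at TR = 2 s).
#' @return list of \linkS4class{TaskBlock}, in acquisition order.
#' @export
segmentBlocks <- function(record, paradigm, dropLeadIn = TRUE,
                          dropVolumes = 5L) {
  if (abs(record@trS - paradigm@trS) > 1e-9)
    stop("record and paradigm TR disagree")
  series <- record@series
  nVol <- dim(series)[4]
  expVol <- as.integer(round(paradigmDuration(paradigm) / paradigm@trS))
  if (nVol != expVol)
    stop("run has ", nVol, " volumes but the paradigm implies ", expVol)

  tr <- paradigm@trS
  seg <- paradigm@segments
  starts <- paradigm@leadInS + cumsum(c(0, head(seg$durationS, -1)))
  stimIdx <- which(seg$condition != "rest")
  counters <- c(positive = 0L, negative = 0L)
  blocks <- vector("list", length(stimIdx))

  for (n in seq_along(stimIdx)) {
    s <- stimIdx[n]
    category <- seg$condition[s]
    stimDur <- seg$durationS[s]
    restDur <- if (s < nrow(seg) && seg$condition[s + 1] == "rest")
      seg$durationS[s + 1] else stop("stimulus segment must be followed by rest")
    t0 <- starts[s]
    # onsets in [stimDur/2, stimDur) and [stimDur + restDur/2, stimDur + restDur)
    stimOn <- t0 + seq(stimDur / 2, stimDur - tr, by = tr)
    recOn  <- t0 + stimDur + seq(restDur / 2, restDur - tr, by = tr)
    stimVol <- as.integer(round(stimOn / tr)) + 1L
    recVol  <- as.integer(round(recOn / tr)) + 1L
    if (max(recVol) > nVol) stop("block window exceeds series length")
    counters[category] <- counters[category] + 1L
    blocks[[n]] <- new("TaskBlock",
      subjectId = record@subjectId, category = category,
      blockIndex = counters[[category]],
      stimulusVolumes = series[, , , stimVol, drop = FALSE],
      recoveryVolumes = series[, , , recVol, drop = FALSE],
      stimulusIndices = stimVol, recoveryIndices = recVol)
  }
  if (dropLeadIn) {
    # windows are indexed in full-run volumes; the discarded stabilization
    # volumes never enter a window, so trimming is bookkeeping only
    nDrop <- as.integer(dropVolumes)
    if (min(blocks[[1]]@stimulusIndices) <= nDrop)
      stop("stabilization trim would cut into the first block window")
    blocks <- lapply(blocks, function(b) {
      b@stimulusIndices <- b@stimulusIndices - nDrop
      b@recoveryIndices <- b@recoveryIndices - nDrop
      b
    })
  }
  blocks
}

#' Audit table of block windows
#'
#' @param blocks list of \linkS4class{TaskBlock}.
#' @return data.frame (subject, category, block, window, volume indices).
#' @export
blockIndexTable <- function(blocks) {
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(
      subject = b@subjectId, category = b@category, block = b@blockIndex,
      state = c("stimulus", "rest"),
      volumes = c(paste(b@stimulusIndices, collapse = ","),
                  paste(b@recoveryIndices, collapse = ","))
    )
  }))
}

#' Frequency-domain band-pass filter
#'
#' Removes the temporal mean, masks DFT bins whose frequency lies outside
#' \code{[lowHz, highHz]} (both tails), and inverts the transform. Linear
#' phase by construction; output shape equals input shape.
#'
#' @param series 4D array (3 spatial axes x time) or a voxels x time matrix.
#' @param trS sampling interval in seconds.
#' @param lowHz,highHz band edges; \code{0 <= lowHz < highHz <=} Nyquist.
#' @return filtered array of the same shape.
#' @export
bandpassFilter <- function(series, trS, lowHz = 0.01, highHz = 0.1) {
  nyq <- 1 / (2 * trS)
  if (!(lowHz >= 0 && lowHz < highHz && highHz <= nyq + 1e-12))
    stop("band must satisfy 0 <= lowHz < highHz <= Nyquist (", nyq, " Hz)")
  d <- dim(series)
  x <- if (length(d) == 4L) flattenSeries(series) else as.matrix(series)
  nT <- ncol(x)
  mu <- rowMeans(x)
  x <- x - mu
  freq <- c(0, seq_len(nT - 1)) / (nT * trS)
  freq <- pmin(freq, 1 / trS - freq)  # fold to [0, Nyquist]
  keep <- freq >= lowHz & freq <= highHz
  X <- mvfft(t(x))
  X[!keep, ] <- 0
  out <- t(Re(mvfft(X, inverse = TRUE)) / nT)
  if (length(d) == 4L) array(out, d) else out
}
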