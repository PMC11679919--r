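# Shared fixtures, built in code and memoized for the suite run.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache)) assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

tinyParcellation <- function() memoFixture("tinyParc", function()
  makeParcellation(c(10, 10, 10), 6, seed = 11))

tinyTruth <- function() memoFixture("tinyTruth", function()
  groundTruth(activePositive = c(1L, 3L), activeNegative = c(2L, 5L),
              activeVoxelFraction = 0.5, effectSize = 3))

# 6 task subjects on the tiny parcellation, segmented; list(pos=, neg=, ...)
tinyTaskData <- function() memoFixture("tinyTask", function() {
  p <- tinyParcellation()
  tr <- tinyTruth()
  par <- defaultTaskParadigm()
  subs <- lapply(1:6, function(s)
    simulateTaskSubject(par, p, tr, baseline = 100, noiseSd = 1, seed = 100 + s,
                        subjectId = sprintf("s%02d", s)))
  blocks <- unlist(lapply(subs, segmentBlocks, paradigm = par),
                   recursive = FALSE)
  list(
    parcellation = p, truth = tr, paradigm = par, subjects = subs,
    blocks = blocks,
    pos = Filter(function(b) blockCategory(b) == "positive", blocks),
    neg = Filter(function(b) blockCategory(b) == "negative", blocks)
  )
})

# a feature matrix with 2 informative features (class mean shift `effect`)
# and `nNoise` pure-noise features; n observations, balanced labels
syntheticFeatureData <- function(n = 126, nNoise = 8, effect = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n / 2)
  X <- cbind(
    matrix(rnorm(n * 2) + effect * (y == 1), n, 2),
    matrix(rnorm(n * nNoise), n, nNoise)
  )
  colnames(X) <- c("inf1", "inf2", paste0("noise", seq_len(nNoise)))
  list(X = X, y = y)
}

# build one TaskBlock directly from stimulus/recovery window arrays
manualBlock <- function(stimArr, recArr, subject = "s01",
                        category = "positive", index = 1L) {
  new("TaskBlock", subjectId = subject, category = category,
      blockIndex = index, stimulusVolumes = stimArr, recoveryVolumes = recArr,
      stimulusIndices = 1:5, recoveryIndices = 11:15)
}
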