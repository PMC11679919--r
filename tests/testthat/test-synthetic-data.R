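test_that("parcellation partitions the foreground into contiguous seeded regions", {
  # single-region case: every foreground voxel gets label 1
  p1 <- makeParcellation(c(12, 12, 12), 1, seed = 5)
  labs1 <- labelVolume(p1)
  expect_setequal(unique(as.vector(labs1[labs1 > 0])), 1L)
  expect_gt(sum(labs1 == 1), 0)

  # partition conservation at 20^3 / 30 regions
  p <- makeParcellation(c(20, 20, 20), 30, seed = 7)
  labs <- labelVolume(p)
  counts <- table(labs[labs > 0])
  expect_length(counts, 30)
  expect_equal(sum(counts), sum(labs > 0))
  expect_true(all(counts >= 1))

  # spatial contiguity: every region is one connected component
  for (r in c(1L, 7L, 30L)) {
    comp <- oracleFloodFill(labs == r, connectivity = 6)
    expect_equal(max(comp), 1L)
  }

  # determinism and error contract
  p2 <- makeParcellation(c(20, 20, 20), 30, seed = 7)
  expect_identical(labelVolume(p), labelVolume(p2))
  expect_error(makeParcellation(c(4, 4, 4), 10000), "exceeds")
})

test_that("task simulator implements the delayed-boxcar signal model exactly", {
  p <- tinyParcellation()
  par <- defaultTaskParadigm()

  # null signal: no active regions, zero noise -> constant baseline
  nullTruth <- groundTruth(activeVoxelFraction = 0.5, effectSize = 3)
  rec0 <- simulateTaskSubject(par, p, nullTruth, baseline = 7, noiseSd = 0, seed = 1)
  expect_true(all(rec0@series == 7))

  # window-mean differencing recovers the effect exactly at zero noise
  tr <- tinyTruth()
  rec <- simulateTaskSubject(par, p, tr, baseline = 100, noiseSd = 0, seed = 1)
  blocks <- segmentBlocks(rec, par)
  b <- Filter(function(b) blockCategory(b) == "positive", blocks)[[1]]
  act <- activeVoxels(tr, p, "positive")
  dims <- dim(labelVolume(p))
  stimFlat <- matrix(stimulusVolumes(b), prod(dims), 5)
  recFlat <- matrix(recoveryVolumes(b), prod(dims), 5)
  linAct <- act[, 1] + (act[, 2] - 1) * dims[1] + (act[, 3] - 1) * dims[1] * dims[2]
  diffs <- rowMeans(stimFlat) - rowMeans(recFlat)
  expect_equal(unname(diffs[linAct]), rep(3, length(linAct)))
  expect_equal(unname(diffs[-linAct]), rep(0, prod(dims) - length(linAct)))

  # determinism with noise
  r1 <- simulateTaskSubject(par, p, tr, noiseSd = 0.5, seed = 3)
  r2 <- simulateTaskSubject(par, p, tr, noiseSd = 0.5, seed = 3)
  expect_identical(r1@series, r2@series)
  expect_false(identical(
    r1@series, simulateTaskSubject(par, p, tr, noiseSd = 0.5, seed = 4)@series))
})

test_that("resting cohort has the requested sizes, demographics and implants", {
  p <- tinyParcellation()
  vx <- regionVoxels(p, 4L)[1:5, ]
  tr <- groundTruth(alffClusters = list(
    list(group = "patient", voxels = vx, amplitude = 4, freqHz = 0.04)))

  cohort <- simulateRestCohort(46, 20, p, tr, durationS = 120, trS = 2,
                               noiseSd = 1, seed = 9)
  man <- cohortManifest(cohort)
  expect_equal(nrow(man), 66)
  expect_equal(sum(man$group == "patient"), 46)
  expect_equal(sum(man$group == "control"), 20)
  # sex assignment at the cohort ratios: 10 M of 46 patients, 6 M of 20 controls
  expect_equal(sum(man$sex == "M" & man$group == "patient"), 10)
  expect_equal(sum(man$sex == "M" & man$group == "control"), 6)
  expect_true(all(man$age > 0))

  # determinism
  cohort2 <- simulateRestCohort(46, 20, p, tr, durationS = 120, trS = 2,
                                noiseSd = 1, seed = 9)
  expect_identical(cohort[[1]]@series, cohort2[[1]]@series)
  expect_error(simulateRestCohort(0, 5, p, tr), "positive")
})

test_that("implanted sinusoid raises patient ALFF by the periodogram-predicted amount", {
  p <- tinyParcellation()
  vx <- regionVoxels(p, 4L)[1:5, ]
  A <- 6; f0 <- 0.05  # exact bin at 120 s / TR 2 (k = 3 of n = 60)
  tr <- groundTruth(alffClusters = list(
    list(group = "patient", voxels = vx, amplitude = A, freqHz = f0)))
  cohort <- simulateRestCohort(8, 8, p, tr, durationS = 120, trS = 2,
                               noiseSd = 0.2, seed = 21)
  man <- cohortManifest(cohort)
  dims <- dim(labelVolume(p))
  lin <- vx[, 1] + (vx[, 2] - 1) * dims[1] + (vx[, 3] - 1) * dims[1] * dims[2]
  clusterAlff <- vapply(cohort, function(s) {
    flat <- matrix(s@series, prod(dims), dim(s@series)[4])
    mean(apply(flat[lin, ], 1, computeAlff, trS = 2, bandHz = c(0.01, 0.08)))
  }, 0)
  patMean <- mean(clusterAlff[man$group == "patient"])
  conMean <- mean(clusterAlff[man$group == "control"])
  expect_gt(patMean, conMean)
  # oracle: ALFF of the noiseless implant itself
  tSec <- (0:59) * 2
  implantAlff <- oracleAlff(A * sin(2 * pi * f0 * tSec + 0.3), trS = 2)
  expect_equal(patMean - conMean, implantAlff, tolerance = 0.15)
})

test_that("activeVoxels resolves the implanted fraction deterministically", {
  p <- tinyParcellation()
  tr <- tinyTruth()
  av <- activeVoxels(tr, p, "positive")
  nExpected <- sum(vapply(tr@activeRegionIds$positive, function(r)
    ceiling(0.5 * nrow(regionVoxels(p, r))), 0))
  expect_equal(nrow(av), nExpected)
  expect_identical(av, activeVoxels(tr, p, "positive"))
  labs <- labelVolume(p)
  expect_true(all(labs[av] %in% tr@activeRegionIds$positive))
})
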