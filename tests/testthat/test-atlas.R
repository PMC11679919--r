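test_that("characteristic region selection recovers implants and orders by importance", {
  td <- tinyTaskData()
  fm <- assembleFeatureMatrix(td$pos, td$parcellation, "positive", "roi")
  sel <- selectCharacteristicRois(fm, C = 1, seed = 2)
  expect_true(all(sel$regionIds %in% regionIds(td$parcellation)))
  # both implanted active regions recovered, and ranked above the noise regions
  expect_true(all(td$truth@activeRegionIds$positive %in% sel$regionIds))
  expect_setequal(head(sel$regionIds, 2), td$truth@activeRegionIds$positive)
  # importance ordering mirrors the selected-subset scores
  expect_equal(sel$regionIds,
               as.integer(sub("region_", "", names(sort(sel$rfe@selectedScores,
                                                        decreasing = TRUE)))))
  expect_error(selectCharacteristicRois(
    assembleFeatureMatrix(td$pos[1:4], td$parcellation, "positive", "voxel",
                          voxelScope = 1L)), "region-level")
})

test_that("sub-ROI voxels stay inside their host region and favor implanted voxels", {
  td <- tinyTaskData()
  host <- td$truth@activeRegionIds$positive[1]
  res <- selectCharacteristicSubrois(td$pos, td$parcellation, host,
                                     C = 1, seed = 3)
  sub <- res$subrois[[as.character(host)]]
  hostVox <- regionVoxels(td$parcellation, host)
  labs <- labelVolume(td$parcellation)
  expect_true(all(labs[sub] == host))
  expect_lte(nrow(sub), nrow(hostVox))
  # monotone reduction: RFE deleted at least one voxel here
  expect_lt(nrow(sub), nrow(hostVox))
  # implanted voxels (50% of the region at effect 3 sd) dominate the survivors
  av <- activeVoxels(td$truth, td$parcellation, "positive")
  av <- av[labs[av] == host, , drop = FALSE]
  dims <- dim(labs)
  avLin <- av[, 1] + (av[, 2] - 1) * dims[1] + (av[, 3] - 1) * dims[1] * dims[2]
  subLin <- sub[, 1] + (sub[, 2] - 1) * dims[1] + (sub[, 3] - 1) * dims[1] * dims[2]
  jaccard <- length(intersect(avLin, subLin)) / length(union(avLin, subLin))
  expect_gte(jaccard, 0.5)
})

test_that("tiny regions are retained wholesale with a warning", {
  # a 2x2x1 grid cannot host an ellipsoid; craft a parcellation directly
  labs <- array(0L, c(4, 4, 4)); labs[2, 2, 2] <- 1L; labs[2:3, 3, 2] <- 2L
  p <- new("Parcellation", labelVolume = labs, voxelSizeMm = c(3, 3, 3),
           originMm = c(0, 0, 0), regionIds = 1:2)
  stim <- array(rnorm(64 * 5), c(4, 4, 4, 5))
  rec <- array(rnorm(64 * 5), c(4, 4, 4, 5))
  blocks <- list(manualBlock(stim, rec), manualBlock(stim + 1, rec - 1, index = 2L))
  expect_warning(res <- selectCharacteristicSubrois(blocks, p, 1L, seed = 1),
                 "wholesale")
  expect_equal(nrow(res$subrois[["1"]]), 1)
})

test_that("pearson correlation matches the longhand quotient", {
  x <- c(2.1, 3.3, 1.8, 5.2, 4.4, 2.9, 3.8, 1.2, 4.9, 3.1)
  y <- c(1.0, 2.7, 1.1, 4.8, 3.9, 2.2, 3.1, 0.4, 4.1, 2.8)
  expect_equal(pearsonR(x, y), oraclePearson(x, y))
  expect_equal(pearsonR(x, x), 1)
  expect_equal(pearsonR(x, -x), -1)
  expect_error(pearsonR(x, rep(1, 10)), "constant")
  expect_error(pearsonR(x, y[1:5]), "lengths")
})

test_that("FC recruitment equals a brute-force scan and applies a strict threshold", {
  td <- tinyTaskData()
  subs <- selectCharacteristicSubrois(td$pos, td$parcellation,
                                      td$truth@activeRegionIds$positive,
                                      C = 1, seed = 3)
  thr <- 0.6  # low threshold so the scan has non-trivial content on noise
  got <- fcExternalVoxels(td$pos, td$parcellation, subs$subrois, threshold = thr)

  # brute-force oracle: correlate every candidate voxel's concatenated
  # series with every sub-ROI reference series
  dims <- dim(labelVolume(td$parcellation))
  series <- do.call(cbind, lapply(td$pos, function(b)
    cbind(matrix(stimulusVolumes(b), prod(dims), 5),
          matrix(recoveryVolumes(b), prod(dims), 5))))
  refs <- lapply(subs$subrois, function(vx) {
    lin <- vx[, 1] + (vx[, 2] - 1) * dims[1] + (vx[, 3] - 1) * dims[1] * dims[2]
    colMeans(series[lin, , drop = FALSE])
  })
  labs <- as.vector(labelVolume(td$parcellation))
  candLin <- which(labs > 0 & !(labs %in% td$truth@activeRegionIds$positive))
  keepOracle <- vapply(candLin, function(v) {
    any(vapply(refs, function(r) cor(series[v, ], r) > thr, TRUE))
  }, TRUE)
  gotLin <- got$voxels[, 1] + (got$voxels[, 2] - 1) * dims[1] +
    (got$voxels[, 3] - 1) * dims[1] * dims[2]
  expect_setequal(gotLin, candLin[keepOracle])
  expect_true(all(got$bestR > thr))
  expect_true(all(labs[gotLin] == got$hosts))

  # strictness: a candidate exactly AT the threshold is not retained
  rSome <- got$bestR[1]
  atThr <- fcExternalVoxels(td$pos, td$parcellation, subs$subrois,
                            threshold = rSome)
  expect_false(gotLin[1] %in%
    (atThr$voxels[, 1] + (atThr$voxels[, 2] - 1) * dims[1] +
       (atThr$voxels[, 3] - 1) * dims[1] * dims[2]))

  # threshold monotonicity: raising the threshold never enlarges the set
  tighter <- fcExternalVoxels(td$pos, td$parcellation, subs$subrois,
                              threshold = thr + 0.1)
  expect_lte(nrow(tighter$voxels), nrow(got$voxels))
  # a candidate identical to a reference is retained at any threshold < 1
  expect_true(nrow(got$voxels) == 0 ||
              max(got$bestR) <= 1 + 1e-12)
})

test_that("atlas assembly enforces disjointness and counts provenance", {
  td <- tinyTaskData()
  p <- td$parcellation
  subrois <- list("1" = regionVoxels(p, 1L)[1:4, ],
                  "3" = regionVoxels(p, 3L)[1:2, ])
  ext <- list(voxels = rbind(regionVoxels(p, 2L)[1, ], regionVoxels(p, 4L)[1, ],
                             regionVoxels(p, 5L)[1, ]),
              hosts = c(2L, 4L, 5L))
  atlas <- assembleAtlas(subrois, ext, p, "positive")
  expect_equal(nRegionsTouched(atlas), 5)
  expect_equal(nrow(atlasVoxels(atlas)), 4 + 2 + 3)
  expect_equal(sum(atlasMask(atlas)), 9)
  prov <- atlasProvenance(atlas)
  expect_equal(sum(prov$origin == "subroi"), 6)
  expect_equal(sum(prov$origin == "external"), 3)

  # empty externals: regions touched = sub-ROI hosts
  a2 <- assembleAtlas(subrois, list(voxels = NULL, hosts = integer()), p,
                      "positive")
  expect_equal(nRegionsTouched(a2), 2)

  # overlap with a characteristic region is an invariant violation
  badExt <- list(voxels = regionVoxels(p, 1L)[5, , drop = FALSE], hosts = 1L)
  expect_error(assembleAtlas(subrois, badExt, p, "positive"), "overlap")
})
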