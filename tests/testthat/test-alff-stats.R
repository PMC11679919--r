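test_that("ALFF matches an independent periodogram oracle and is homogeneous", {
  tr <- 2; n <- 150
  t <- (0:(n - 1)) * tr
  expect_equal(computeAlff(rep(0, n), tr), 0)

  # out-of-band exact-bin sinusoid (0.2 Hz = bin 60): orthogonal to the band.
  # phase-symmetric about the series midpoint so the linear detrend is a
  # no-op and orthogonality is exact
  out <- cos(2 * pi * 0.2 * (t - mean(t)))
  expect_lt(computeAlff(out, tr), 1e-10)

  # in-band exact-bin sinusoid (0.04 Hz = bin 12): oracle agreement and
  # amplitude linearity
  for (A in c(1, 2)) {
    x <- A * sin(2 * pi * 0.04 * t + 0.7)
    expect_equal(computeAlff(x, tr), oracleAlff(x, tr), tolerance = 1e-10)
  }
  x1 <- sin(2 * pi * 0.04 * t + 0.7)
  expect_equal(computeAlff(2 * x1, tr), 2 * computeAlff(x1, tr))

  # scale homogeneity incl. sign, on arbitrary data after detrending
  set.seed(9)
  z <- rnorm(n) + 0.03 * seq_len(n)
  expect_equal(computeAlff(-3 * z, tr), 3 * computeAlff(z, tr), tolerance = 1e-12)
  expect_equal(computeAlff(z, tr), oracleAlff(z, tr), tolerance = 1e-10)

  expect_error(computeAlff(rnorm(100), tr, bandHz = c(0.05, 0.5)), "Nyquist")
})

test_that("ALFF maps are aligned, homogeneous under the null, and detect implants", {
  p <- tinyParcellation()
  dims <- dim(labelVolume(p))
  tr0 <- groundTruth()
  rec <- simulateRestCohort(1, 1, p, tr0, durationS = 300, trS = 2,
                            noiseSd = 1, seed = 17)[[1]]
  m <- alffMap(rec, parcellation = p)
  expect_equal(dim(alffValues(m)), dims)
  fg <- labelVolume(p) > 0
  expect_true(all(alffValues(m)[!fg] == 0))
  vals <- alffValues(m)[fg]
  # null map is spatially homogeneous: CoV < 0.2 at 150 volumes
  expect_lt(sd(vals) / mean(vals), 0.2)

  # implanted 0.04 Hz cluster raises cluster-mean ALFF
  vx <- regionVoxels(p, 2L)[1:6, ]
  tr1 <- groundTruth(alffClusters = list(
    list(group = "patient", voxels = vx, amplitude = 2, freqHz = 0.04)))
  rec1 <- simulateRestCohort(1, 1, p, tr1, durationS = 300, trS = 2,
                             noiseSd = 1, seed = 18)[[1]]
  m1 <- alffValues(alffMap(rec1, parcellation = p))
  inside <- mean(m1[vx])
  outside <- mean(m1[fg]) # cluster is a tiny share of foreground
  expect_gt(inside, outside)
})

test_that("covariate removal matches the normal equations", {
  age <- c(21, 34, 28, 45, 39, 52)
  sex <- c("M", "F", "F", "M", "F", "M")
  # perfect fit: values linear in age
  expect_lt(max(abs(regressOutCovariates(3 + 0.5 * age, age, sex))), 1e-10)

  # normal-equations oracle on a toy set
  set.seed(3)
  v <- rnorm(6)
  D <- cbind(1, age, as.numeric(sex == "F"))
  beta <- solve(t(D) %*% D, t(D) %*% v)
  expect_equal(regressOutCovariates(v, age, sex),
               as.numeric(v - D %*% beta), tolerance = 1e-10)

  # covariates orthogonal to values: residuals are the centered values
  vOrth <- as.numeric(v - D %*% beta)
  expect_equal(regressOutCovariates(vOrth, age, sex), vOrth, tolerance = 1e-10)

  expect_error(regressOutCovariates(v, rep(1, 6), rep("M", 6)), "collinear")
  expect_error(regressOutCovariates(v[1:3], age[1:3], sex[1:3]), "at least 4")
})

test_that("voxelwise t-test is zero for identical groups and exact on a toy voxel", {
  dims <- c(3, 3, 3)
  set.seed(5)
  A <- lapply(1:3, function(i) array(abs(rnorm(27)), dims))
  tt <- voxelwiseTtest(A, A)
  expect_true(all(tt$tMap == 0))

  # hand toy: A = B = {1,2,3} at every voxel -> t = 0, p = 1
  mk <- function(v) array(v, dims)
  tt2 <- voxelwiseTtest(lapply(1:3, mk), lapply(1:3, mk))
  expect_true(all(tt2$tMap == 0))
  expect_true(all(tt2$pMap == 1))
  expect_equal(tt2$df, 4)

  # orientation: patients higher -> positive t; covariates reduce df
  B <- lapply(1:3, function(i) A[[i]] + 2)
  tt3 <- voxelwiseTtest(B, A)
  expect_true(all(tt3$tMap > 0))
  tt4 <- voxelwiseTtest(B, A, age = c(30, 40, 50, 35, 45, 55),
                        sex = c("M", "F", "M", "F", "M", "F"))
  expect_equal(tt4$df, 2)
  expect_error(voxelwiseTtest(A[1], A), "at least 2")
})

test_that("BH-FDR equals the brute-force step-up definition", {
  p <- c(0.001, 0.008, 0.039, 0.041)
  expect_equal(fdrBh(p, q = 0.01), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(fdrBh(p, q = 0.01), oracleBhStepUp(p, 0.01))
  expect_false(any(fdrBh(rep(1, 10), 0.01)))
  expect_true(all(fdrBh(rep(0, 10), 0.01)))
  expect_length(fdrBh(numeric(0), 0.01), 0)

  set.seed(12)
  for (i in 1:10) {
    pv <- runif(50)^2
    for (q in c(0.01, 0.05, 0.2))
      expect_equal(fdrBh(pv, q), oracleBhStepUp(pv, q))
    # FDR dominance: q = 0.01 rejections are a subset of q = 0.05
    expect_true(all(fdrBh(pv, 0.01) <= fdrBh(pv, 0.05)))
  }
})

test_that("cluster extraction matches flood fill and reports physical sizes", {
  p <- makeParcellation(c(10, 10, 10), 4, seed = 2)
  dims <- c(10, 10, 10)

  # single significant voxel at 3 mm isotropic: 27 mm^3
  m1 <- array(FALSE, dims); m1[5, 5, 5] <- TRUE
  tmap <- array(0, dims); tmap[5, 5, 5] <- -3.2
  cl1 <- extractClusters(m1, tmap, p)
  expect_equal(cl1$nVoxels, 1)
  expect_equal(cl1$sizeMm3, 27)
  expect_equal(cl1$peakIntensity, -3.2)

  # 3 face-connected voxels: one cluster of 81 mm^3
  m3 <- array(FALSE, dims); m3[4:6, 5, 5] <- TRUE
  t3 <- array(0, dims); t3[4:6, 5, 5] <- c(2, 4.5, 1)
  cl3 <- extractClusters(m3, t3, p, connectivity = 6)
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$sizeMm3, 81)
  expect_equal(cl3$peakIntensity, 4.5)
  expect_equal(c(cl3$peakI, cl3$peakJ, cl3$peakK), c(5, 5, 5))
  # world coordinate via the voxel-to-world mapping (origin 0, 3 mm voxels)
  expect_equal(c(cl3$peakXmm, cl3$peakYmm, cl3$peakZmm), c(4, 4, 4) * 3)

  # random mask: component structure equals the flood-fill oracle
  set.seed(77)
  for (conn in c(6, 18, 26)) {
    mr <- array(runif(1000) < 0.2, dims)
    tr <- array(rnorm(1000), dims)
    got <- extractClusters(mr, tr, p, connectivity = conn)
    oracle <- oracleFloodFill(mr, conn)
    expect_equal(sum(got$nVoxels), sum(mr))
    expect_equal(nrow(got), max(oracle))
    expect_setequal(got$nVoxels, as.integer(table(oracle[oracle > 0])))
  }

  # empty mask -> empty table
  expect_equal(nrow(extractClusters(array(FALSE, dims), tmap, p)), 0)
})

test_that("groupComparison wires test, FDR and clusters together", {
  p <- tinyParcellation()
  dims <- dim(labelVolume(p))
  vx <- regionVoxels(p, 3L)[1:4, ]
  set.seed(41)
  mkMap <- function(shift) {
    a <- array(abs(rnorm(prod(dims), mean = 5, sd = 0.3)), dims)
    a[vx] <- a[vx] + shift
    a
  }
  A <- lapply(1:10, function(i) mkMap(3))
  B <- lapply(1:10, function(i) mkMap(0))
  gc <- groupComparison(A, B, p, mask = labelVolume(p) > 0, q = 0.01)
  tab <- clusterTable(gc)
  expect_gt(nrow(tab), 0)
  lin <- tab$peakI + (tab$peakJ - 1) * dims[1] + (tab$peakK - 1) * dims[1] * dims[2]
  vxLin <- vx[, 1] + (vx[, 2] - 1) * dims[1] + (vx[, 3] - 1) * dims[1] * dims[2]
  expect_true(any(lin %in% vxLin))
  expect_true(all(tab$peakIntensity > 0))  # A higher than B
})
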