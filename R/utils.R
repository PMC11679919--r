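# Internal helpers shared across modules.

# Evaluate expr with a local, seeded RNG state; the caller's RNG stream is
# untouched. All stochastic operations in the package funnel through this so
# a seed argument fully determines their output.
withLocalSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a master seed, kept inside 32-bit range.
deriveSeed <- function(masterSeed, offset) {
  as.integer((as.numeric(masterSeed) * 1009 + offset * 9176) %% 2147483647)
}

# Linear index <-> (i,j,k) for a 3D grid. `ijk` is an n x 3 integer matrix.
ijkToLinear <- function(ijk, dims) {
  as.integer(ijk[, 1] + (ijk[, 2] - 1L) * dims[1] + (ijk[, 3] - 1L) * dims[1] * dims[2])
}

linearToIjk <- function(lin, dims) {
  lin <- as.integer(lin) - 1L
  i <- lin %% dims[1]
  j <- (lin %/% dims[1]) %% dims[2]
  k <- lin %/% (dims[1] * dims[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

# Flatten the spatial axes of a 4D series to a voxels x time matrix.
flattenSeries <- function(series) {
  d <- dim(series)
  dim(series) <- c(prod(d[1:3]), d[4])
  series
}

# Row-wise min/max for a small matrix (columns = time points).
rowRange <- function(m) {
  lo <- m[, 1]; hi <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) {
    lo <- pmin(lo, m[, j]); hi <- pmax(hi, m[, j])
  }
  list(min = lo, max = hi)
}

# Stratified fold assignment: within each class, shuffle (seeded) and deal
# round-robin. Returns an integer fold id per sample. Errors if any training
# fold would lose a class entirely.
stratifiedFolds <- function(y, nFolds, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  withLocalSeed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  for (f in seq_len(nFolds)) {
    if (nlevels(droplevels(y[fold != f])) < 2L)
      stop("fold construction left a training fold with a single class")
  }
  fold
}

# 3D neighbourhood offsets for a given connectivity (6, 18 or 26).
connectivityOffsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1,
    "18" = nz >= 1 & nz <= 2,
    "26" = nz >= 1
  )
  off[keep, , drop = FALSE]
}
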