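# Independent oracles used by the tests. These are deliberately written
# with different algorithms/primitives than the package implementation.

# Recursive flood fill (stack-based to avoid C-stack limits) over a 3D mask.
oracleFloodFill <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, nz >= 1), ,
             drop = FALSE]
  labels <- array(0L, dims)
  lab <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if (!mask[i, j, k] || labels[i, j, k] > 0L) next
    lab <- lab + 1L
    stack <- list(c(i, j, k))
    labels[i, j, k] <- lab
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(off))) {
        nb <- v + off[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (mask[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- lab
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  labels
}

# Periodogram-based ALFF: explicit cosine/sine projections (no fft), after
# removing an OLS linear trend fitted longhand.
oracleAlff <- function(series, trS, bandHz = c(0.01, 0.08)) {
  n <- length(series)
  tt <- seq_len(n)
  beta <- cov(tt, series) / var(tt)
  alpha <- mean(series) - beta * mean(tt)
  x <- series - alpha - beta * tt
  ks <- seq_len(floor(n / 2))
  amps <- vapply(ks, function(k) {
    a <- sum(x * cos(2 * pi * k * (seq_len(n) - 1) / n)) * 2 / n
    b <- sum(x * sin(2 * pi * k * (seq_len(n) - 1) / n)) * 2 / n
    sqrt(a^2 + b^2)
  }, 0)
  freq <- ks / (n * trS)
  sel <- freq >= bandHz[1] - 1e-12 & freq <= bandHz[2] + 1e-12
  mean(amps[sel])
}

# Literal step-up definition of Benjamini-Hochberg rejection.
oracleBhStepUp <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0L
  for (i in seq_len(m)) if (ps[i] <= q * i / m) kmax <- i
  rej <- logical(m)
  if (kmax > 0L) rej[ord[seq_len(kmax)]] <- TRUE
  rej
}

# Independent stratified-fold CV accuracy of an RBF-free linear SVM on a
# feature subset, with its own fold construction (interleaved by class
# order after a seeded permutation distinct from the package helper).
oracleCvAccuracy <- function(X, y, subset, C = 1, nFolds = 10, seed = 1) {
  X <- as.matrix(X)[, subset, drop = FALSE]
  y <- factor(y)
  set.seed(seed * 7919)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- (seq_along(idx) - 1L) %% nFolds + 1L
  }
  correct <- 0L
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                    cost = C, scale = FALSE)
    correct <- correct + sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
  }
  correct / length(y)
}

# Longhand Pearson correlation via the covariance/sd quotient.
oraclePearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  num / (sqrt(sum((x - mean(x))^2) / (n - 1)) * sqrt(sum((y - mean(y))^2) / (n - 1)))
}
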