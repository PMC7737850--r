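# Shared fixtures: everything is generated in code at test time.

# a small cohort that trains in well under a second
tinyCohort <- function(seed = 1, n = 300, p = 30, nInformative = 4,
                       signalStrength = 2) {
  generateCohort(SimConfig(
    nPatients = n, nFeatures = p, nInformative = nInformative,
    sparsity = 0.9, plantedSparsity = 0.6,
    signalStrength = signalStrength, seed = seed))
}

# a training configuration sized for unit tests
tinyConfig <- function(seed = 1, ...) {
  args <- list(hiddenSizes = c(8L, 4L), nEpochs = 10L, nSnapshots = 2L,
               batchSize = 64L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(TrainConfig, args)
}

# normalized patient matrix + labels from a cohort
normalizedData <- function(cohort) {
  norm <- normalizeFeatures(patientMatrix(cohort, dense = TRUE))
  list(x = norm$values, y = outcomeLabels(cohort), stats = norm$stats)
}

# independent forward-pass oracle: explicit loops, no shared code path
oracleForward <- function(params, X) {
  vapply(seq_len(nrow(X)), function(i) {
    a <- X[i, ]
    L <- length(params@weights)
    for (l in seq_len(L)) {
      W <- params@weights[[l]]
      z <- numeric(ncol(W))
      for (k in seq_len(ncol(W)))
        z[k] <- sum(W[, k] * a) + params@biases[[l]][k]
      a <- if (l == L) 1 / (1 + exp(-z)) else pmax(z, 0)
    }
    a
  }, numeric(1))
}

# independent Feature Sparsity Importance oracle: literal per-feature loops
oracleImportance <- function(W1) {
  p <- nrow(W1); J <- ncol(W1)
  means <- numeric(p); vars <- numeric(p)
  for (k in seq_len(p)) {
    col <- abs(W1[k, ])
    means[k] <- sum(col) / J
    vars[k] <- sum((col - means[k])^2) / (J - 1)
  }
  mx <- max(means)
  if (mx == 0) rep(0, p) else (means - vars) / mx
}
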