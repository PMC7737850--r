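test_that("weight variance uses the J-1 denominator", {
  expect_equal(weightVariance(c(0.5, 0.5)), 0)
  expect_equal(weightVariance(c(1, 0)), 0.5)        # (0.25 + 0.25) / 1
  expect_equal(weightVariance(c(1, 0, 1)), 1 / 3)
  expect_error(weightVariance(0.4), "J >= 2")
})

test_that("feature importance rewards full connectivity and penalizes element-wise sparsity", {
  # fully connected vs disconnected extremes
  W <- rbind(A = c(1, 1, 1), B = c(0, 0, 0))
  expect_equal(featureImportance(W), c(A = 1, B = 0))

  # same max mean: the feature with scattered weights is penalized
  W2 <- rbind(A = c(1, 0), B = c(1, 1))
  expect_equal(featureImportance(W2), c(A = 0, B = 1))

  # all-zero matrix: all importances zero by convention
  expect_equal(unname(featureImportance(matrix(0, 3, 4))), rep(0, 3))

  expect_error(featureImportance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("feature importance matches the literal brute-force oracle", {
  set.seed(11)
  for (i in 1:25) {
    W1 <- matrix(runif(20 * 5), 20, 5)
    expect_equal(unname(featureImportance(W1)), oracleImportance(W1),
                 tolerance = 1e-12)
  }
})

test_that("importance is not scale-invariant (documented non-invariance)", {
  # multiplying W1 by c scales means by c but variances by c^2, so the
  # ranking can change; a 'normalize first' refactor would break this.
  set.seed(4)
  W1 <- matrix(runif(30, 0.3, 0.9), 10, 3)
  expect_false(isTRUE(all.equal(featureImportance(W1 / 2),
                                featureImportance(W1))))
  expect_false(isTRUE(all.equal(featureImportance(W1 / 3) * 3,
                                featureImportance(W1))))
})

test_that("for fixed mean, importance strictly decreases with column variance", {
  # three features, identical mean 0.5, increasing spread
  W <- rbind(c(0.5, 0.5, 0.5, 0.5),
             c(0.7, 0.3, 0.7, 0.3),
             c(1.0, 0.0, 1.0, 0.0))
  R <- unname(featureImportance(W))
  expect_true(all(diff(R) < 0))
})

test_that("aggregation is the elementwise mean across snapshots", {
  expect_equal(aggregateImportance(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  v <- c(0.2, 0.8, 0.5)
  expect_equal(aggregateImportance(matrix(v, 1, byrow = TRUE)), v)
  expect_equal(aggregateImportance(rbind(v, v, v)), v)
  expect_error(aggregateImportance(list(c(1, 2), c(1, 2, 3))), "length")
})

test_that("features are categorized disconnected/partial/full", {
  W <- rbind(c(0.01, 0.03), c(0.95, 0.99), c(0.95, 0.02))
  expect_equal(unname(categorizeFeatures(W)),
               c("disconnected", "full", "partial"))
  expect_error(categorizeFeatures(W, low = 0.9, high = 0.1), "low < high")
})

test_that("top-k selection orders by importance with name tie-breaks", {
  R <- c(f1 = 0.9, f2 = 0.1, f3 = 0.5)
  sel <- selectTopK(R, 2)
  expect_equal(selectedFeatures(sel), c("f1", "f3"))

  tied <- c(b = 0.5, a = 0.5, c = 0.1)
  expect_equal(selectedFeatures(selectTopK(tied, 1)), "a")

  all3 <- selectTopK(R, 3)
  expect_equal(selectedFeatures(all3), c("f1", "f3", "f2"))

  # idempotence: reselecting the selected set returns it unchanged
  again <- selectTopK(all3@selected[1:2], 2)
  expect_equal(selectedFeatures(again), selectedFeatures(sel))

  expect_error(selectTopK(R, 0), "k must")
  expect_error(selectTopK(R, 4), "k must")
})

test_that("sigma-outlier selection thresholds at mu + n*sigma with strict inequality", {
  set.seed(2)
  v <- stats::setNames(rnorm(100, 0.08, 0.005), sprintf("f%03d", 1:100))
  v["f999"] <- 0.5
  sel <- selectOutliers(v, nSigma = 3)
  # verify against the definition computed here
  expect_true(all(v[selectedFeatures(sel)] > mean(v) + 3 * sd(v)))
  expect_equal(selectedFeatures(sel), "f999")

  flat <- stats::setNames(rep(0.3, 10), letters[1:10])
  expect_length(selectedFeatures(selectOutliers(flat)), 0)  # sigma = 0
})

test_that("cumulative selection takes the smallest prefix reaching the quantile", {
  R <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(selectedFeatures(selectCumulative(R, 0.79)), c("a", "b"))
  expect_equal(selectedFeatures(selectCumulative(R, 0.999)), c("a", "b", "c"))

  oneHot <- c(a = 0, b = 0.4, c = 0)
  expect_equal(selectedFeatures(selectCumulative(oneHot, 0.5)), "b")
  expect_equal(selectedFeatures(selectCumulative(oneHot, 0.95)), "b")

  # negatives are floored at zero; zero total -> empty
  expect_length(selectedFeatures(selectCumulative(c(a = -1, b = 0), 0.9)), 0)
})

test_that("all selection policies return descending-ordered subsets", {
  set.seed(9)
  v <- stats::setNames(runif(50), sprintf("f%02d", 1:50))
  for (sel in list(selectTopK(v, 12), selectOutliers(v, 1),
                   selectCumulative(v, 0.6))) {
    expect_true(all(diff(sel@selected) <= 0))
    expect_true(all(selectedFeatures(sel) %in% names(v)))
  }
})

test_that("importanceReport aggregates per-snapshot values consistently", {
  d <- normalizedData(tinyCohort(seed = 6))
  ens <- trainSnapshots(d$x, d$y, config = tinyConfig(seed = 3, nSnapshots = 3L,
                                                      nEpochs = 9L))
  rep <- importanceReport(ens, featureNames = colnames(d$x))
  expect_s4_class(rep, "ImportanceReport")
  expect_equal(dim(rep@perSnapshot), c(3, ncol(d$x)))
  expect_equal(unname(importanceValues(rep)), unname(colMeans(rep@perSnapshot)))
  expect_equal(rep@mu, mean(importanceValues(rep)))
  expect_true(all(rep@categories %in% c("disconnected", "partial", "full")))
  # per-snapshot rows agree with featureImportance on the raw first layers
  for (m in 1:3)
    expect_equal(unname(rep@perSnapshot[m, ]),
                 unname(featureImportance(snapshots(ens)[[m]]@weights[[1]])))
})
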