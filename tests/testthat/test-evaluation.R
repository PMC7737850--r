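test_that("confusion metrics recompute from counts and flag undefined ratios", {
  m <- confusionMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(unname(m$counts), c(1, 0, 2, 1))       # TP FP TN FN
  expect_equal(m$metrics[["accuracy"]], 0.75)
  expect_equal(m$metrics[["tpr"]], 0.5)
  expect_equal(m$metrics[["tnr"]], 1)
  expect_equal(m$metrics[["ppv"]], 1)
  expect_equal(m$metrics[["npv"]], 2 / 3)
  expect_equal(m$metrics[["f1"]], 2 / 3)

  perfect <- confusionMetrics(c(1, 0, 1), c(1, 0, 1))
  expect_true(all(perfect$metrics == 1))

  # inactive always-positive model on balanced labels
  inact <- confusionMetrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(inact$metrics[["tpr"]], 1)
  expect_equal(inact$metrics[["tnr"]], 0)
  expect_equal(inact$metrics[["accuracy"]], 0.5)
  expect_true(is.nan(inact$metrics[["npv"]]))         # 0/0, never silently 0

  expect_error(confusionMetrics(c(1, 0), c(1, 0, 1)), "length")
})

test_that("runCV produces k x repeats paired evaluations without leakage shortcuts", {
  cohort <- tinyCohort(seed = 4, n = 200, p = 15)
  cfg <- tinyConfig(seed = 9, cvK = 4L, cvRepeats = 2L)
  cv <- runCV(cohort, cfg)
  expect_equal(nrow(cv$perEvaluation), 8)
  metricNames <- c("accuracy", "tpr", "tnr", "ppv", "npv", "f1")
  expect_true(all(metricNames %in% names(cv$perEvaluation)))
  expect_equal(sort(cv$aggregate$metric), sort(metricNames))

  # restricting to the full feature set changes nothing
  cvAll <- runCV(cohort, cfg, featureSubset = eventCodes(cohort),
                 foldPlan = cv$foldPlan)
  expect_equal(cvAll$perEvaluation, cv$perEvaluation)

  expect_error(runCV(cohort, cfg, featureSubset = "no_such_code"), "unknown")
})

test_that("Pearson feature correlation reduces to phi for binary pairs", {
  expect_equal(pearsonFeatureCorrelation(1:3, c(1, 2, 3))$r, 1)
  expect_equal(pearsonFeatureCorrelation(1:3, c(3, 2, 1))$r, -1)

  # 2x2 table TP=4 FP=1 FN=1 TN=4 -> phi = 0.6
  x <- c(rep(1, 5), rep(0, 5))
  y <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(pearsonFeatureCorrelation(x, y)$r, 0.6, tolerance = 1e-12)

  expect_error(pearsonFeatureCorrelation(rep(1, 5), c(1, 0, 1, 0, 1)),
               "constant")
})

test_that("paired t-test matches the closed form and rejects degenerate input", {
  a <- c(0.7, 0.8, 0.9)
  b <- c(0.6, 0.7, 0.85)
  res <- pairedTTest(a, b)
  # closed-form oracle computed here from the definition
  d <- a - b
  tOracle <- mean(d) / (sd(d) / sqrt(3))
  pOracle <- 2 * pt(-abs(tOracle), df = 2)
  expect_equal(res$t, tOracle, tolerance = 1e-10)
  expect_equal(res$p.value, pOracle, tolerance = 1e-10)

  expect_error(pairedTTest(a, a), "zero variance")
  expect_error(pairedTTest(a, a + 0.1), "zero variance")
  expect_error(pairedTTest(a, c(1, 2)), "length")
})

test_that("random subsets are seeded draws without replacement", {
  expect_equal(sort(randomSubset(7, 7, seed = 3)), 1:7)
  expect_identical(randomSubset(50, 10, seed = 5), randomSubset(50, 10, seed = 5))
  expect_length(randomSubset(10, 0), 0)
  expect_error(randomSubset(5, 6), "exceed")
})

test_that("backward-stepwise elimination removes noise features before signal", {
  # lambda = 0 isolates the elimination logic from the entropy regularizer,
  # which at this tiny width can pin the first layer to zero before the
  # data gradient builds up
  stepCfg <- function(seed) {
    TrainConfig(hiddenSizes = c(16L, 8L), nEpochs = 120L, nSnapshots = 3L,
                batchSize = 64L, alpha0 = 0.3, lambda = 0, seed = seed)
  }
  stepCohort <- function(seed) {
    generateCohort(SimConfig(nPatients = 600, nFeatures = 12,
                             nInformative = 2, sparsity = 0.9,
                             plantedSparsity = 0.3, signalStrength = 5,
                             seed = seed))
  }

  # subset of two informative features: both survive
  cohort <- stepCohort(21)
  pl <- plantedFeatures(cohort)
  keep <- backwardStepwise(cohort, pl, config = stepCfg(3), tol = 0.02)
  expect_setequal(keep$subset, pl)

  # planted + pure-noise starters: the noise features fall first
  # (majority over seeds)
  hits <- 0L
  for (seed in 1:3) {
    co <- stepCohort(31 + seed)
    plC <- plantedFeatures(co)
    noise <- setdiff(eventCodes(co), plC)[1:2]
    res <- backwardStepwise(co, c(plC, noise), config = stepCfg(3),
                            tol = 0.02)
    dropped <- res$trace$dropped[-1]
    if (length(dropped) && all(dropped %in% noise)) hits <- hits + 1L
  }
  expect_gte(hits, 2L)

  expect_error(backwardStepwise(cohort, pl[1], config = stepCfg(1)),
               "at least two")
})

test_that("random-forest baseline ranks planted features above background", {
  cohort <- tinyCohort(seed = 13, n = 300, p = 20, nInformative = 3,
                       signalStrength = 3)
  imp <- rfBaselineRanking(cohort, nTrees = 200, seed = 7)
  expect_length(imp, 20)
  expect_named(imp)
  pl <- plantedFeatures(cohort)
  noise <- setdiff(names(imp), pl)
  expect_true(all(imp[pl] > median(imp[noise])))

  # deterministic given the seed
  expect_identical(rfBaselineRanking(cohort, nTrees = 200, seed = 7), imp)

  # plugs into the shared selection interface
  sel <- selectTopK(imp, 3)
  expect_setequal(selectedFeatures(sel), pl)

  oneClass <- EventMatrix(patientMatrix(cohort, dense = TRUE),
                          labels = rep(1, 300))
  expect_error(rfBaselineRanking(oneClass), "single-class")
})

test_that("random-forest baseline finds no outliers on label-free noise (majority of seeds)", {
  clean <- 0L
  for (seed in 1:3) {
    co <- generateCohort(SimConfig(nPatients = 200, nFeatures = 15,
                                   nInformative = 3, signalStrength = 0,
                                   seed = 60 + seed))
    imp <- rfBaselineRanking(co, nTrees = 100, seed = seed)
    if (length(selectedFeatures(selectOutliers(imp, nSigma = 3))) == 0)
      clean <- clean + 1L
  }
  expect_gte(clean, 2L)
})
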