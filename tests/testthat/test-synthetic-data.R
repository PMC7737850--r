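test_that("generated cohorts match the configured sparsity and are reproducible", {
  cfg <- SimConfig(nPatients = 50, nFeatures = 100, nInformative = 10,
                   sparsity = 0.95, seed = 1)
  cohort <- generateCohort(cfg)
  X <- patientMatrix(cohort, dense = TRUE)
  expect_equal(dim(X), c(50, 100))

  # background columns: zero fraction within a binomial 99.9% band of 0.95
  bg <- setdiff(colnames(X), plantedFeatures(cohort))
  nCells <- 50 * length(bg)
  zf <- mean(X[, bg] == 0)
  expect_lt(abs(zf - 0.95), 3.3 * sqrt(0.95 * 0.05 / nCells))

  # planted columns follow their own (denser) sparsity
  pl <- plantedFeatures(cohort)
  expect_lt(mean(X[, pl] == 0), 0.85)

  # determinism: same seed, bit-identical cohort
  again <- generateCohort(cfg)
  expect_identical(patientMatrix(again, dense = TRUE), X)
  expect_identical(outcomeLabels(again), outcomeLabels(cohort))
  expect_identical(plantedFeatures(again), pl)

  expect_error(generateCohort(SimConfig(nFeatures = 5, nInformative = 10)),
               "nInformative")
})

test_that("zero signal strength makes labels independent of every feature", {
  cohort <- generateCohort(SimConfig(nPatients = 400, nFeatures = 50,
                                     signalStrength = 0, seed = 7))
  X <- patientMatrix(cohort, dense = TRUE)
  y <- outcomeLabels(cohort)
  r <- abs(suppressWarnings(stats::cor(X, y)))
  expect_true(all(r[is.finite(r)] < 3 / sqrt(400)))
})

test_that("planted features correlate with labels more than background features", {
  for (seed in 1:3) {
    cohort <- generateCohort(SimConfig(nPatients = 1000, nFeatures = 100,
                                       nInformative = 10, seed = seed))
    X <- patientMatrix(cohort, dense = TRUE)
    y <- outcomeLabels(cohort)
    r <- abs(suppressWarnings(stats::cor(X, y)))[, 1]
    pl <- plantedFeatures(cohort)
    expect_gt(mean(r[pl], na.rm = TRUE),
              mean(r[setdiff(colnames(X), pl)], na.rm = TRUE))
  }
})

test_that("encodeEvents tabulates, aggregates duplicates and ignores record order", {
  log <- data.frame(patient_id = c("pA", "pB"),
                    event_code = c("E00..", "bd3.."),
                    count = c(2, 1))
  m <- patientMatrix(encodeEvents(log), dense = TRUE)
  expect_equal(unname(m), rbind(c(2, 0), c(0, 1)))
  expect_equal(colnames(m), c("E00..", "bd3.."))

  dup <- data.frame(patient_id = c("pA", "pA"),
                    event_code = c("E00..", "E00.."), count = c(1, 2))
  expect_equal(as.vector(patientMatrix(encodeEvents(dup), dense = TRUE)), 3)

  single <- data.frame(patient_id = "p1", event_code = "c1", count = 5)
  expect_equal(dim(patientMatrix(encodeEvents(single))), c(1, 1))

  shuffled <- log[c(2, 1), ]
  expect_identical(patientMatrix(encodeEvents(shuffled), dense = TRUE), m)

  bad <- data.frame(patient_id = "p", event_code = "c", count = -1)
  expect_error(encodeEvents(bad), "non-negative")
})

test_that("normalizeFeatures scales to [0,1], handles constants, and clips", {
  out <- normalizeFeatures(cbind(f = c(0, 2, 4)))
  expect_equal(as.vector(out$values), c(0, 0.5, 1))

  const <- normalizeFeatures(cbind(f = c(3, 3)))
  expect_equal(as.vector(const$values), c(0, 0))

  # test value above the training max clips to 1
  trainStats <- normalizeFeatures(cbind(f = c(0, 4)))$stats
  clipped <- normalizeFeatures(cbind(f = 10), referenceStats = trainStats)
  expect_equal(as.vector(clipped$values), 1)

  # idempotence: renormalizing normalized data with its own stats is a no-op
  X <- matrix(rpois(60, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  n1 <- normalizeFeatures(X)
  n2 <- normalizeFeatures(n1$values, referenceStats = normalizeFeatures(n1$values)$stats)
  expect_equal(n2$values, n1$values)

  wrong <- trainStats
  wrong$feature <- "other"
  expect_error(normalizeFeatures(cbind(f = 1), referenceStats = wrong),
               "do not match")
})

test_that("fold plans partition patients with cyclic three-role rotation", {
  plan <- makeCVFolds(10, k = 5, repeats = 2, seed = 1)
  expect_s4_class(plan, "FoldPlan")
  asg <- foldAssignments(plan)
  expect_length(asg, 2)
  expect_length(asg[[1]], 5)

  for (r in 1:2) {
    tested <- sort(unlist(lapply(asg[[r]], `[[`, "test")))
    expect_equal(tested, 1:10)              # each patient tested once
    for (ev in asg[[r]]) {
      expect_length(ev$test, 2)             # 10 / 5: every fold size 2
      expect_length(ev$validation, 2)
      expect_length(ev$train, 6)            # k - 2 folds
      expect_equal(sort(c(ev$train, ev$validation, ev$test)), 1:10)
    }
  }
  expect_error(makeCVFolds(10, k = 2), "k must be >= 3")
})
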