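test_that("cosine schedule evaluates the closed form with 1-based restarts", {
  expect_equal(cosineLR(1, 0.1, 100, 5), 0.1)                 # cycle start
  expect_equal(cosineLR(11, 0.1, 100, 5), 0.05)               # mid-cycle
  expect_equal(cosineLR(20, 0.1, 100, 5),
               0.05 * (1 + cos(19 * pi / 20)), tolerance = 1e-12)
  expect_equal(cosineLR(21, 0.1, 100, 5), 0.1)                # restart spike
  expect_error(cosineLR(0, 0.1, 100, 5), ">= 1")
  expect_error(cosineLR(101, 0.1, 100, 5), "exceeds")
})

test_that("cosine schedule stays in (0, alpha0], peaks at cycle starts, decays within cycles", {
  for (cfg in list(c(T = 100, M = 5), c(T = 30, M = 3), c(T = 17, M = 4))) {
    a <- cosineLR(seq_len(cfg["T"]), 0.2, cfg["T"], cfg["M"])
    expect_true(all(a > 0 & a <= 0.2))
    cl <- ceiling(cfg["T"] / cfg["M"])
    starts <- seq(1, cfg["T"], by = cl)
    expect_true(all(abs(a[starts] - 0.2) < 1e-12))
    for (s in starts) {
      cyc <- a[s:min(s + cl - 1, cfg["T"])]
      expect_true(all(diff(cyc) < 0))      # strictly decreasing within a cycle
    }
  }
})

test_that("training captures M snapshots and is deterministic in the seed", {
  d <- normalizedData(tinyCohort(seed = 2))
  cfg <- tinyConfig(seed = 5, nSnapshots = 5L, nEpochs = 10L)
  ens <- trainSnapshots(d$x, d$y, config = cfg)
  expect_s4_class(ens, "SnapshotEnsemble")
  expect_length(snapshots(ens), 5)

  again <- trainSnapshots(d$x, d$y, config = cfg)
  expect_identical(trainHistory(again), trainHistory(ens))
  expect_identical(snapshots(again)[[5]]@weights, snapshots(ens)[[5]]@weights)

  h <- trainHistory(ens)
  expect_equal(h$lr, cosineLR(1:10, cfg@alpha0, 10, 5))
  expect_true(all(is.finite(h$trainLoss)))
})

test_that("the entropy penalty polarizes first-layer weights towards {0,1}", {
  for (seed in 1:3) {
    d <- normalizedData(tinyCohort(seed = seed))
    cfg <- TrainConfig(hiddenSizes = c(8L, 4L), nEpochs = 30L,
                       nSnapshots = 3L, batchSize = 64L, seed = 50 + seed)
    cfg0 <- cfg; cfg0@lambda <- 0
    polReg <- polarizationFraction(trainSnapshots(d$x, d$y, config = cfg))
    polFree <- polarizationFraction(trainSnapshots(d$x, d$y, config = cfg0))
    expect_gt(polReg, polFree)
  }
})

test_that("ensemble prediction is the unweighted mean of member outputs", {
  d <- normalizedData(tinyCohort(seed = 3))
  ens <- trainSnapshots(d$x, d$y, config = tinyConfig(seed = 1))
  X <- d$x[1:7, , drop = FALSE]

  # single-member ensemble equals that member's forward output
  one <- ens
  one@snapshots <- ens@snapshots[1]
  one@schedule$nSnapshots <- 1L
  expect_equal(ensemblePredict(one, X)$probability,
               forwardPass(snapshots(ens)[[1]], X))

  # identical members: mean identity
  same <- ens
  same@snapshots <- rep(ens@snapshots[2], 2)
  expect_equal(ensemblePredict(same, X)$probability,
               forwardPass(snapshots(ens)[[2]], X))

  # two members: arithmetic mean, labels at the 0.5 threshold
  pr <- ensemblePredict(ens, X)
  manual <- (forwardPass(snapshots(ens)[[1]], X) +
             forwardPass(snapshots(ens)[[2]], X)) / 2
  expect_equal(pr$probability, manual, tolerance = 1e-12)
  expect_equal(pr$label, as.integer(pr$probability >= 0.5))

  empty <- ens
  empty@snapshots <- list()
  empty@schedule$nSnapshots <- 0L
  expect_error(ensemblePredict(empty, X), "no snapshots")
})

test_that("held-out ensemble log-loss does not exceed the worst member's", {
  cohort <- tinyCohort(seed = 8, n = 400)
  d <- normalizedData(cohort)
  idx <- 1:300
  ens <- trainSnapshots(d$x[idx, ], d$y[idx],
                        config = tinyConfig(seed = 2, nEpochs = 20L,
                                            nSnapshots = 4L))
  xHold <- d$x[-idx, , drop = FALSE]
  yHold <- d$y[-idx]
  logLoss <- function(p) -mean(yHold * log(pmax(p, 1e-12)) +
                               (1 - yHold) * log(pmax(1 - p, 1e-12)))
  memberLosses <- vapply(snapshots(ens),
                         function(s) logLoss(forwardPass(s, xHold)),
                         numeric(1))
  expect_lte(logLoss(ensemblePredict(ens, xHold)$probability),
             max(memberLosses))
})
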