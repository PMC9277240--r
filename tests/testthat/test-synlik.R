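test_that("hmm and independent-MNB modes agree for single-snapshot data", {
  net <- buildAutoreg(autoregTruth)
  d <- simulateDataset(net, autoregTruth, obsTimes = 8, nCells = 25,
                       seed = 61)
  cfgH <- synlikConfig(nSim = 10000, K = 2, mode = "hmm")
  cfgI <- synlikConfig(nSim = 10000, K = 2, mode = "independent_mnb")
  llH <- as.numeric(syntheticLoglik(net, autoregTruth, d, cfgH, seed = 3))
  llI <- as.numeric(syntheticLoglik(net, autoregTruth, d, cfgI, seed = 3))
  expect_lt(abs(llH - llI), 0.5)
})

test_that("data drawn from the surrogate itself has finite likelihood", {
  net <- buildAutoreg(autoregTruth)
  d <- simulateDataset(net, autoregTruth, obsTimes = c(4, 8), nCells = 10,
                       seed = 62)
  ll <- syntheticLoglik(net, autoregTruth, d, synlikConfig(nSim = 2000),
                        seed = 4)
  hmm <- attr(ll, "surrogate")
  self <- sampleHMM(hmm, 1, seed = 5)
  expect_true(is.finite(forwardLoglik(hmm, counts(self)[1, , 1])))
  expect_true(is.finite(as.numeric(ll)))
})

test_that("synthetic likelihood is deterministic given (theta, seed)", {
  net <- buildAutoreg(autoregTruth)
  d <- simulateDataset(net, autoregTruth, obsTimes = c(4, 8), nCells = 10,
                       seed = 63)
  cfg <- synlikConfig(nSim = 1000)
  a <- as.numeric(syntheticLoglik(net, autoregTruth, d, cfg, seed = 9))
  b <- as.numeric(syntheticLoglik(net, autoregTruth, d, cfg, seed = 9))
  expect_identical(a, b)
  c2 <- as.numeric(syntheticLoglik(net, autoregTruth, d, cfg, seed = 10))
  expect_false(identical(a, c2))
})

test_that("estimator variance scales with data size and simulation budget", {
  net <- buildAutoreg(autoregTruth)
  full <- generateFixture("autoreg_negfb", seed = 64)$data
  sizes <- c(8, 16, 25)
  cfg <- synlikConfig(nSim = 1000, nRestarts = 1, maxIter = 60, tol = 1e-5)
  vres <- vapply(seq_along(sizes), function(i) {
    sub <- snapshotDataset(counts(full)[seq_len(sizes[i]), , ,
                                        drop = FALSE][, , 1],
                           times = obsTimes(full))
    syntheticLoglikVariance(net, autoregTruth, sub, cfg, nReps = 8,
                            seed = 70 + i)$variance
  }, numeric(1))
  # spread grows with the number of observed cells
  expect_gt(coef(lm(vres ~ sizes))[2], 0)

  # zero-cell data: exactly zero
  empty <- snapshotDataset(array(0L, c(0, 4, 1)), times = obsTimes(full))
  expect_identical(
    syntheticLoglikVariance(net, autoregTruth, empty, cfg, seed = 1)$variance,
    0)

  # variance decreases with nSim
  d25 <- snapshotDataset(counts(full)[, , 1], times = obsTimes(full))
  vSmall <- syntheticLoglikVariance(net, autoregTruth, d25,
                                    synlikConfig(nSim = 500, nRestarts = 1,
                                                 maxIter = 60, tol = 1e-5),
                                    nReps = 8, seed = 80)$variance
  vLarge <- syntheticLoglikVariance(net, autoregTruth, d25,
                                    synlikConfig(nSim = 5000, nRestarts = 1,
                                                 maxIter = 60, tol = 1e-5),
                                    nReps = 8, seed = 81)$variance
  expect_lt(vLarge, vSmall)
})

test_that("nSim guard enforces the identifiability floor", {
  expect_error(synlikConfig(nSim = 15, K = 2), "nSim")
})
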