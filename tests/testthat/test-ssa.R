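test_that("immigration-death SSA matches the Poisson closed form", {
  net <- buildBirthDeath()
  n <- 10000
  d <- simulateDataset(net, c(rho = 5), obsTimes = c(1, 10), nCells = n,
                       seed = 21)
  for (j in 1:2) {
    lam <- 5 * (1 - exp(-c(1, 10)[j]))
    x <- counts(d)[, j, 1]
    se <- sqrt(lam / n)
    expect_lt(abs(mean(x) - lam), 3 * se)
    # Poisson: variance equals the mean
    expect_lt(abs(var(x) - lam), 3 * lam * sqrt(2 / n))
  }
  # total-variation against Poisson at t = 10
  x <- counts(d)[, 2, 1]
  lam <- 5 * (1 - exp(-10))
  emp <- tabulate(x + 1, nbins = 40) / n
  expect_lt(0.5 * sum(abs(emp - dpois(0:39, lam))), 0.02)
})

test_that("zero propensities freeze the state", {
  net <- buildBirthDeath()
  tr <- simulateSSA(net, c(rho = 0), init = 0L, obsTimes = c(1, 5, 10),
                    seed = 2)
  expect_true(all(tr$states == 0))
  # pure death from 1: nonincreasing, survival ~ exp(-t)
  d <- simulateDataset(net, c(rho = 0), init = 1L, obsTimes = c(0.5, 1, 2),
                       nCells = 5000, seed = 3)
  x <- counts(d)[, , 1]
  expect_true(all(x %in% 0:1))
  expect_true(all(x[, 1] >= x[, 2] & x[, 2] >= x[, 3]))
  for (j in 1:3) {
    pt <- exp(-c(0.5, 1, 2)[j])
    se <- sqrt(pt * (1 - pt) / 5000)
    expect_lt(abs(mean(x[, j]) - pt), 4 * se)
  }
})

test_that("datasets are seed-deterministic and correctly shaped", {
  fx1 <- generateFixture("autoreg_negfb", seed = 7)
  fx2 <- generateFixture("autoreg_negfb", seed = 7)
  expect_identical(counts(fx1$data), counts(fx2$data))
  expect_identical(dim(counts(fx1$data)), c(25L, 4L, 1L))
  expect_identical(obsTimes(fx1$data), c(4, 8, 12, 16))
  expect_true(isCorrelated(fx1$data))

  fx3 <- generateFixture("autoreg_negfb", seed = 8)
  expect_false(identical(counts(fx1$data), counts(fx3$data)))

  tg <- generateFixture("toggle", seed = 7)
  expect_identical(dim(counts(tg$data)), c(100L, 8L, 2L))

  # n = 1 dataset equals the observed slice of a single trajectory
  net <- buildBirthDeath()
  d1 <- simulateDataset(net, c(rho = 4), obsTimes = c(1, 2), nCells = 1,
                        seed = 5)
  expect_identical(dim(counts(d1)), c(1L, 2L, 1L))
})

test_that("Extrande with constant signal reproduces plain SSA statistics", {
  params <- c(k12 = 1, k21 = 0.5, k21s = 2, k23 = 1, k32 = 0.5, k34 = 0.5,
              k43 = 0.5, rho1 = 0.1, rho2 = 2, rho3 = 8, rho4 = 20,
              delta_m = 1)
  net <- buildMapk(params)
  # constant signal 0.5 <=> plain SSA with k21s pre-multiplied by 0.5
  csig <- signal(c(0, 10), c(0.5, 0.5), upperBound = 0.5)
  params2 <- params; params2["k21s"] <- params["k21s"] * 0.5
  net2 <- buildMapk(params2)
  net2@modulated[] <- FALSE
  n <- 10000
  dE <- simulateDataset(net, params, obsTimes = c(2, 4), nCells = n,
                        seed = 31, sig = csig)
  dS <- simulateDataset(net2, params2, obsTimes = c(2, 4), nCells = n,
                        seed = 32)
  for (j in 1:2) {
    xe <- counts(dE)[, j, 1]; xs <- counts(dS)[, j, 1]
    z <- (mean(xe) - mean(xs)) /
      sqrt(var(xe) / n + var(xs) / n)
    expect_lt(abs(z), 4)
    zv <- (var(xe) - var(xs)) / sqrt(2 * var(xe)^2 / n + 2 * var(xs)^2 / n)
    expect_lt(abs(zv), 4)
  }
})

test_that("signal contract violations and runaway propensities error", {
  net <- buildBirthDeath()
  expect_error(simulateDataset(net, c(rho = 1e30), obsTimes = 1, nCells = 1,
                               seed = 1), "overflow")
  params <- c(k12 = 1, k21 = 0.5, k21s = 2, k23 = 1, k32 = 0.5, k34 = 0.5,
              k43 = 0.5, rho1 = 0.1, rho2 = 2, rho3 = 8, rho4 = 20,
              delta_m = 1)
  mnet <- buildMapk(params)
  expect_error(simulateSSA(mnet, params, obsTimes = 1, seed = 1),
               "simulateExtrande")
  expect_error(signal(c(0, 1), c(0, 2), upperBound = 1), "upperBound")
})
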