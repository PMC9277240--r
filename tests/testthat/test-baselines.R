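test_that("GSL per-time likelihood equals the closed-form Gaussian fit", {
  net <- buildBirthDeath()
  th <- c(rho = 40)
  d <- simulateDataset(net, th, obsTimes = 3, nCells = 15, seed = 91)
  cfg <- gslConfig(nSim = 2000, mode = "per_time", shrinkage = 0)
  ll <- gslLoglik(net, th, d, cfg, seed = 13)
  # recompute from the same simulation stream (child seed 1 of 13)
  sims <- simulateDataset(net, th, obsTimes = 3, nCells = 2000,
                          seed = nbsynlik:::.childSeed(13, 1))
  y <- counts(sims)[, 1, 1]
  mu <- mean(y); s2 <- mean((y - mu)^2)
  expect_equal(ll, sum(dnorm(counts(d)[, 1, 1], mu, sqrt(s2), log = TRUE)),
               tolerance = 1e-9)
})

test_that("GSL is near-exact for approximately Gaussian data", {
  # immigration-death at large rho: Poisson(40), close to Gaussian
  net <- buildBirthDeath()
  th <- c(rho = 40)
  d <- simulateDataset(net, th, obsTimes = c(2, 4), nCells = 50, seed = 92)
  ll <- gslLoglik(net, th, d, gslConfig(nSim = 20000, mode = "joint"),
                  seed = 14)
  lam <- 40 * (1 - exp(-c(2, 4)))
  ref <- sum(vapply(1:2, function(j)
    sum(dnorm(counts(d)[, j, 1], lam[j], sqrt(lam[j]), log = TRUE)),
    numeric(1)))
  # joint Gaussian with near-diagonal structure approximates the Poisson ref
  expect_lt(abs(ll - ref) / abs(ref), 0.05)
})

test_that("LMA linearization: identity at sigma_b = 0, accuracy at truth", {
  # no active binding: unchanged, zero iterations
  th0 <- autoregTruth; th0["sigma_b"] <- 0
  net0 <- buildAutoreg(th0)
  lin0 <- lmaLinearize(net0, th0)
  expect_identical(lin0$iterations, 0L)
  expect_identical(lin0$net@orders, net0@orders)

  # constitutive limit: stationary mean is rho_u * b exactly
  ms0 <- momentEquations(lin0$net, th0, order = 2)
  st0 <- stationaryMoments(ms0, net0@init)
  expect_equal(st0[["0.0.1"]], th0[["rho_u"]] * th0[["b"]],
               tolerance = 1e-5)

  # with feedback: LMA mean within 5% of the SSA stationary mean
  net <- buildAutoreg(autoregTruth)
  lin <- lmaLinearize(net, autoregTruth)
  expect_gt(lin$iterations, 0)
  st <- stationaryMoments(momentEquations(lin$net, autoregTruth, 2),
                          net@init)
  d <- simulateDataset(net, autoregTruth, obsTimes = 30, nCells = 10000,
                       seed = 93)
  ssaMean <- mean(counts(d))
  expect_lt(abs(st[["0.0.1"]] - ssaMean) / ssaMean, 0.05)
})

test_that("moment equations reproduce closed forms", {
  net <- buildBirthDeath()
  ms <- momentEquations(net, c(rho = 5), order = 4)
  # d<x>/dt = rho - <x>
  expect_equal(ms$A0["1", "0"], 5)
  expect_equal(ms$A0["1", "1"], -1)
  # stationary raw moments are Poisson (Touchard polynomials)
  lam <- 5
  st <- stationaryMoments(ms, 0L)
  expect_equal(st[["1"]], lam, tolerance = 1e-6)
  expect_equal(st[["2"]], lam + lam^2, tolerance = 1e-6)
  expect_equal(st[["3"]], lam + 3 * lam^2 + lam^3, tolerance = 1e-6)
  expect_equal(st[["4"]], lam + 7 * lam^2 + 6 * lam^3 + lam^4,
               tolerance = 1e-6)
  # zero production from an empty state: all moments stay zero
  msz <- momentEquations(net, c(rho = 0), order = 2)
  mm <- solveMoments(msz, 0L, c(1, 5))
  expect_true(all(mm[, -1] == 0))
  # non-affine propensity is a contract error
  anet <- buildAutoreg(autoregTruth)
  expect_error(momentEquations(anet, autoregTruth), "affine")
})

test_that("MBI likelihood structure and CLT concentration", {
  net <- buildBirthDeath()
  th <- c(rho = 6)
  # S = 1: Gaussian dimension 2 per time (mean + second moment)
  keys <- nbsynlik:::.obsMomentKeys(1, 1L, 1)
  expect_length(keys, 2)
  # log-lik at the true parameters grows with n (CLT concentration)
  ll <- vapply(c(50, 200, 800), function(n) {
    d <- simulateDataset(net, th, obsTimes = c(1, 2), nCells = n,
                         seed = 94 + n)
    mbiLoglik(net, th, d)
  }, numeric(1))
  expect_true(all(diff(ll) > 0))
  # autoreg (nonlinear): LMA route produces a finite likelihood
  anet <- buildAutoreg(autoregTruth)
  fx <- generateFixture("autoreg_negfb", seed = 95)
  expect_true(is.finite(mbiLoglik(anet, autoregTruth, fx$data)))
})

test_that("summary moments and ABC discrepancy follow their definitions", {
  cst <- snapshotDataset(matrix(3L, 4, 2), times = c(1, 2))
  s <- summaryMoments(cst)
  expect_equal(unname(s), c(3, 9, 3, 9)) # m2 = m1^2 for constant data
  # 2-cell hand computation, two species
  arr <- array(c(1L, 3L, 2L, 4L), c(2, 1, 2))
  d2 <- snapshotDataset(arr, times = 5, speciesNames = c("A", "B"))
  s2 <- summaryMoments(d2)
  expect_equal(unname(s2), c(2, 3, 5, 7, 10))
  expect_identical(names(s2),
                   c("t5.m1.1", "t5.m1.2", "t5.m2.11", "t5.m2.12",
                     "t5.m2.22"))

  expect_equal(abcDiscrepancy(c(1, 2), c(1, 2)), 0)
  expect_equal(abcDiscrepancy(c(2, 1, 1), c(1, 1, 1)), 1)
  expect_equal(abcDiscrepancy(c(0.5, 0), c(0, 0)), 0.25) # absolute fallback
})

test_that("sequential ABC shrinks the posterior and covers the truth", {
  net <- buildBirthDeath()
  truth <- c(rho = 5)
  data <- simulateDataset(net, truth, obsTimes = c(1, 2), nCells = 50,
                          seed = 96)
  prior <- priorBox(c(rho = 0), c(rho = 15))
  rounds <- abcSMC(net, prior, data, abcConfig(nRounds = 4, nAccept = 80),
                   seed = 97)
  sds <- vapply(rounds, function(r) sd(r$theta), numeric(1))
  expect_true(all(diff(sds) < 0))
  eps <- vapply(rounds, `[[`, numeric(1), "epsilon")
  expect_true(all(diff(eps[-1]) < 0))
  final <- rounds[[4]]$theta
  expect_gt(quantile(final, 0.95), 5)
  expect_lt(quantile(final, 0.05), 5)
  # epsilon = Inf: round 1 is prior draws
  expect_identical(rounds[[1]]$epsilon, Inf)
  expect_identical(rounds[[1]]$nTried, nrow(rounds[[1]]$theta))
  # seeded rerun reproduces acceptances
  rounds2 <- abcSMC(net, prior, data, abcConfig(nRounds = 2, nAccept = 40),
                    seed = 98)
  rounds3 <- abcSMC(net, prior, data, abcConfig(nRounds = 2, nAccept = 40),
                    seed = 98)
  expect_identical(rounds2[[2]]$theta, rounds3[[2]]$theta)
})
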