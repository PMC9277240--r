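test_that("MH sampler behaves on degenerate and known targets", {
  prior <- priorBox(c(a = -5, b = -5), c(a = 5, b = 5))
  target <- function(th) sum(dnorm(th, 0, 1, log = TRUE))
  # vanishing proposals: acceptance rate -> 1, chain nearly constant
  ch0 <- mhSample(target, prior, c(a = 0.3, b = -0.2), 500,
                  proposalSd = 1e-9, seed = 2)
  expect_gt(acceptanceRate(ch0), 0.99)
  expect_lt(max(apply(draws(ch0), 2, sd)), 1e-6)
  # draws stay inside the box
  ch <- mhSample(target, prior, c(a = 4.9, b = -4.9), 4000,
                 proposalSd = c(1, 1), seed = 3)
  expect_true(all(draws(ch) >= -5 & draws(ch) <= 5))
  expect_error(mhSample(target, prior, c(a = 9, b = 0), 10, seed = 1),
               "outside")
})

test_that("pseudo-marginal chain with an unbiased estimator matches the exact chain", {
  # Poisson-likelihood toy: x ~ Poisson(lambda), one observation battery
  xobs <- c(4, 6, 5, 3, 7)
  prior <- priorBox(c(lambda = 0.1), c(lambda = 20))
  exact <- function(th) sum(dpois(xobs, th, log = TRUE))
  # unbiased likelihood estimator: multiply by a mean-1 lognormal weight
  counterEnv <- new.env(); counterEnv$i <- 0
  noisy <- function(th) {
    counterEnv$i <- counterEnv$i + 1
    w <- nbsynlik:::.withSeed(1000 + counterEnv$i,
                              rnorm(1, -0.125, 0.5)) # log of mean-1 LN
    exact(th) + w
  }
  chE <- mhSample(exact, prior, c(lambda = 5), 20000, proposalSd = 1,
                  seed = 4)
  chN <- mhSample(noisy, prior, c(lambda = 5), 20000, proposalSd = 1,
                  seed = 5)
  mE <- mean(draws(chE)[-(1:2000), 1])
  mN <- mean(draws(chN)[-(1:2000), 1])
  expect_lt(abs(mE - mN), 0.25)
})

test_that("MLE recovers known optima", {
  prior <- priorBox(c(a = -4, b = -4), c(a = 4, b = 4))
  quad <- function(th) -sum((th - c(1.5, -0.5))^2)
  fit <- mleFit(quad, prior, nStarts = 4, budget = 500, seed = 6)
  expect_lt(max(abs(fit$theta - c(1.5, -0.5))), 1e-3)

  # immigration-death with FSP likelihood: rho within 10%
  net <- buildBirthDeath()
  d <- simulateDataset(net, c(rho = 5), obsTimes = c(1, 2), nCells = 100,
                       seed = 7)
  fn <- makeLoglikFn(net, d, "fsp")
  fitR <- mleFit(fn, priorBox(c(rho = 0.5), c(rho = 15)), nStarts = 2,
                 budget = 60, seed = 8)
  expect_lt(abs(fitR$theta - 5) / 5, 0.10)
  expect_error(mleFit(function(th) -Inf, prior, nStarts = 2, seed = 1),
               "invalid")
})

test_that("posterior predictive pools cells and widens under parameter spread", {
  net <- buildBirthDeath()
  pp1 <- posteriorPredictive(net, c(rho = 5), obsTimes = c(1, 2),
                             nCellsPerTheta = 30, seed = 9)
  expect_identical(dim(counts(pp1)), c(30L, 2L, 1L))
  thetas <- cbind(rho = c(1, 15))
  pp2 <- posteriorPredictive(net, thetas, obsTimes = c(1, 2),
                             nCellsPerTheta = 200, seed = 10)
  expect_identical(dim(counts(pp2)), c(400L, 2L, 1L))
  pp3 <- posteriorPredictive(net, cbind(rho = c(8, 8)), obsTimes = c(1, 2),
                             nCellsPerTheta = 200, seed = 10)
  expect_gt(var(counts(pp2)[, 2, 1]), var(counts(pp3)[, 2, 1]))
})

test_that("credible intervals and convergence diagnostics are correct", {
  draws <- matrix(c(sort(runif(1000)), rnorm(1000)), 1000, 2,
                  dimnames = list(NULL, c("u", "z")))
  ch <- new("Chain", draws = draws, logliks = numeric(1000),
            accepted = rep(TRUE, 1000), seed = 1, method = "test")
  ci <- credibleInterval(ch, "u", level = 1, burnin = 0)
  expect_equal(unname(ci), range(draws[, "u"]))
  ci9 <- credibleInterval(ch, "u", level = 0.9, burnin = 0)
  expect_equal(unname(ci9), unname(quantile(draws[, "u"], c(0.05, 0.95))))
  expect_error(credibleInterval(ch, "u", burnin = 1), "burn-in")

  prior <- priorBox(c(z = -8), c(z = 8))
  chains <- lapply(1:3, function(s)
    mhSample(function(th) dnorm(th, 0, 1, log = TRUE), prior, c(z = 0),
             3000, proposalSd = 1.5, seed = s))
  rh <- gelmanRubin(chains)
  expect_lt(rh[["z"]], 1.1)
})
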