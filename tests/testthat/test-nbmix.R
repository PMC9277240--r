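test_that("NB log-pmf special cases: geometric, normalization, Poisson limit", {
  x <- 0:20
  expect_equal(nbLogpmf(x, 1, 0.3), log(0.3) + x * log(0.7))
  expect_lt(abs(sum(exp(nbLogpmf(0:1e6, 2.5, 0.3))) - 1), 1e-10)
  mu <- 5; r <- 1e6
  expect_lt(max(abs(exp(nbLogpmf(0:30, r, r / (r + mu))) - dpois(0:30, mu))),
            1e-4)
  expect_error(nbLogpmf(3, -1, 0.5), "r must")
  expect_error(nbLogpmf(3, 1, 1), "r must")
  expect_error(nbLogpmf(2.5, 1, 0.5), "integers")
})

test_that("mixture log-pmf reduces correctly and matches direct summation", {
  m1 <- nbMixture(1, r = 3, means = 10)
  x <- 0:30
  expect_equal(mnbLogpmf(x, m1), nbLogpmf(x, 3, 3 / 13))
  set.seed(2)
  m3 <- nbMixture(c(0.2, 0.5, 0.3), r = c(1, 4, 9), means = c(2, 15, 60))
  direct <- log(0.2 * dnbinom(x, 1, mu = 2) + 0.5 * dnbinom(x, 4, mu = 15) +
                  0.3 * dnbinom(x, 9, mu = 60))
  expect_equal(mnbLogpmf(x, m3), direct, tolerance = 1e-12)
  # equal components: weights are irrelevant
  meq <- nbMixture(c(0.9, 0.1), r = c(3, 3), means = c(10, 10))
  expect_equal(mnbLogpmf(x, meq), nbLogpmf(x, 3, 3 / 13), tolerance = 1e-12)
})

test_that("mixture sampling is reproducible with correct moments", {
  mix <- nbMixture(c(0.4, 0.6), r = c(2, 6), means = c(3, 30))
  n <- 1e5
  x <- sampleMNB(mix, n, seed = 5)
  expect_identical(x, sampleMNB(mix, n, seed = 5))
  m <- sum(mixtureWeights(mix) * nbMeans(mix))
  v <- sum(mixtureWeights(mix) * (nbMeans(mix)^2 + nbMeans(mix) *
                                    fanoFactors(mix))) - m^2
  expect_lt(abs(mean(x) - m), 3 * sqrt(v / n))
  expect_length(sampleMNB(mix, 0, seed = 1), 0)
  # K = 1, r = 1 is geometric
  g <- sampleMNB(nbMixture(1, r = 1, p = 0.25), 1e5, seed = 6)
  expect_lt(abs(mean(g) - 3), 3 * sqrt(12 / 1e5))
})

test_that("EM recovers NB parameters and mixture weights", {
  set.seed(11)
  x <- rnbinom(1e4, size = 5, mu = 20)
  fit <- fitMNBEM(x, K = 1, seed = 1)
  expect_lt(abs(nbMeans(fit$mixture) - 20) / 20, 0.02)
  expect_lt(abs(fit$mixture@r - 5) / 5, 0.15)
  expect_monotone_trace(fit$trace)

  x2 <- c(rnbinom(5000, size = 4, mu = 2), rnbinom(5000, size = 6, mu = 80))
  fit2 <- fitMNBEM(x2, K = 2, seed = 1)
  w <- sort(mixtureWeights(fit2$mixture))
  expect_lt(max(abs(w - 0.5)), 0.05)
  expect_equal(sort(nbMeans(fit2$mixture)), c(2, 80), tolerance = 0.15)
})

test_that("EM handles degenerate inputs and rejects invalid samples", {
  expect_error(fitMNBEM(numeric(0), K = 1), "nonempty")
  expect_error(fitMNBEM(c(1, 2.5, 3), K = 1), "integers")
  # all-equal samples with K > 1: degenerate-safe (components merge)
  fit <- fitMNBEM(rep(7L, 200), K = 2, seed = 1)
  expect_s4_class(fit$mixture, "NBMixture")
  expect_equal(sum(mixtureWeights(fit$mixture)), 1, tolerance = 1e-12)
  expect_equal(unique(round(nbMeans(fit$mixture), 6)), 7)
})

test_that("fitted K-mixture log-likelihood is nested in K", {
  set.seed(3)
  x <- c(rnbinom(2000, 3, mu = 4), rnbinom(2000, 8, mu = 40))
  ll <- vapply(1:3, function(K)
    max(fitMNBEM(x, K = K, nRestarts = 2, seed = 4)$trace), numeric(1))
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-3])))
})

test_that("mixtures serialize to JSON and back", {
  mix <- nbMixture(c(0.3, 0.7), r = c(2, 5), means = c(4, 25))
  path <- tempfile(fileext = ".json")
  writeMixtureJSON(mix, path)
  back <- readMixtureJSON(path)
  expect_equal(mixtureWeights(back), mixtureWeights(mix))
  expect_equal(nbMeans(back), nbMeans(mix), tolerance = 1e-12)
  expect_equal(back@r, mix@r, tolerance = 1e-12)
})
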