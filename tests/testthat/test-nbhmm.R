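test_that("forward algorithm reduces to NB sums (K=1) and mixtures (T=1)", {
  r <- array(c(3, 5, 2), c(3, 1, 1))
  p <- r / (r + c(10, 20, 5))
  h1 <- nbhmm(pi = 1, trans = matrix(1, 1, 1), r = r, p = p)
  x <- c(8L, 25L, 3L)
  expect_equal(forwardLoglik(h1, x),
               sum(dnbinom(x, size = r[, 1, 1], prob = p[, 1, 1],
                           log = TRUE)), tolerance = 1e-12)
  hT1 <- randomHMM(3, 1, seed = 8)
  mix <- new("NBMixture", weights = hT1@pi, r = hT1@r[1, , 1],
             p = hT1@p[1, , 1])
  expect_equal(forwardLoglik(hT1, 12L), mnbLogpmf(12L, mix),
               tolerance = 1e-12)
})

test_that("forward algorithm equals exhaustive path enumeration", {
  for (seed in 1:4) {
    K <- sample(2:3, 1)
    hmm <- randomHMM(K, 4, seed = seed)
    x <- counts(sampleHMM(hmm, 1, seed = seed + 50))[1, , 1]
    expect_lt(abs(forwardLoglik(hmm, x) - bruteForwardLoglik(hmm, x)), 1e-10)
  }
  # two observed species, conditionally independent emissions
  hmm2 <- randomHMM(2, 3, S = 2, seed = 9)
  x2 <- matrix(c(4L, 10L, 2L, 7L, 30L, 1L), 3, 2)
  expect_lt(abs(forwardLoglik(hmm2, x2) - bruteForwardLoglik(hmm2, x2)),
            1e-10)
})

test_that("Baum-Welch recovers a well-separated two-state HMM", {
  truth <- nbhmm(pi = c(0.7, 0.3),
                 trans = matrix(c(0.85, 0.15, 0.25, 0.75), 2, byrow = TRUE),
                 r = array(rep(c(4, 9), each = 5), c(5, 2, 1)),
                 p = array(c(rep(4 / (4 + 3), 5), rep(9 / (9 + 70), 5)),
                           c(5, 2, 1)))
  d <- sampleHMM(truth, 500, seed = 13)
  fit <- fitBaumWelch(d, K = 2, seed = 1)
  expect_monotone_trace(fit$trace, tol = 1e-8)
  mu <- nbMeans(fit$hmm)[, , 1]
  ord <- order(mu[1, ])
  expect_lt(max(abs(mu[, ord] - rep(c(3, 70), each = 5)) /
                  rep(c(3, 70), each = 5)), 0.10)
  for (t in 1:4) {
    tr <- fit$hmm@trans[t, ord, ord]
    expect_lt(max(abs(tr - matrix(c(0.85, 0.15, 0.25, 0.75), 2,
                                  byrow = TRUE))), 0.1)
  }
  expect_lt(max(abs(fit$hmm@pi[ord] - c(0.7, 0.3))), 0.1)
})

test_that("K = 1 Baum-Welch reduces to independent per-time NB fits", {
  set.seed(5)
  arr <- array(rnbinom(400 * 3, size = 4, mu = c(5, 15, 40)[rep(1:3,
                                                                each = 400)]),
               c(400, 3, 1))
  fit <- fitBaumWelch(arr, K = 1, nRestarts = 1, tol = 1e-10,
                      maxIter = 500)
  for (t in 1:3) {
    mfit <- fitMNBEM(arr[, t, 1], K = 1, nRestarts = 1)
    expect_equal(nbMeans(fit$hmm)[t, 1, 1], nbMeans(mfit$mixture),
                 tolerance = 1e-4)
    expect_equal(fit$hmm@r[t, 1, 1], mfit$mixture@r, tolerance = 1e-3)
  }
})

test_that("HMM init from per-time mixtures is mean-matched and improvable", {
  mA <- nbMixture(c(0.6, 0.4), r = c(3, 6), means = c(4, 30))
  mB <- nbMixture(c(0.5, 0.5), r = c(6, 3), means = c(35, 5)) # swapped order
  h <- initHMMFromMNB(list(mA, mB))
  expect_equal(nbMeans(h)[2, , 1], c(5, 35)) # matched by sorted mean
  expect_equal(h@pi, c(0.6, 0.4))
  expect_equal(h@trans[1, 1, ], c(0.9, 0.1))
  # permutation invariance of input component order
  mBperm <- nbMixture(c(0.5, 0.5), r = c(3, 6), means = c(5, 35))
  h2 <- initHMMFromMNB(list(mA, mBperm))
  expect_equal(nbMeans(h2), nbMeans(h))

  # EM improves on its own start
  d <- sampleHMM(randomHMM(2, 2, seed = 3), 300, seed = 4)
  perTime <- lapply(1:2, function(t)
    fitMNBEM(counts(d)[, t, 1], K = 2, seed = t)$mixture)
  h0 <- initHMMFromMNB(perTime)
  ll0 <- sum(forwardLoglik(h0, d))
  fit <- fitBaumWelch(d, K = 2, seed = 2)
  expect_gte(max(fit$trace) + 1e-6, ll0)
})

test_that("ancestral sampling matches the transition law and marginals", {
  # tight emissions (r = 50) so states are classifiable by thresholding
  hmm <- nbhmm(pi = c(0.5, 0.5),
               trans = matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE),
               r = array(rep(c(50, 50), each = 2), c(2, 2, 1)),
               p = array(c(rep(50 / 51, 2), rep(50 / 130, 2)), c(2, 2, 1)))
  n <- 50000
  d <- sampleHMM(hmm, n, seed = 17)
  expect_identical(dim(counts(d)), c(50000L, 2L, 1L))
  # classify states by threshold (means 1 vs 80, well separated)
  z <- counts(d)[, , 1] > 30
  p11 <- mean(!z[, 2][!z[, 1]])
  p22 <- mean(z[, 2][z[, 1]])
  expect_lt(abs(p11 - 0.7), 0.02)
  expect_lt(abs(p22 - 0.8), 0.02)

  # marginal mixture at t = 2 matches Monte-Carlo marginals
  mix2 <- hmmMarginal(hmm, 2)
  expect_equal(mixtureWeights(mix2), c(0.5 * 0.7 + 0.5 * 0.2,
                                       0.5 * 0.3 + 0.5 * 0.8))
  emp <- tabulate(counts(d)[, 2, 1] + 1, nbins = 400) / n
  pmf <- exp(mnbLogpmf(0:399, mix2))
  expect_lt(0.5 * sum(abs(emp - pmf)), 0.02)
})

test_that("HMMs serialize to JSON and back", {
  hmm <- randomHMM(2, 3, seed = 21)
  path <- tempfile(fileext = ".json")
  writeHMMJSON(hmm, path)
  back <- readHMMJSON(path)
  expect_equal(back@pi, hmm@pi)
  expect_equal(back@trans, hmm@trans)
  expect_equal(back@r, hmm@r)
  expect_equal(back@p, hmm@p)
  x <- c(3L, 8L, 1L)
  expect_equal(forwardLoglik(back, x), forwardLoglik(hmm, x))
})
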