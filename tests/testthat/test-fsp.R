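test_that("immigration-death generator has the expected sparse structure", {
  net <- buildBirthDeath()
  tr <- fspTruncation(net, 10)
  A <- fspGenerator(net, c(rho = 3), tr)
  expect_identical(dim(A), c(11L, 11L))
  # tridiagonal: births on the subdiagonal, deaths on the superdiagonal
  expect_equal(A[2, 1], 3)
  expect_equal(A[5, 6], 5)
  expect_equal(A[3, 5], 0)
  cs <- Matrix::colSums(A)
  expect_equal(cs[1:10], rep(0, 10), tolerance = 1e-12)
  expect_lt(cs[11], 0) # boundary leaks the birth out of the truncation
})

test_that("burst generator matches the geometric jump law and b -> 0 limit", {
  net <- buildBirthDeath(bursty = TRUE)
  tr <- fspTruncation(net, 30)
  A <- fspGenerator(net, c(rho = 2, b = 1.5), tr)
  pk <- function(k) 1.5^k / 2.5^(k + 1)
  expect_equal(A[4, 1], 2 * pk(3), tolerance = 1e-12)
  expect_equal(A[1, 1], -2 * (1 - pk(0)), tolerance = 1e-12)
  # b -> 0: bursts concentrate at k = 0, production becomes a no-op
  A0 <- fspGenerator(net, c(rho = 2, b = 0), tr)
  expect_equal(A0[1, 1], 0)
  expect_equal(sum(abs(A0[, 1])), 0)
})

test_that("matrix-exponential propagation matches a truncated series oracle", {
  set.seed(4)
  Q <- matrix(rgamma(9, 1), 3); diag(Q) <- 0; diag(Q) <- -colSums(Q)
  p0 <- c(1, 0, 0); t <- 0.01
  series <- p0
  term <- p0
  for (k in 1:8) { term <- (Q %*% term) * t / k; series <- series + term }
  pe <- as.numeric(Matrix::expm(Matrix::Matrix(Q * t, sparse = TRUE)) %*% p0)
  expect_lt(max(abs(pe - series)), 1e-10)
})

test_that("FSP recovers the Poisson law of the immigration-death process", {
  net <- buildBirthDeath()
  tr <- fspTruncation(net, 60)
  p0 <- numeric(61); p0[1] <- 1
  p <- fspPropagate(net, c(rho = 5), tr, p0, 0, 10)
  lam <- 5 * (1 - exp(-10))
  expect_lt(0.5 * sum(abs(p - dpois(0:60, lam))), 1e-6)
  # t1 = t0 leaves the vector untouched
  p2 <- fspPropagate(net, c(rho = 5), tr, p0, 2, 2)
  expect_equal(as.numeric(p2), p0)
})

test_that("marginals sum over latent dimensions and preserve mass", {
  net <- buildAutoreg(autoregTruth)
  tr <- fspTruncation(net, c(1, 1, 40))
  sol <- fspSolve(net, autoregTruth, times = c(4, 8), trunc = tr)
  p <- sol@probs[, 2]
  marg <- fspMarginal(p, tr, "P")
  expect_equal(sum(marg), sum(p), tolerance = 1e-12)
  # direct enumeration oracle
  direct <- vapply(0:40, function(k)
    sum(p[tr@states[, 3] == k]), numeric(1))
  expect_equal(as.numeric(marg), direct)
  expect_true(all(diff(massDefect(sol)) >= -1e-12))
})

test_that("filtering log-likelihood matches hand-computable reductions", {
  net <- buildBirthDeath()
  th <- c(rho = 4)
  tr <- fspTruncation(net, 50)
  # T = 1 reduces to the log marginal pmf
  ll <- fspFilterLoglik(net, th, tr, times = 2, obs = 3)
  expect_equal(ll, dpois(3, 4 * (1 - exp(-2)), log = TRUE), tolerance = 1e-8)
  # fully observed chain: product of transition-operator entries
  A <- fspGenerator(net, th, tr)
  P1 <- as.matrix(Matrix::expm(A * 1.5))
  P2 <- as.matrix(Matrix::expm(A * 1.0))
  ll2 <- fspFilterLoglik(net, th, tr, times = c(1.5, 2.5), obs = c(2, 5))
  expect_equal(ll2, log(P1[3, 1]) + log(P2[6, 3]), tolerance = 1e-10)
  # zero-support observation
  llz <- suppressWarnings(fspFilterLoglik(net, th, tr, times = 1,
                                          obs = 50 + 5))
  expect_identical(llz, -Inf)
})

test_that("dataset likelihood is additive and mode-consistent at T = 1", {
  net <- buildBirthDeath()
  th <- c(rho = 4)
  d <- simulateDataset(net, th, obsTimes = c(1, 3), nCells = 6, seed = 9)
  tr <- fspTruncation(net, 60)
  tot <- fspDatasetLoglik(net, th, d, trunc = tr)
  percell <- vapply(1:6, function(i)
    fspFilterLoglik(net, th, tr, d@times, counts(d)[i, , 1]), numeric(1))
  expect_equal(tot, sum(percell), tolerance = 1e-10)

  d1c <- snapshotDataset(counts(d)[, 1, , drop = FALSE], times = 1,
                         correlated = TRUE)
  d1u <- snapshotDataset(counts(d)[, 1, , drop = FALSE], times = 1,
                         correlated = FALSE)
  expect_equal(fspDatasetLoglik(net, th, d1c, trunc = tr),
               fspDatasetLoglik(net, th, d1u, trunc = tr), tolerance = 1e-10)
})

test_that("time-varying FSP agrees with Extrande sampling", {
  fm <- generateFixture("mapk_snapshots", seed = 3)
  net <- fm$network; th <- fm$truth$params
  tr <- fspAutoTruncate(net, th, 2, sig = fm$signal)
  p <- fspPropagate(net, th, tr, local({
    p0 <- numeric(nrow(tr@states))
    p0[which(tr@states[, 1] == 1 & tr@states[, 5] == 0)] <- 1
    p0
  }), 0, 2, sig = fm$signal)
  marg <- fspMarginal(p, tr, "M")
  n <- 10000
  d <- simulateDataset(net, th, obsTimes = 2, nCells = n, seed = 44,
                       sig = fm$signal)
  emp <- tabulate(counts(d)[, 1, 1] + 1, nbins = length(marg)) / n
  expect_lt(0.5 * sum(abs(emp - marg)), 0.02)
})

test_that("auto-truncation reaches the target mass defect", {
  net <- buildBirthDeath(bursty = TRUE)
  tr <- fspAutoTruncate(net, c(rho = 5, b = 2), times = 20,
                        defectTol = 1e-8)
  p <- fspPropagate(net, c(rho = 5, b = 2), tr,
                    local({ p0 <- numeric(nrow(tr@states)); p0[1] <- 1; p0 }),
                    0, 20)
  expect_lt(attr(p, "massDefect"), 1e-8)
  expect_equal(sum((0:tr@bounds[1]) * p), 10, tolerance = 1e-6)
})
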