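# shared fixtures and independent oracles used across test files

autoregTruth <- c(rho_u = 5, rho_b = 0, sigma_b = 0.05, sigma_u = 1, b = 2)

# exhaustive hidden-path enumeration: independent oracle for the forward
# algorithm (sums over all K^T paths)
bruteForwardLoglik <- function(hmm, x) {
  x <- matrix(x, ncol = dim(hmm@r)[3])
  K <- length(hmm@pi); T <- nrow(x); S <- ncol(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lps <- apply(paths, 1, function(z) {
    lp <- log(hmm@pi[z[1]])
    if (T > 1) for (t in 2:T) lp <- lp + log(hmm@trans[t - 1, z[t - 1], z[t]])
    for (t in seq_len(T)) for (s in seq_len(S))
      lp <- lp + dnbinom(x[t, s], size = hmm@r[t, z[t], s],
                         prob = hmm@p[t, z[t], s], log = TRUE)
    lp
  })
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

# random NB-HMM with well-defined parameters
randomHMM <- function(K, T, S = 1, seed = 1) {
  set.seed(seed)
  pi <- rgamma(K, 1) + 0.1; pi <- pi / sum(pi)
  trans <- array(0, c(max(T - 1, 0), K, K))
  if (T > 1) for (t in seq_len(T - 1)) {
    m <- matrix(rgamma(K * K, 1) + 0.1, K)
    trans[t, , ] <- m / rowSums(m)
  }
  r <- array(runif(T * K * S, 0.5, 8), c(T, K, S))
  mu <- array(runif(T * K * S, 1, 40), c(T, K, S))
  nbhmm(pi = pi, trans = if (T > 1) trans else NULL, r = r, p = r / (r + mu))
}

# EM trace monotonicity up to numerical tolerance
expect_monotone_trace <- function(trace, tol = 1e-8) {
  if (length(trace) > 1) {
    ok <- diff(trace) >= -tol * (abs(trace[-length(trace)]) + 1)
    expect_true(all(ok), label = paste("monotone trace,", sum(!ok), "drops"))
  } else expect_true(length(trace) >= 1)
}
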