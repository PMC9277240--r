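## Metropolis-Hastings posterior sampling with (possibly stochastic)
## likelihood estimates, multi-start maximum-likelihood estimation, and
## posterior-predictive simulation.

#' Random-walk Metropolis-Hastings under a box prior
#'
#' Independent Gaussian steps per parameter; proposals outside the box are
#' rejected (zero prior density). When the likelihood function is a
#' stochastic estimator (synthetic models, GSL), the current state's
#' estimate is stored and reused (pseudo-marginal style) unless
#' \code{refreshCurrent = TRUE}, which re-estimates it each iteration.
#'
#' @param loglikFn function(theta) returning a log-likelihood (estimate);
#'   may be stochastic
#' @param prior a \linkS4class{PriorBox}
#' @param theta0 initial parameters (inside the box)
#' @param nIter number of iterations
#' @param proposalSd per-parameter proposal standard deviations; default
#'   2 percent of each prior range
#' @param seed RNG seed for the proposal/acceptance stream
#' @param refreshCurrent re-evaluate the current state's likelihood at
#'   every iteration
#' @param method tag stored on the chain
#' @return a \linkS4class{Chain}
#' @export
mhSample <- function(loglikFn, prior, theta0, nIter,
                     proposalSd = 0.02 * (prior@upper - prior@lower),
                     seed = 1L, refreshCurrent = FALSE, method = "custom") {
  pnames <- names(prior@lower)
  theta0 <- theta0[pnames]
  if (!inPrior(prior, theta0)) stop("theta0 outside the prior box")
  P <- length(pnames)
  proposalSd <- rep_len(proposalSd, P)
  draws <- matrix(0, nIter, P, dimnames = list(NULL, pnames))
  lls <- numeric(nIter)
  acc <- logical(nIter)
  cur <- theta0
  llCur <- loglikFn(cur)
  if (!is.finite(llCur))
    stop("log-likelihood not finite at theta0", call. = FALSE)
  .withSeed(seed, {
    for (i in seq_len(nIter)) {
      step <- rnorm(P, 0, proposalSd)
      u <- runif(1)
      prop <- cur + step
      if (inPrior(prior, setNames(prop, pnames))) {
        if (refreshCurrent) llCur <- loglikFn(cur)
        llProp <- loglikFn(prop)
        if (is.finite(llProp) && log(u) < llProp - llCur) {
          cur <- prop
          llCur <- llProp
          acc[i] <- TRUE
        }
      }
      draws[i, ] <- cur
      lls[i] <- llCur
    }
  })
  new("Chain", draws = draws, logliks = lls, accepted = acc,
      seed = as.numeric(seed), method = method)
}

#' Multi-start maximum-likelihood estimation on a box
#'
#' Derivative-free Nelder-Mead search in logit-transformed box coordinates
#' from several prior-drawn starting points. For stochastic objectives use
#' a common-random-number likelihood (see \code{\link{makeLoglikFn}} with
#' \code{crn = TRUE}) so the search surface is deterministic.
#'
#' @param loglikFn function(theta) returning a log-likelihood
#' @param prior a \linkS4class{PriorBox}
#' @param nStarts number of starting points
#' @param budget objective evaluations per start
#' @param seed RNG seed (start selection)
#' @return list with \code{theta} (the best point found) and \code{loglik}
#'   (its re-evaluated log-likelihood)
#' @export
mleFit <- function(loglikFn, prior, nStarts = 5L, budget = 300L, seed = 1L) {
  lo <- prior@lower; hi <- prior@upper
  pnames <- names(lo)
  toTheta <- function(z) lo + (hi - lo) / (1 + exp(-z))
  toZ <- function(th) {
    f <- pmin(pmax((th - lo) / (hi - lo), 1e-6), 1 - 1e-6)
    log(f / (1 - f))
  }
  obj <- function(z) {
    ll <- tryCatch(loglikFn(setNames(toTheta(z), pnames)),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- priorSample(prior, nStarts, seed)
  best <- NULL
  for (i in seq_len(nStarts)) {
    fit <- tryCatch(
      if (length(lo) == 1)
        optim(toZ(starts[i, ]), obj, method = "Brent", lower = -15,
              upper = 15, control = list(maxit = budget))
      else
        optim(toZ(starts[i, ]), obj, method = "Nelder-Mead",
              control = list(maxit = budget)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < 1e10 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimization starts invalid", call. = FALSE)
  theta <- setNames(toTheta(best$par), pnames)
  list(theta = theta, loglik = loglikFn(theta))
}

#' Posterior-predictive simulation
#'
#' SSA simulation under supplied parameter draws: a single named vector
#' reduces to \code{\link{simulateDataset}}; a matrix of draws (e.g. from
#' a \linkS4class{Chain}) simulates \code{nCellsPerTheta} cells per row.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param thetas named vector or draws matrix with named columns
#' @param obsTimes observation times
#' @param nCellsPerTheta cells per parameter set
#' @param seed RNG seed
#' @param sig optional \linkS4class{Signal}
#' @param init initial state
#' @return a \linkS4class{SnapshotDataset} pooling all simulated cells
#' @export
posteriorPredictive <- function(net, thetas, obsTimes, nCellsPerTheta = 1L,
                                seed = 1L, sig = NULL, init = net@init) {
  if (is.null(dim(thetas))) thetas <- matrix(thetas, 1,
                                             dimnames = list(NULL, names(thetas)))
  parts <- lapply(seq_len(nrow(thetas)), function(i)
    simulateDataset(net, setNames(thetas[i, ], colnames(thetas)),
                    init = init, obsTimes = obsTimes,
                    nCells = nCellsPerTheta, seed = .childSeed(seed, i),
                    correlated = TRUE, sig = sig)@counts)
  arr <- do.call(abind3, list(parts))
  new("SnapshotDataset", counts = arr, times = as.numeric(obsTimes),
      speciesNames = net@species[net@observed], correlated = TRUE)
}

# minimal 3-d array bind along dim 1
abind3 <- function(parts) {
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0L, c(n, d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Equal-tailed credible interval from a chain
#'
#' @param chain a \linkS4class{Chain}
#' @param param parameter name or index
#' @param level credible level (e.g. 0.9); \code{level = 1} gives the full
#'   sample range
#' @param burnin fraction of initial iterations discarded (default 0.2)
#' @return named vector c(lo, hi)
#' @export
credibleInterval <- function(chain, param, level = 0.9, burnin = 0.2) {
  x <- chain@draws[, param]
  drop <- floor(length(x) * burnin)
  if (drop >= length(x)) stop("burn-in leaves no samples", call. = FALSE)
  x <- x[(drop + 1):length(x)]
  a <- (1 - level) / 2
  setNames(quantile(x, c(a, 1 - a), names = FALSE), c("lo", "hi"))
}

#' Gelman-Rubin potential scale reduction across chains
#'
#' @param chains list of \linkS4class{Chain} objects (same parameters)
#' @param burnin fraction of initial iterations discarded
#' @return named vector of split-free R-hat per parameter
#' @export
gelmanRubin <- function(chains, burnin = 0.2) {
  mats <- lapply(chains, function(ch) {
    x <- ch@draws
    x[(floor(nrow(x) * burnin) + 1):nrow(x), , drop = FALSE]
  })
  n <- min(vapply(mats, nrow, numeric(1)))
  mats <- lapply(mats, function(m) m[seq_len(n), , drop = FALSE])
  m <- length(mats)
  vapply(colnames(mats[[1]]), function(p) {
    means <- vapply(mats, function(x) mean(x[, p]), numeric(1))
    vars <- vapply(mats, function(x) var(x[, p]), numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}
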