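## The three comparison methods: Gaussian synthetic likelihoods (GSL),
## moment-based inference (MBI) on sample moments with analytic moment
## means/covariances (LMA-linearized where the network has protein-promoter
## binding), and sequential ABC with per-time moment summaries.

# multivariate normal log-density via Cholesky; NULL if not PD
.dmvnormLog <- function(X, mu, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  d <- length(mu)
  Z <- forwardsolve(t(R), t(X) - mu)
  -0.5 * colSums(Z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

.rmvnorm <- function(n, mu, Sigma) {
  R <- chol(Sigma)
  matrix(rnorm(n * length(mu)), n) %*% R + rep(mu, each = n)
}

#' Gaussian synthetic likelihood configuration
#'
#' @param nSim simulations per evaluation
#' @param mode \code{"joint"} (one S*T-dimensional Gaussian over each
#'   cell's vectorized trajectory; requires correlated data) or
#'   \code{"per_time"} (independent S-dimensional Gaussians per time)
#' @param shrinkage diagonal shrinkage factor lambda: Sigma +
#'   lambda tr(Sigma)/dim I (escalated if the covariance is singular)
#' @return a list of class \code{gslConfig}
#' @export
gslConfig <- function(nSim = 10000L, mode = c("joint", "per_time"),
                      shrinkage = 1e-6) {
  mode <- match.arg(mode)
  structure(list(nSim = as.integer(nSim), mode = mode,
                 shrinkage = shrinkage), class = "gslConfig")
}

#' Gaussian synthetic likelihood estimate
#'
#' Simulates the network at theta and models observed molecule numbers as
#' multivariate Gaussian with mean and covariance estimated from the
#' simulations by maximum likelihood. In joint mode each cell's T x S
#' trajectory is vectorized (time fastest within species) into one
#' S*T-dimensional Gaussian; in per-time mode independent Gaussians are
#' fit per time point.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param theta named parameter vector
#' @param data a \linkS4class{SnapshotDataset}
#' @param cfg a \code{\link{gslConfig}}
#' @param seed RNG seed for the simulations
#' @param sig optional \linkS4class{Signal}
#' @param init initial state
#' @return log-likelihood estimate (sum over cells)
#' @export
gslLoglik <- function(net, theta, data, cfg = gslConfig(), seed,
                      sig = NULL, init = net@init) {
  if (cfg$mode == "joint" && !data@correlated)
    stop("joint GSL needs time-correlated data; use mode = 'per_time'",
         call. = FALSE)
  sims <- simulateDataset(net, theta, init = init, obsTimes = data@times,
                          nCells = cfg$nSim, seed = .childSeed(seed, 1),
                          correlated = TRUE, sig = sig)
  simArr <- sims@counts; obsArr <- data@counts
  T <- dim(obsArr)[2]; S <- dim(obsArr)[3]
  evalBlock <- function(Ysim, Yobs) {
    mu <- colMeans(Ysim)
    Sg <- crossprod(sweep(Ysim, 2, mu)) / nrow(Ysim) # MLE covariance
    lam <- cfg$shrinkage
    for (k in 1:8) {
      ll <- .dmvnormLog(Yobs, mu, Sg + diag(lam * sum(diag(Sg)) /
                                              ncol(Sg), ncol(Sg)))
      if (!is.null(ll)) {
        if (k > 1) warning("GSL covariance shrinkage escalated to ", lam)
        return(sum(ll))
      }
      lam <- lam * 100
    }
    warning("GSL covariance singular; returning -Inf")
    -Inf
  }
  if (cfg$mode == "joint") {
    flat <- function(a) matrix(a, dim(a)[1], T * S)
    evalBlock(flat(simArr), flat(obsArr))
  } else {
    tot <- 0
    for (t in seq_len(T)) {
      tot <- tot + evalBlock(matrix(simArr[, t, ], ncol = S),
                             matrix(obsArr[, t, ], ncol = S))
      if (!is.finite(tot)) return(-Inf)
    }
    tot
  }
}

# monomial keys for the observed first and second uncentred moments
.obsMomentKeys <- function(S, obsIdx, nSpecies) {
  firsts <- lapply(seq_len(S), function(i) {
    e <- integer(nSpecies); e[obsIdx[i]] <- 1L; e
  })
  seconds <- list()
  for (i in seq_len(S)) for (j in i:S) {
    e <- integer(nSpecies); e[obsIdx[i]] <- e[obsIdx[i]] + 1L
    e[obsIdx[j]] <- e[obsIdx[j]] + 1L
    seconds[[length(seconds) + 1]] <- e
  }
  c(firsts, seconds)
}

#' Moment-based inference log-likelihood
#'
#' Models the observed per-time first and second uncentred sample moments
#' as multivariate Gaussian (CLT for sample moments over n cells), with
#' mean equal to the analytic CME moments and covariance from the exact
#' finite-n sample-moment formulas, e.g. Var(m1) = (mu2 - mu1^2)/n,
#' Cov(m1, m2) = (mu3 - mu1 mu2)/n, Var(m2) = (mu4 - mu2^2)/n (multivariate
#' analogues for several observed species). Times are treated as
#' independent. Networks with protein-promoter binding are LMA-linearized
#' first so that the moment equations close; linear networks are exact.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param theta named parameter vector
#' @param data a \linkS4class{SnapshotDataset}
#' @param sig optional \linkS4class{Signal}
#' @param init initial state
#' @return log-likelihood (-Inf with a warning when the moment covariance
#'   is not positive definite)
#' @export
mbiLoglik <- function(net, theta, data, sig = NULL, init = net@init) {
  rates <- .rateValues(net, theta)
  nonlinear <- any(vapply(seq_len(nrow(net@change)), function(j)
    rates[j] > 0 && sum(net@orders[j, ]) >= 2, logical(1)))
  lnet <- if (nonlinear) lmaLinearize(net, theta)$net else net
  ms <- momentEquations(lnet, theta, order = 4L)
  mm <- solveMoments(ms, init, data@times, sig)
  obsIdx <- net@observed
  S <- length(obsIdx)
  C <- nCells(data)
  phis <- .obsMomentKeys(S, obsIdx, length(net@species))
  d <- length(phis)
  phiKeys <- vapply(phis, .mkey, character(1))
  prodKeys <- outer(seq_len(d), seq_len(d), Vectorize(function(i, j)
    .mkey(phis[[i]] + phis[[j]])))
  ll <- 0
  for (t in seq_len(length(data@times))) {
    mu <- mm[t, phiKeys]
    Ephiphi <- matrix(mm[t, prodKeys], d, d)
    Sg <- (Ephiphi - tcrossprod(mu)) / C
    # observed sample moments
    X <- matrix(data@counts[, t, ], C, S)
    obs <- c(colMeans(X),
             unlist(lapply(seq_len(S), function(i)
               vapply(i:S, function(j) mean(X[, i] * X[, j]), numeric(1)))))
    lt <- .dmvnormLog(matrix(obs, 1), mu, Sg)
    if (is.null(lt)) {
      warning("moment covariance not positive definite; -Inf")
      return(-Inf)
    }
    ll <- ll + lt
  }
  as.numeric(ll)
}

#' Per-time moment summary statistics
#'
#' Concatenated per-time first and second uncentred moments over the
#' observed species, time-major; within a time the ordering is all means
#' followed by second moments x_i x_j for i <= j.
#'
#' @param data a \linkS4class{SnapshotDataset}
#' @return named numeric summary vector
#' @export
summaryMoments <- function(data) {
  arr <- data@counts
  C <- dim(arr)[1]; T <- dim(arr)[2]; S <- dim(arr)[3]
  out <- c()
  for (t in seq_len(T)) {
    X <- matrix(arr[, t, ], C, S)
    m1 <- colMeans(X)
    names(m1) <- sprintf("t%g.m1.%d", data@times[t], seq_len(S))
    m2 <- c()
    for (i in seq_len(S)) for (j in i:S) {
      v <- mean(X[, i] * X[, j])
      names(v) <- sprintf("t%g.m2.%d%d", data@times[t], i, j)
      m2 <- c(m2, v)
    }
    out <- c(out, m1, m2)
  }
  out
}

#' ABC discrepancy: sum of squared relative errors
#'
#' \eqn{\sum_i ((s_{sim,i} - s_{obs,i}) / s_{obs,i})^2}, with an absolute
#' squared error fallback for observed entries below 1e-12 in magnitude.
#' Asymmetric by construction (relative to the observed summaries).
#'
#' @param sSim,sObs summary vectors of equal length
#' @return nonnegative scalar
#' @export
abcDiscrepancy <- function(sSim, sObs) {
  stopifnot(length(sSim) == length(sObs))
  denom <- ifelse(abs(sObs) < 1e-12, 1, sObs)
  sum(((sSim - sObs) / denom)^2)
}

#' ABC-SMC configuration
#'
#' @param nRounds number of rounds (round 1 samples from the prior)
#' @param nAccept acceptances per round
#' @param inflate proposal covariance inflation factor
#' @param epsilon1 tolerance of round 1 (default Inf: accept everything)
#' @param minAcceptRate abort threshold for a round's acceptance rate
#' @return a list of class \code{abcConfig}
#' @export
abcConfig <- function(nRounds = 4L, nAccept = 100L, inflate = 2,
                      epsilon1 = Inf, minAcceptRate = 1e-4) {
  structure(list(nRounds = as.integer(nRounds),
                 nAccept = as.integer(nAccept), inflate = inflate,
                 epsilon1 = epsilon1, minAcceptRate = minAcceptRate),
            class = "abcConfig")
}

#' Sequential approximate Bayesian computation
#'
#' Round 1 draws parameters from the box prior and accepts those whose
#' summary discrepancy (squared relative errors of per-time first and
#' second moments) is at most epsilon1. Each later round samples from a
#' Gaussian proposal fitted to the previous round's acceptances (covariance
#' inflated), rejected against the box prior, with tolerance set to the
#' median of the previous round's accepted discrepancies; importance
#' weights are 1/proposal density (uniform prior). Iterates until the
#' requested number of acceptances per round.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param prior a \linkS4class{PriorBox}
#' @param data observed \linkS4class{SnapshotDataset}
#' @param cfg an \code{\link{abcConfig}}
#' @param seed RNG seed
#' @param sig optional \linkS4class{Signal}
#' @param init initial state
#' @return list of rounds, each with \code{theta} (accepted draws),
#'   \code{weights}, \code{discrepancies}, \code{epsilon}, \code{nTried}
#' @export
abcSMC <- function(net, prior, data, cfg = abcConfig(), seed, sig = NULL,
                   init = net@init) {
  sObs <- summaryMoments(data)
  C <- nCells(data)
  pnames <- names(prior@lower)
  simCounter <- 0L
  simulateSummary <- function(theta) {
    simCounter <<- simCounter + 1L
    d <- simulateDataset(net, setNames(theta, pnames), init = init,
                         obsTimes = data@times, nCells = C,
                         seed = .childSeed(seed, 7919 + simCounter),
                         correlated = data@correlated, sig = sig)
    summaryMoments(d)
  }
  rounds <- list()
  eps <- cfg$epsilon1
  .withSeed(seed, {
    for (r in seq_len(cfg$nRounds)) {
      if (r > 1) {
        prev <- rounds[[r - 1]]
        eps <- median(prev$discrepancies)
        muP <- colSums(prev$theta * prev$weights) / sum(prev$weights)
        ctr <- sweep(prev$theta, 2, muP)
        SgP <- crossprod(ctr * prev$weights, ctr) / sum(prev$weights)
        SgP <- cfg$inflate * SgP +
          diag(1e-10 * (prior@upper - prior@lower)^2, length(pnames))
      }
      acc <- matrix(0, 0, length(pnames))
      disc <- numeric(0); wts <- numeric(0)
      tried <- 0L
      while (nrow(acc) < cfg$nAccept) {
        tried <- tried + 1L
        if (tried > max(1000, cfg$nAccept / cfg$minAcceptRate))
          stop("ABC round ", r, " acceptance rate below threshold (",
               nrow(acc), "/", tried, " accepted, epsilon=", signif(eps, 4),
               ")", call. = FALSE)
        if (r == 1) {
          th <- prior@lower + runif(length(pnames)) *
            (prior@upper - prior@lower)
        } else {
          th <- as.numeric(.rmvnorm(1, muP, SgP))
          if (!inPrior(prior, setNames(th, pnames))) next
        }
        dsc <- abcDiscrepancy(simulateSummary(th), sObs)
        if (dsc <= eps) {
          acc <- rbind(acc, th)
          disc <- c(disc, dsc)
          wts <- c(wts, if (r == 1) 1 else
            1 / max(exp(.dmvnormLog(matrix(th, 1), muP, SgP)), 1e-300))
        }
      }
      colnames(acc) <- pnames
      rounds[[r]] <- list(theta = acc, weights = wts / sum(wts),
                          discrepancies = disc, epsilon = eps,
                          nTried = tried)
    }
  })
  rounds
}
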