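## The synthetic-model likelihood estimator: simulate the network at theta,
## fit the surrogate (NB-HMM for time series, independent per-time NB
## mixtures for population snapshots), evaluate the observed data under the
## surrogate. The surrogate is refit from scratch at every theta, so the
## estimate is stochastic; callers control seeds explicitly.

#' Synthetic-likelihood configuration
#'
#' @param nSim simulations per likelihood evaluation
#' @param K number of mixture components / hidden states
#' @param mode \code{"hmm"} (time-correlated surrogate) or
#'   \code{"independent_mnb"} (per-time mixtures; appropriate for
#'   population snapshots or weak time correlations)
#' @param nRestarts EM restarts per fit
#' @param maxIter EM iteration cap
#' @param tol EM relative convergence tolerance
#' @param weightFloor floor on weights / transition rows
#' @param tiedTrans,tiedEmis tie HMM transitions / emissions across time
#' @return a list of class \code{synlikConfig}
#' @export
synlikConfig <- function(nSim = 10000L, K = 2L,
                         mode = c("hmm", "independent_mnb"),
                         nRestarts = 3L, maxIter = 200L, tol = 1e-6,
                         weightFloor = 1e-6, tiedTrans = FALSE,
                         tiedEmis = FALSE) {
  mode <- match.arg(mode)
  if (nSim < 10 * K)
    stop("nSim must be at least 10 * K for identifiability", call. = FALSE)
  structure(list(nSim = as.integer(nSim), K = as.integer(K), mode = mode,
                 nRestarts = as.integer(nRestarts),
                 maxIter = as.integer(maxIter), tol = tol,
                 weightFloor = weightFloor, tiedTrans = tiedTrans,
                 tiedEmis = tiedEmis),
            class = "synlikConfig")
}

#' Synthetic-model log-likelihood estimate
#'
#' Three steps: (1) simulate \code{nSim} trajectories of the network at
#' \code{theta} with the SSA (Extrande when a signal is present), on the
#' dataset's observation grid; (2) fit the surrogate to the simulations
#' (Baum-Welch for \code{mode = "hmm"}, per-time NB-mixture EM for
#' \code{mode = "independent_mnb"}); (3) evaluate the observed data under
#' the fitted surrogate (forward algorithm, or sums of mixture log-pmfs).
#' Fit failures return -Inf (treated as rejection by samplers) rather than
#' raising.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param theta named parameter vector
#' @param data a \linkS4class{SnapshotDataset}
#' @param cfg a \code{\link{synlikConfig}}
#' @param seed RNG seed (simulation and fit seeds derive from it)
#' @param sig optional \linkS4class{Signal}
#' @param init initial state for the simulations
#' @return log-likelihood estimate; attribute \code{"surrogate"} carries
#'   the fitted model(s)
#' @export
syntheticLoglik <- function(net, theta, data, cfg = synlikConfig(), seed,
                            sig = NULL, init = net@init) {
  sims <- simulateDataset(net, theta, init = init, obsTimes = data@times,
                          nCells = cfg$nSim, seed = .childSeed(seed, 1),
                          correlated = TRUE, sig = sig)
  obs <- data@counts
  storage.mode(obs) <- "double"
  out <- tryCatch({
    if (cfg$mode == "hmm") {
      fit <- fitBaumWelch(sims, cfg$K, tol = cfg$tol, maxIter = cfg$maxIter,
                          nRestarts = cfg$nRestarts,
                          weightFloor = cfg$weightFloor,
                          tiedTrans = cfg$tiedTrans, tiedEmis = cfg$tiedEmis,
                          seed = .childSeed(seed, 2))
      ll <- sum(forwardLoglik(fit$hmm, data))
      attr(ll, "surrogate") <- fit$hmm
      ll
    } else {
      T <- dim(obs)[2]
      ll <- 0
      mixes <- vector("list", T)
      simArr <- sims@counts
      for (t in seq_len(T)) {
        X <- matrix(as.numeric(simArr[, t, ]), ncol = dim(simArr)[3])
        fit <- .fitProductMNB(X, cfg$K, tol = cfg$tol,
                              maxIter = cfg$maxIter,
                              nRestarts = cfg$nRestarts,
                              weightFloor = cfg$weightFloor,
                              seed = .childSeed(seed, 100 + t))
        mixes[[t]] <- fit
        # evaluate the joint product-NB mixture at each cell's counts
        Xobs <- matrix(as.numeric(obs[, t, ]), ncol = dim(obs)[3])
        K <- length(fit$weights)
        lp <- matrix(log(fit$weights), nrow(Xobs), K, byrow = TRUE)
        for (k in seq_len(K)) for (s in seq_len(ncol(Xobs)))
          lp[, k] <- lp[, k] + dnbinom(Xobs[, s], size = fit$r[k, s],
                                       prob = fit$p[k, s], log = TRUE)
        m <- apply(lp, 1, max)
        ll <- ll + sum(m + log(rowSums(exp(lp - m))))
      }
      attr(ll, "surrogate") <- mixes
      ll
    }
  }, error = function(e) {
    warning("synthetic-likelihood fit failed: ", conditionMessage(e))
    -Inf
  })
  out
}

#' Variance of the synthetic-likelihood estimator
#'
#' Repeated independent evaluations at fixed theta. The spread grows with
#' the number of observed datapoints and shrinks with \code{nSim}; useful
#' for choosing the simulation budget so MCMC acceptance rates stay
#' workable.
#'
#' @inheritParams syntheticLoglik
#' @param nReps number of independent evaluations
#' @return list with \code{variance}, \code{sd}, and the \code{estimates}
#' @export
syntheticLoglikVariance <- function(net, theta, data, cfg = synlikConfig(),
                                    nReps = 10L, seed, sig = NULL,
                                    init = net@init) {
  if (nCells(data) == 0)
    return(list(variance = 0, sd = 0, estimates = numeric(0)))
  est <- vapply(seq_len(nReps), function(i)
    as.numeric(syntheticLoglik(net, theta, data, cfg,
                               seed = .childSeed(seed, i), sig = sig,
                               init = init)),
    numeric(1))
  list(variance = var(est), sd = sd(est), estimates = est)
}

#' Closure factory for likelihood functions
#'
#' Wraps a likelihood estimator as \code{function(theta)} for use with
#' \code{\link{mhSample}} and \code{\link{mleFit}}. For stochastic methods
#' a fresh seed is derived per call from the master seed and an internal
#' counter (the refit-from-scratch-per-theta procedure); with
#' \code{crn = TRUE} the same seed is reused on every call (common random
#' numbers, useful for optimization).
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param data a \linkS4class{SnapshotDataset}
#' @param method \code{"sm"}, \code{"gsl"}, \code{"mbi"} or \code{"fsp"}
#' @param seed master seed
#' @param cfg method configuration (\code{\link{synlikConfig}} for sm,
#'   \code{\link{gslConfig}} for gsl, ignored otherwise)
#' @param sig optional \linkS4class{Signal}
#' @param init initial state
#' @param crn reuse one seed across calls (common random numbers)
#' @return function(theta) returning a log-likelihood (estimate)
#' @export
makeLoglikFn <- function(net, data, method = c("sm", "gsl", "mbi", "fsp"),
                         seed = 1L, cfg = NULL, sig = NULL, init = net@init,
                         crn = FALSE) {
  method <- match.arg(method)
  counter <- 0L
  trunc <- NULL
  if (method == "fsp")
    force(init)
  function(theta) {
    counter <<- counter + 1L
    s <- if (crn) seed else .childSeed(seed, counter)
    switch(method,
      sm = as.numeric(syntheticLoglik(net, theta, data,
                                      cfg %||% synlikConfig(), s, sig, init)),
      gsl = as.numeric(gslLoglik(net, theta, data, cfg %||% gslConfig(), s,
                                 sig, init)),
      mbi = mbiLoglik(net, theta, data, sig = sig, init = init),
      fsp = fspDatasetLoglik(net, theta, data, trunc = NULL, sig = sig,
                             init = init))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
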