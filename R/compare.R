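## Likelihood-fidelity comparison: sample parameters from the prior,
## compute the exact FSP log-likelihood and the approximations (synthetic
## model, GSL, MBI) at each, and tabulate paired values. Reproduces the
## surrogate-fidelity experiment for networks small enough for the FSP.

#' Compare approximate log-likelihoods against FSP ground truth
#'
#' @param net a \linkS4class{ReactionNetwork} (FSP-tractable)
#' @param data observed \linkS4class{SnapshotDataset}
#' @param prior a \linkS4class{PriorBox} from which M parameter sets are
#'   drawn
#' @param M number of prior draws
#' @param seed master seed (theta draws and stochastic evaluations)
#' @param methods subset of \code{c("sm", "gsl", "mbi")}
#' @param smCfg,gslCfg method configurations
#' @param sig optional \linkS4class{Signal}
#' @param thetas optional explicit parameter matrix (overrides M/prior
#'   draws; used to re-evaluate the same thetas under different seeds)
#' @return data.frame with the drawn parameters, column \code{fsp}, and
#'   one column per approximation
#' @export
compareLikelihoods <- function(net, data, prior, M = 20L, seed = 1L,
                               methods = c("sm", "gsl", "mbi"),
                               smCfg = synlikConfig(nSim = 5000L),
                               gslCfg = gslConfig(nSim = 5000L),
                               sig = NULL, thetas = NULL) {
  if (is.null(thetas)) thetas <- priorSample(prior, M, .childSeed(seed, 1))
  M <- nrow(thetas)
  out <- as.data.frame(thetas)
  out$fsp <- NA_real_
  for (m in methods) out[[m]] <- NA_real_
  for (i in seq_len(M)) {
    th <- setNames(as.numeric(thetas[i, ]), colnames(thetas))
    out$fsp[i] <- fspDatasetLoglik(net, th, data, sig = sig)
    if ("sm" %in% methods)
      out$sm[i] <- as.numeric(syntheticLoglik(net, th, data, smCfg,
                                              seed = .childSeed(seed, 100 + i),
                                              sig = sig))
    if ("gsl" %in% methods)
      out$gsl[i] <- gslLoglik(net, th, data, gslCfg,
                              seed = .childSeed(seed, 200 + i), sig = sig)
    if ("mbi" %in% methods)
      out$mbi[i] <- tryCatch(mbiLoglik(net, th, data, sig = sig),
                             error = function(e) -Inf)
  }
  out
}

#' Mean absolute log-likelihood error per method
#'
#' Summarizes a \code{\link{compareLikelihoods}} table: mean |approximate -
#' FSP| per method, with -Inf evaluations counted at the worst finite
#' deviation observed for that method (so failures are penalized, not
#' dropped).
#'
#' @param cmp data.frame from \code{\link{compareLikelihoods}}
#' @return named numeric vector of mean absolute deviations
#' @export
likelihoodErrorSummary <- function(cmp) {
  methods <- setdiff(names(cmp), c(names(cmp)[seq_len(which(names(cmp) == "fsp") - 1)], "fsp"))
  vapply(methods, function(m) {
    dev <- abs(cmp[[m]] - cmp$fsp)
    bad <- !is.finite(dev)
    if (all(bad)) return(Inf)
    dev[bad] <- max(dev[!bad])
    mean(dev)
  }, numeric(1))
}
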