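#' Stochastic reaction network
#'
#' Declarative representation of a mass-action reaction network. Reactions
#' are stored column-aligned with species: \code{change} holds net
#' stoichiometries, \code{orders} mass-action reactant orders (propensity
#' uses falling factorials), and \code{compOrders} optional complement
#' orders \eqn{(1 - x_s)} for 0/1 promoter-state species whose bound form
#' has been eliminated by conservation. A reaction may carry a geometric
#' burst on a target species (the burst supplies the jump, so the fixed
#' change in the target is zero) and/or be modulated by a time-dependent
#' input signal.
#'
#' @slot name model name
#' @slot species character vector of species names
#' @slot kinds \code{"count"} or \code{"promoter-state"} per species
#' @slot maxHints per-species truncation hints for the FSP (NA = none)
#' @slot change integer matrix, reactions x species
#' @slot orders integer matrix of mass-action orders
#' @slot compOrders integer matrix of complement orders (promoter species)
#' @slot rateParams rate parameter name per reaction
#' @slot burstTarget species index receiving a geometric burst (NA = none)
#' @slot burstMeanParam parameter name of the burst mean (NA = none)
#' @slot modulated logical; propensity multiplied by the input signal
#' @slot observed indices of observed species
#' @slot conservation list of \code{list(species =, total =)} linear laws
#' @slot init default initial state
#' @slot feedback optional regime tag (e.g. \code{"negative"})
#' @export
setClass("ReactionNetwork",
  representation(
    name = "character", species = "character", kinds = "character",
    maxHints = "numeric", change = "matrix", orders = "matrix",
    compOrders = "matrix", rateParams = "character",
    burstTarget = "integer", burstMeanParam = "character",
    modulated = "logical", observed = "integer", conservation = "list",
    init = "integer", feedback = "character"
  )
)

setValidity("ReactionNetwork", function(object) {
  S <- length(object@species)
  R <- nrow(object@change)
  msg <- character()
  if (anyDuplicated(object@species)) msg <- c(msg, "species names must be unique")
  if (!all(object@kinds %in% c("count", "promoter-state")))
    msg <- c(msg, "kinds must be 'count' or 'promoter-state'")
  for (m in list(object@orders, object@compOrders)) {
    if (!identical(dim(m), dim(object@change)))
      msg <- c(msg, "change/orders/compOrders dimensions differ")
  }
  if (ncol(object@change) != S) msg <- c(msg, "change must have one column per species")
  if (length(object@rateParams) != R) msg <- c(msg, "one rate parameter per reaction")
  if (length(object@burstTarget) != R || length(object@modulated) != R)
    msg <- c(msg, "burst/modulation fields must match reaction count")
  for (j in seq_len(R)) {
    tgt <- object@burstTarget[j]
    if (!is.na(tgt) && object@change[j, tgt] != 0) {
      msg <- c(msg, "burst reactions must have zero fixed change in the target")
      break
    }
  }
  if (any(object@observed < 1 | object@observed > S))
    msg <- c(msg, "observed indices out of range")
  for (cl in object@conservation) {
    if (any(abs(rowSums(object@change[, cl$species, drop = FALSE])) > 0)) {
      msg <- c(msg, "conservation law violated by a reaction")
      break
    }
  }
  if (length(object@init) != S) msg <- c(msg, "init must have one entry per species")
  if (length(msg)) msg else TRUE
})

#' Time-dependent input signal
#'
#' Piecewise signal (e.g. a kinase concentration) modulating reaction
#' propensities; \code{upperBound} is required by Extrande thinning and
#' must dominate every interpolated value.
#'
#' @slot times increasing time points
#' @slot values nonnegative signal values
#' @slot interpolation \code{"linear"} or \code{"previous"}
#' @slot upperBound finite upper bound on the interpolated signal
#' @export
setClass("Signal",
  representation(times = "numeric", values = "numeric",
                 interpolation = "character", upperBound = "numeric"))

setValidity("Signal", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE)) msg <- c(msg, "times must be strictly increasing")
  if (length(object@times) != length(object@values)) msg <- c(msg, "times/values length mismatch")
  if (any(object@values < 0)) msg <- c(msg, "values must be nonnegative")
  if (!object@interpolation %in% c("linear", "previous"))
    msg <- c(msg, "interpolation must be 'linear' or 'previous'")
  if (!is.finite(object@upperBound) || object@upperBound < max(object@values))
    msg <- c(msg, "upperBound must be finite and >= max(values)")
  if (length(msg)) msg else TRUE
})

#' Single-cell count dataset
#'
#' Molecule counts of observed species for C cells at T observation times.
#' \code{correlated = TRUE} marks rows of one cell as a time series (live
#' cell imaging); \code{FALSE} marks independent population snapshots, for
#' which likelihoods factorize over (cell, time).
#'
#' @slot counts integer array, cells x times x species
#' @slot times observation times
#' @slot speciesNames observed species names
#' @slot correlated logical
#' @export
setClass("SnapshotDataset",
  representation(counts = "array", times = "numeric",
                 speciesNames = "character", correlated = "logical"))

setValidity("SnapshotDataset", function(object) {
  d <- dim(object@counts)
  msg <- character()
  if (length(d) != 3) msg <- c(msg, "counts must be a 3-d array (cells x times x species)")
  else {
    if (d[2] != length(object@times)) msg <- c(msg, "times length must match dim 2")
    if (d[3] != length(object@speciesNames)) msg <- c(msg, "speciesNames must match dim 3")
  }
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be nonnegative integers")
  if (is.unsorted(object@times, strictly = TRUE)) msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Mixture of negative binomials
#'
#' Finite mixture with components NB(r, p), pmf
#' \eqn{\Gamma(x+r)/(\Gamma(r) x!) p^r (1-p)^x}; component mean
#' \eqn{\mu = r(1-p)/p} and Fano factor \eqn{1 + \mu/r > 1}.
#'
#' @slot weights mixture weights (simplex)
#' @slot r component dispersions (> 0)
#' @slot p component success probabilities in (0, 1)
#' @export
setClass("NBMixture",
  representation(weights = "numeric", r = "numeric", p = "numeric"))

setValidity("NBMixture", function(object) {
  msg <- character()
  K <- length(object@weights)
  if (K < 1) msg <- c(msg, "at least one component")
  if (abs(sum(object@weights) - 1) > 1e-12) msg <- c(msg, "weights must sum to 1")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (length(object@r) != K || length(object@p) != K) msg <- c(msg, "component length mismatch")
  if (any(object@r <= 0)) msg <- c(msg, "r must be positive")
  if (any(object@p <= 0 | object@p >= 1)) msg <- c(msg, "p must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Negative-binomial-emission hidden Markov model
#'
#' The synthetic model proper: a finite-state Markov chain over the
#' observation grid with per-(time, state) NB emissions, conditionally
#' independent across observed species given the hidden state. Transition
#' matrices are per consecutive-observation interval (time-inhomogeneous by
#' default). Integrating out the hidden state at any time yields a mixture
#' of negative binomials.
#'
#' @slot pi initial distribution over the K hidden states
#' @slot trans array (T-1) x K x K of row-stochastic transition matrices
#' @slot r,p arrays T x K x S of NB emission parameters
#' @slot times observation times (length T)
#' @slot species observed species names (length S)
#' @export
setClass("NBHMM",
  representation(pi = "numeric", trans = "array", r = "array", p = "array",
                 times = "numeric", species = "character"))

setValidity("NBHMM", function(object) {
  msg <- character()
  K <- length(object@pi)
  dr <- dim(object@r)
  T <- dr[1]
  if (abs(sum(object@pi) - 1) > 1e-12) msg <- c(msg, "pi must sum to 1")
  if (!identical(dim(object@p), dr)) msg <- c(msg, "r/p dimension mismatch")
  if (dr[2] != K) msg <- c(msg, "emission state dimension must equal length(pi)")
  if (T > 1) {
    dt <- dim(object@trans)
    if (!identical(dt, c(T - 1L, K, K))) msg <- c(msg, "trans must be (T-1) x K x K")
    else {
      rs <- apply(object@trans, c(1, 2), sum)
      if (any(abs(rs - 1) > 1e-12)) msg <- c(msg, "transition rows must sum to 1")
    }
  }
  if (length(object@times) && length(object@times) != T)
    msg <- c(msg, "times length must equal emission time dimension")
  if (any(object@r <= 0) || any(object@p <= 0 | object@p >= 1))
    msg <- c(msg, "emission parameters out of range")
  if (length(msg)) msg else TRUE
})

#' Uniform box prior
#'
#' @slot lower,upper named per-parameter bounds; density is constant inside
#'   the box and zero outside.
#' @export
setClass("PriorBox", representation(lower = "numeric", upper = "numeric"))

setValidity("PriorBox", function(object) {
  msg <- character()
  if (length(object@lower) != length(object@upper)) msg <- c(msg, "bound length mismatch")
  if (is.null(names(object@lower)) || is.null(names(object@upper)))
    msg <- c(msg, "bounds must be named")
  if (any(object@lower >= object@upper)) msg <- c(msg, "lower must be < upper")
  if (length(msg)) msg else TRUE
})

#' MCMC chain
#'
#' @slot draws iterations x parameters matrix (inside the prior box)
#' @slot logliks stored log-likelihood estimates per iteration
#' @slot accepted acceptance flags
#' @slot seed master seed used
#' @slot method method tag (e.g. \code{"sm"}, \code{"fsp"})
#' @export
setClass("Chain",
  representation(draws = "matrix", logliks = "numeric", accepted = "logical",
                 seed = "numeric", method = "character"))

setValidity("Chain", function(object) {
  n <- nrow(object@draws)
  if (length(object@logliks) != n || length(object@accepted) != n)
    "draws/logliks/accepted lengths differ" else TRUE
})

#' FSP state-space truncation
#'
#' Enumeration of all states within per-species bounds that satisfy the
#' network's conservation laws for a given initial state, with a
#' state-to-index bijection used to assemble the truncated CME generator.
#'
#' @slot states integer matrix, states x species
#' @slot bounds per-species upper bounds
#' @slot radix mixed-radix encoding weights
#' @slot codes sorted numeric codes of enumerated states
#' @slot order permutation aligning codes with state rows
#' @slot species species names
#' @export
setClass("FSPTruncation",
  representation(states = "matrix", bounds = "numeric", radix = "numeric",
                 codes = "numeric", order = "integer", species = "character"))

#' FSP solution
#'
#' @slot truncation the \linkS4class{FSPTruncation} used
#' @slot probs states x times probability matrix
#' @slot times solution times
#' @slot massDefect 1 - total mass per time (FSP truncation error bound)
#' @export
setClass("FSPSolution",
  representation(truncation = "FSPTruncation", probs = "matrix",
                 times = "numeric", massDefect = "numeric"))
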