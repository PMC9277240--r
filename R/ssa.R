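## Exact stochastic simulation: Gillespie direct method, Extrande thinning
## for signal-modulated networks, and dataset-scale sampling. The event loop
## lives in src/ssa.cpp; per-cell RNG streams are derived deterministically
## from the master seed so datasets are reproducible bit-for-bit.

.cppNetArgs <- function(net, params) {
  bt <- net@burstTarget
  list(change = net@change, orders = net@orders, comp = net@compOrders,
       rates = .rateValues(net, params),
       burstTarget = as.integer(ifelse(is.na(bt), -1L, bt - 1L)),
       burstMean = .burstMeans(net, params),
       modulated = net@modulated)
}

.simCore <- function(net, params, init, obsTimes, nCells, seed, sig,
                     maxEvents) {
  if (is.unsorted(obsTimes, strictly = TRUE))
    stop("obsTimes must be strictly increasing", call. = FALSE)
  if (any(init < 0)) stop("invalid initial state", call. = FALSE)
  a <- .cppNetArgs(net, params)
  .cpp_simulate_dataset(a$change, a$orders, a$comp, a$rates, a$burstTarget,
                        a$burstMean, a$modulated, as.integer(init),
                        as.numeric(obsTimes), as.integer(nCells),
                        as.double(seed), as.double(maxEvents),
                        .signalToCpp(sig))
}

#' Simulate one exact SSA trajectory
#'
#' Gillespie direct method; burst reactions draw geometric jumps. The state
#' is recorded immediately before each observation time (left-limit
#' convention at exact ties).
#'
#' @param net a \linkS4class{ReactionNetwork} without signal-modulated
#'   reactions
#' @param params named parameter vector
#' @param init initial state (defaults to the network's)
#' @param obsTimes strictly increasing observation times
#' @param seed RNG seed
#' @param maxEvents event cap guarding against runaway propensities
#' @return list with \code{times}, a times x species \code{states} matrix,
#'   and \code{seed}
#' @export
simulateSSA <- function(net, params, init = net@init, obsTimes, seed,
                        maxEvents = 1e7) {
  if (any(net@modulated))
    stop("network has signal-modulated reactions; use simulateExtrande",
         call. = FALSE)
  arr <- .simCore(net, params, init, obsTimes, 1L, seed, NULL, maxEvents)
  states <- matrix(arr, length(obsTimes), length(net@species),
                   dimnames = list(NULL, net@species))
  list(times = obsTimes, states = states, seed = seed)
}

#' Simulate one exact trajectory with a time-dependent input (Extrande)
#'
#' Thinning against a rate bound built from the signal's declared upper
#' bound: candidate events fire at the bound rate and are accepted with
#' probability (actual total propensity) / bound, which leaves the sampled
#' process exactly distributed under the time-varying propensities.
#'
#' @inheritParams simulateSSA
#' @param sig a \linkS4class{Signal} with a finite upper bound
#' @return as \code{\link{simulateSSA}}
#' @export
simulateExtrande <- function(net, params, init = net@init, obsTimes, sig,
                             seed, maxEvents = 1e7) {
  stopifnot(is(sig, "Signal"))
  arr <- .simCore(net, params, init, obsTimes, 1L, seed, sig, maxEvents)
  states <- matrix(arr, length(obsTimes), length(net@species),
                   dimnames = list(NULL, net@species))
  list(times = obsTimes, states = states, seed = seed)
}

#' Simulate a dataset of independent cells
#'
#' \code{nCells} independent trajectories restricted to the observed
#' species; per-cell seeds are derived deterministically from the master
#' seed (cells are independent streams).
#'
#' @inheritParams simulateSSA
#' @param nCells number of cells
#' @param correlated flag stored on the dataset: TRUE marks rows of one
#'   cell as a time series, FALSE as independent population snapshots
#' @param sig optional \linkS4class{Signal} (switches to Extrande)
#' @return a \linkS4class{SnapshotDataset}
#' @export
simulateDataset <- function(net, params, init = net@init, obsTimes, nCells,
                            seed, correlated = TRUE, sig = NULL,
                            maxEvents = 1e7) {
  stopifnot(nCells >= 1)
  arr <- .simCore(net, params, init, obsTimes, nCells, seed, sig, maxEvents)
  obs <- arr[, , net@observed, drop = FALSE]
  new("SnapshotDataset", counts = obs, times = as.numeric(obsTimes),
      speciesNames = net@species[net@observed], correlated = correlated)
}

#' Construct a SnapshotDataset from a count array
#'
#' @param counts cells x times x species integer array (a cells x times
#'   matrix is promoted to a single-species array)
#' @param times observation times
#' @param speciesNames observed species names
#' @param correlated time-series flag
#' @return a \linkS4class{SnapshotDataset}
#' @export
snapshotDataset <- function(counts, times, speciesNames = "X",
                            correlated = TRUE) {
  if (is.matrix(counts)) counts <- array(counts, c(dim(counts), 1))
  new("SnapshotDataset", counts = counts, times = as.numeric(times),
      speciesNames = speciesNames, correlated = correlated)
}
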