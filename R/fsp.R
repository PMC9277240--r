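## Finite state projection: truncated CME generator (including geometric
## burst jumps and signal-modulated rates), probability propagation by
## matrix exponential (time-homogeneous) or stiff ODE integration
## (time-varying), marginals, and exact time-series likelihoods by
## filtering over latent states. Ground truth for small networks.

#' Enumerate a truncated state space
#'
#' All states with \code{0 <= x_s <= bounds[s]} satisfying the network's
#' conservation laws at the given initial state, with a mixed-radix
#' state-to-index bijection.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param bounds per-species upper bounds (promoter-state species are
#'   bounded by 1 automatically)
#' @param init reference state for the conservation laws
#' @param cap maximum admissible number of states
#' @return an \linkS4class{FSPTruncation}
#' @export
fspTruncation <- function(net, bounds, init = net@init, cap = 1e6) {
  S <- length(net@species)
  bounds <- rep_len(as.numeric(bounds), S)
  bounds[net@kinds == "promoter-state"] <- 1
  if (prod(bounds + 1) > 50 * cap)
    stop("truncation enumeration too large", call. = FALSE)
  grid <- as.matrix(expand.grid(lapply(bounds, function(b) 0:b)))
  colnames(grid) <- net@species
  for (cl in net@conservation) {
    tot <- sum(init[cl$species])
    grid <- grid[rowSums(grid[, cl$species, drop = FALSE]) == tot, ,
                 drop = FALSE]
  }
  if (nrow(grid) > cap)
    stop(sprintf("truncation size %d exceeds cap %g", nrow(grid), cap),
         call. = FALSE)
  radix <- cumprod(c(1, bounds[-S] + 1))
  codes <- as.numeric(grid %*% radix)
  ord <- order(codes)
  new("FSPTruncation", states = grid, bounds = bounds, radix = radix,
      codes = codes[ord], order = as.integer(ord), species = net@species)
}

# indices of states (rows) in the truncation; NA if outside
.stateIndex <- function(trunc, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  inside <- rowSums(states < 0 | states > rep(trunc@bounds,
                                              each = nrow(states))) == 0
  idx <- rep(NA_integer_, nrow(states))
  if (any(inside)) {
    code <- as.numeric(states[inside, , drop = FALSE] %*% trunc@radix)
    pos <- findInterval(code, trunc@codes)
    ok <- pos >= 1 & trunc@codes[pmax(pos, 1)] == code
    idx[inside][ok] <- trunc@order[pos[ok]]
  }
  idx
}

# vectorized propensities over all enumerated states for one reaction
.propVec <- function(net, j, states, rate) {
  a <- rep(rate, nrow(states))
  for (s in seq_len(ncol(states))) {
    o <- net@orders[j, s]
    if (o > 0) for (i in seq_len(o)) a <- a * pmax(states[, s] - i + 1, 0)
    if (net@compOrders[j, s] > 0) a <- a * (states[, s] == 0)
  }
  a
}

#' Truncated CME generator
#'
#' Sparse rate matrix A with A[i, j] the rate from state j to state i and
#' diagonal minus the total outflow, so that dp/dt = A p and columns sum to
#' <= 0 (leaked mass at the truncation boundary is the FSP error). Burst
#' reactions contribute one entry per geometric jump size k >= 1, truncated
#' where the cumulative tail mass falls below \code{burstTol}; k = 0
#' firings are no-ops. Signal-modulated reactions can be assembled
#' separately (signal factor excluded) for time-varying propagation.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param params named parameter vector
#' @param trunc an \linkS4class{FSPTruncation}
#' @param which \code{"all"} (default), \code{"static"} (non-modulated
#'   reactions only) or \code{"modulated"} (modulated reactions, unit
#'   signal)
#' @param burstTol tail-mass cutoff for burst jump enumeration
#' @return a sparse \code{dgCMatrix}
#' @export
fspGenerator <- function(net, params, trunc, which = "all",
                         burstTol = 1e-12) {
  states <- trunc@states
  n <- nrow(states)
  rates <- .rateValues(net, params)
  bmeans <- .burstMeans(net, params)
  ii <- jj <- integer(0); xx <- numeric(0)
  diagOut <- numeric(n)
  use <- switch(which,
    all = rep(TRUE, nrow(net@change)),
    static = !net@modulated,
    modulated = net@modulated,
    stop("unknown generator subset"))
  for (j in which(use)) {
    a <- .propVec(net, j, states, rates[j])
    act <- which(a > 0)
    if (!length(act)) next
    tgt <- net@burstTarget[j]
    if (is.na(tgt)) {
      dest <- states[act, , drop = FALSE] +
        rep(net@change[j, ], each = length(act))
      di <- .stateIndex(trunc, dest)
      ok <- !is.na(di)
      ii <- c(ii, di[ok]); jj <- c(jj, act[ok]); xx <- c(xx, a[act][ok])
      diagOut[act] <- diagOut[act] + a[act]
    } else {
      b <- bmeans[j]
      if (b <= 0) next # burst concentrates at k = 0: production is a no-op
      q <- b / (1 + b)
      kmax <- max(1, ceiling(log(burstTol) / log(q)))
      base <- states[act, , drop = FALSE] +
        rep(net@change[j, ], each = length(act))
      for (k in seq_len(kmax)) {
        w <- q^k / (1 + b) # P(k) = b^k / (1+b)^(k+1)
        dest <- base
        dest[, tgt] <- dest[, tgt] + k
        di <- .stateIndex(trunc, dest)
        ok <- !is.na(di)
        if (any(ok)) {
          ii <- c(ii, di[ok]); jj <- c(jj, act[ok])
          xx <- c(xx, w * a[act][ok])
        }
      }
      diagOut[act] <- diagOut[act] + a[act] * q # total jump prob 1 - P(0)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  A - Matrix::Diagonal(n, diagOut)
}

# delta distribution at a state
.deltaP0 <- function(trunc, init) {
  p0 <- numeric(nrow(trunc@states))
  idx <- .stateIndex(trunc, matrix(init, nrow = 1))
  if (is.na(idx)) stop("initial state outside truncation", call. = FALSE)
  p0[idx] <- 1
  p0
}

#' Propagate FSP probabilities
#'
#' Solves dp/dt = A(t) p on the truncation. Time-homogeneous generators
#' use the matrix exponential; with a \linkS4class{Signal} the generator
#' is split as A0 + f(t) A1 and integrated with a stiff solver (the
#' generator is re-weighted continuously through the signal interpolant).
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param params named parameter vector
#' @param trunc an \linkS4class{FSPTruncation}
#' @param p0 probability vector on the truncation (sum <= 1)
#' @param t0,t1 start / end times
#' @param sig optional \linkS4class{Signal}
#' @param rtol,atol integration tolerances (time-varying case)
#' @return probability vector at t1; attribute \code{massDefect} holds
#'   1 - sum(p)
#' @export
fspPropagate <- function(net, params, trunc, p0, t0, t1, sig = NULL,
                         rtol = 1e-9, atol = 1e-12) {
  stopifnot(sum(p0) <= 1 + 1e-9)
  if (t1 < t0) stop("t1 must be >= t0", call. = FALSE)
  if (t1 == t0) {
    attr(p0, "massDefect") <- 1 - sum(p0)
    return(p0)
  }
  if (is.null(sig) || !any(net@modulated)) {
    A <- fspGenerator(net, params, trunc)
    p <- as.numeric(Matrix::expm(A * (t1 - t0)) %*% p0)
  } else {
    A0 <- fspGenerator(net, params, trunc, which = "static")
    A1 <- fspGenerator(net, params, trunc, which = "modulated")
    rhs <- function(t, y, parms)
      list(as.numeric(A0 %*% y) + signalValue(sig, t) * as.numeric(A1 %*% y))
    sol <- deSolve::lsoda(y = p0, times = c(t0, t1), func = rhs,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("FSP integration failed; consider loosening tolerances",
           call. = FALSE)
    p <- as.numeric(sol[2, -1])
  }
  p <- pmax(p, 0)
  attr(p, "massDefect") <- 1 - sum(p)
  p
}

#' Marginal pmf of one species from an FSP probability vector
#'
#' Sums over all latent dimensions (e.g. promoter states); the output sums
#' to the total retained mass.
#'
#' @param p probability vector on the truncation
#' @param trunc an \linkS4class{FSPTruncation}
#' @param species species index or name
#' @return named numeric pmf over counts 0..bound
#' @export
fspMarginal <- function(p, trunc, species) {
  s <- if (is.character(species)) match(species, trunc@species) else species
  counts <- trunc@states[, s]
  out <- numeric(trunc@bounds[s] + 1)
  agg <- tapply(as.numeric(p), counts, sum)
  out[as.integer(names(agg)) + 1] <- agg
  names(out) <- 0:trunc@bounds[s]
  out
}

# map each state to an integer key of its observed-species tuple
.obsKeys <- function(trunc, obsIdx) {
  b <- trunc@bounds[obsIdx]
  radix <- cumprod(c(1, b[-length(b)] + 1))
  as.numeric(trunc@states[, obsIdx, drop = FALSE] %*% radix)
}

.obsKeyOf <- function(obs, bounds) {
  radix <- cumprod(c(1, bounds[-length(bounds)] + 1))
  as.numeric(obs %*% radix)
}

#' Exact time-series log-likelihood of one cell by FSP filtering
#'
#' Recursive Bayesian filtering: propagate the distribution to each
#' observation time, weight by the probability mass on states consistent
#' with the observed counts (latent species are marginalized), condition
#' (zero out inconsistent states and renormalize), and accumulate log
#' weights.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param params named parameter vector
#' @param trunc an \linkS4class{FSPTruncation}
#' @param times observation times
#' @param obs T x S matrix (or length-T vector) of observed counts
#' @param sig optional \linkS4class{Signal}
#' @param init initial state (delta initial distribution)
#' @return log-likelihood (-Inf with a warning if an observation has no
#'   support inside the truncation)
#' @export
fspFilterLoglik <- function(net, params, trunc, times, obs, sig = NULL,
                            init = net@init) {
  obs <- .seqMatrix(obs, length(times), length(net@observed))
  data <- snapshotDataset(array(obs, c(1, dim(obs))), times,
                          net@species[net@observed], correlated = TRUE)
  fspDatasetLoglik(net, params, data, trunc = trunc, sig = sig, init = init)
}

#' Exact dataset log-likelihood by FSP
#'
#' Correlated datasets: sum over cells of the filtering log-likelihood
#' (transition operators over the unique inter-observation gaps are built
#' once and reused across cells). Independent snapshots: the distribution
#' is propagated once and the joint marginal pmf of the observed species
#' is evaluated per (cell, time).
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param params named parameter vector
#' @param data a \linkS4class{SnapshotDataset} over the observed species
#' @param trunc an \linkS4class{FSPTruncation}; NULL triggers
#'   \code{\link{fspAutoTruncate}}
#' @param sig optional \linkS4class{Signal}
#' @param init initial state
#' @param t0 initial time
#' @return total log-likelihood
#' @export
fspDatasetLoglik <- function(net, params, data, trunc = NULL, sig = NULL,
                             init = net@init, t0 = 0) {
  if (is.null(trunc))
    trunc <- fspAutoTruncate(net, params, data@times, data = data,
                             sig = sig, init = init)
  obsIdx <- net@observed
  arr <- data@counts
  C <- dim(arr)[1]; T <- dim(arr)[2]; S <- dim(arr)[3]
  bObs <- trunc@bounds[obsIdx]
  stateKey <- .obsKeys(trunc, obsIdx)
  keyGroups <- split(seq_along(stateKey), stateKey)
  obsKey <- matrix(0, C, T)
  outside <- matrix(FALSE, C, T)
  for (t in seq_len(T)) {
    ot <- matrix(arr[, t, ], C, S)
    outside[, t] <- rowSums(ot > rep(bObs, each = C)) > 0
    obsKey[, t] <- .obsKeyOf(ot, bObs)
  }
  if (any(outside))
    warning("observations outside the truncation: contributing -Inf")
  p0 <- .deltaP0(trunc, init)
  times <- data@times

  if (!data@correlated) {
    # snapshots: propagate once, evaluate the joint observed-species pmf
    ll <- 0
    p <- p0; tprev <- t0
    for (t in seq_len(T)) {
      p <- fspPropagate(net, params, trunc, p, tprev, times[t], sig)
      tprev <- times[t]
      pmf <- rowsum(as.numeric(p), stateKey)
      hit <- match(as.character(obsKey[, t]), rownames(pmf))
      w <- ifelse(is.na(hit) | outside[, t], 0, pmf[hit])
      if (any(w <= 0)) {
        warning("observation with zero FSP support; log-likelihood -Inf")
        return(-Inf)
      }
      ll <- ll + sum(log(w))
    }
    return(ll)
  }

  # time series: per-cell filtering; transition operators cached per gap
  A <- NULL
  cache <- new.env(parent = emptyenv())
  step <- function(M, ta, tb) {
    if (is.null(sig) || !any(net@modulated)) {
      key <- sprintf("%.15g", tb - ta)
      if (is.null(cache[[key]])) {
        if (is.null(A)) A <<- fspGenerator(net, params, trunc)
        cache[[key]] <- Matrix::expm(A * (tb - ta))
      }
      as.matrix(cache[[key]] %*% M)
    } else {
      n <- nrow(M)
      A0 <- if (is.null(cache$A0)) cache$A0 <- fspGenerator(net, params, trunc, "static") else cache$A0
      A1 <- if (is.null(cache$A1)) cache$A1 <- fspGenerator(net, params, trunc, "modulated") else cache$A1
      rhs <- function(tt, y, parms) {
        Y <- matrix(y, n)
        list(as.numeric(A0 %*% Y + signalValue(sig, tt) * (A1 %*% Y)))
      }
      sol <- deSolve::lsoda(y = as.numeric(M), times = c(ta, tb), func = rhs,
                            rtol = 1e-9, atol = 1e-12)
      matrix(pmax(sol[2, -1], 0), n)
    }
  }
  M <- matrix(p0, nrow = length(p0), ncol = C)
  ll <- numeric(C)
  tprev <- t0
  for (t in seq_len(T)) {
    M <- step(M, tprev, times[t])
    tprev <- times[t]
    for (ci in seq_len(C)) {
      if (!is.finite(ll[ci])) next
      rows <- keyGroups[[as.character(obsKey[ci, t])]]
      w <- if (is.null(rows) || outside[ci, t]) 0 else sum(M[rows, ci])
      if (w <= 0) {
        ll[ci] <- -Inf
        M[, ci] <- 0
      } else {
        ll[ci] <- ll[ci] + log(w)
        keepv <- numeric(nrow(M))
        keepv[rows] <- M[rows, ci] / w
        M[, ci] <- keepv
      }
    }
  }
  if (any(!is.finite(ll)))
    warning("cell(s) with zero FSP support; total log-likelihood -Inf")
  sum(ll)
}

#' Automatic FSP truncation sizing
#'
#' Starts from the largest observed count plus 50\% headroom per count
#' species (or a floor of 20) and doubles the bounds until the mass defect
#' at the final queried time drops below \code{defectTol}.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param params named parameter vector
#' @param times observation times (defect checked at the last one)
#' @param data optional \linkS4class{SnapshotDataset} providing observed
#'   maxima
#' @param sig optional \linkS4class{Signal}
#' @param init initial state
#' @param defectTol target mass defect
#' @param cap cap on the number of states
#' @return an \linkS4class{FSPTruncation}
#' @export
fspAutoTruncate <- function(net, params, times, data = NULL, sig = NULL,
                            init = net@init, defectTol = 1e-8, cap = 1e6) {
  S <- length(net@species)
  bounds <- rep(20, S)
  if (!is.null(data)) {
    mx <- apply(data@counts, 3, max)
    bounds[net@observed] <- pmax(ceiling(mx * 1.5), 20)
  }
  hint <- !is.na(net@maxHints)
  bounds[hint] <- net@maxHints[hint]
  for (iter in 1:20) {
    trunc <- fspTruncation(net, bounds, init = init, cap = cap)
    p <- fspPropagate(net, params, trunc, .deltaP0(trunc, init), 0,
                      max(times), sig)
    if (attr(p, "massDefect") < defectTol) return(trunc)
    grow <- net@kinds == "count"
    bounds[grow] <- bounds[grow] * 2
  }
  stop("FSP auto-truncation failed to reach the target mass defect",
       call. = FALSE)
}

#' Solve the FSP over a time grid
#'
#' Convenience wrapper returning the full \linkS4class{FSPSolution}
#' (probability vectors and mass defects at each requested time).
#'
#' @inheritParams fspAutoTruncate
#' @param trunc an \linkS4class{FSPTruncation} (auto-sized when NULL)
#' @return an \linkS4class{FSPSolution}
#' @export
fspSolve <- function(net, params, times, trunc = NULL, sig = NULL,
                     init = net@init) {
  if (is.null(trunc))
    trunc <- fspAutoTruncate(net, params, times, sig = sig, init = init)
  p <- .deltaP0(trunc, init)
  probs <- matrix(0, nrow(trunc@states), length(times))
  defect <- numeric(length(times))
  tprev <- 0
  for (i in seq_along(times)) {
    p <- fspPropagate(net, params, trunc, p, tprev, times[i], sig)
    tprev <- times[i]
    probs[, i] <- p
    defect[i] <- attr(p, "massDefect")
  }
  new("FSPSolution", truncation = trunc, probs = probs, times = times,
      massDefect = defect)
}
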