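## Raw-moment equations of the CME for networks with affine propensities,
## d<x^a>/dt = sum_r <a_r(x) ((x + s_r)^a - x^a)>, expanded symbolically
## over the monomial basis up to a chosen order (default 4: the sample-
## moment covariances of moment-based inference need fourth moments).
## Geometric bursts contribute the raw moments of the jump distribution.
## The linear mapping approximation (LMA) converts protein-promoter
## binding into an effective first-order reaction so these equations close.

# ---- sparse polynomials over S variables: named coefficient vectors ----
.mkey <- function(alpha) paste(alpha, collapse = ".")
.mparse <- function(key) as.integer(strsplit(key, ".", fixed = TRUE)[[1]])

.padd <- function(p, key, coef) {
  p[key] <- (if (key %in% names(p)) p[[key]] else 0) + coef
  p
}

.pmul <- function(p1, p2, S) {
  out <- numeric(0)
  for (k1 in names(p1)) for (k2 in names(p2)) {
    a <- .mparse(k1) + .mparse(k2)
    out <- .padd(out, .mkey(a), p1[[k1]] * p2[[k2]])
  }
  out
}

.pconst <- function(c, S) setNames(c, .mkey(integer(S)))

# univariate factor as a polynomial in species s: falling factorial or 1-x
.pfactor <- function(S, s, order = 0L, comp = 0L) {
  p <- .pconst(1, S)
  e <- integer(S)
  if (order > 0) for (i in seq_len(order)) {
    e[s] <- 1L
    term <- setNames(c(-(i - 1), 1), c(.mkey(integer(S)), .mkey(e)))
    p <- .pmul(p, term, S)
  }
  if (comp > 0) {
    e <- integer(S); e[s] <- 1L
    term <- setNames(c(1, -1), c(.mkey(integer(S)), .mkey(e)))
    for (i in seq_len(comp)) p <- .pmul(p, term, S)
  }
  p
}

# propensity polynomial of reaction j (signal factor excluded)
.propPoly <- function(net, j, rate) {
  S <- length(net@species)
  p <- .pconst(rate, S)
  for (s in seq_len(S)) {
    o <- net@orders[j, s]; cm <- net@compOrders[j, s]
    if (o > 0 || cm > 0) p <- .pmul(p, .pfactor(S, s, o, cm), S)
  }
  p
}

# raw moments E[k^i], i = 0..n, of the geometric burst with mean b:
# factorial moments are i! b^i, converted with Stirling numbers 2nd kind
.geomRawMoments <- function(b, n) {
  S2 <- matrix(0, n + 1, n + 1)
  S2[1, 1] <- 1
  if (n >= 1) for (i in 1:n) for (j in 1:i)
    S2[i + 1, j + 1] <- (if (j <= i - 1) j * S2[i, j + 1] else 0) +
      (if (j - 1 <= i - 1) S2[i, j] else 0)
  vapply(0:n, function(i)
    sum(S2[i + 1, 1:(i + 1)] * factorial(0:i) * b^(0:i)), numeric(1))
}

# polynomial E_k[(x + d + k e_tgt)^alpha - x^alpha]
.jumpPoly <- function(alpha, d, tgt, kmom) {
  S <- length(alpha)
  p <- .pconst(1, S)
  for (s in seq_len(S)) {
    as_ <- alpha[s]
    if (as_ == 0) next
    fac <- numeric(0)
    for (m in 0:as_) {
      e <- integer(S); e[s] <- m
      cc <- 0
      pw <- as_ - m
      if (!is.na(tgt) && s == tgt) {
        # E[(d + k)^pw]
        for (i in 0:pw) cc <- cc + choose(pw, i) * d[s]^(pw - i) * kmom[i + 1]
      } else cc <- d[s]^pw
      fac <- .padd(fac, .mkey(e), choose(as_, m) * cc)
    }
    p <- .pmul(p, fac, S)
  }
  .padd(p, .mkey(alpha), -1)
}

# monomial multi-indices with 0 <= |alpha| <= order (constant first)
.monomials <- function(S, order) {
  grid <- as.matrix(expand.grid(rep(list(0:order), S)))
  grid <- grid[rowSums(grid) <= order, , drop = FALSE]
  grid[order(rowSums(grid), apply(grid, 1, .mkey)), , drop = FALSE]
}

#' Moment equations for affine-propensity networks
#'
#' Builds the closed linear ODE system for all raw moments up to
#' \code{order}: coefficient matrices A0 (static reactions) and A1
#' (signal-modulated reactions, unit signal) such that
#' dm/dt = (A0 + f(t) A1) m over the monomial vector m (whose first entry
#' is the constant 1). Zero-rate reactions are skipped; any remaining
#' propensity of degree above one is a contract error (apply
#' \code{\link{lmaLinearize}} first).
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param params named parameter vector
#' @param order maximum moment order (default 4)
#' @return list with \code{monomials} (matrix), \code{A0}, \code{A1}
#' @export
momentEquations <- function(net, params, order = 4L) {
  S <- length(net@species)
  rates <- .rateValues(net, params)
  bmeans <- .burstMeans(net, params)
  mono <- .monomials(S, order)
  keys <- apply(mono, 1, .mkey)
  M <- nrow(mono)
  A0 <- matrix(0, M, M, dimnames = list(keys, keys))
  A1 <- A0
  for (j in seq_len(nrow(net@change))) {
    if (rates[j] == 0) next
    pp <- .propPoly(net, j, rates[j])
    deg <- max(vapply(names(pp), function(k) sum(.mparse(k)), numeric(1)))
    if (deg > 1)
      stop("propensity of reaction ", j, " is not affine; ",
           "linearize first (LMA)", call. = FALSE)
    tgt <- net@burstTarget[j]
    kmom <- if (!is.na(tgt)) .geomRawMoments(bmeans[j], order) else NULL
    Amat <- if (net@modulated[j]) "A1" else "A0"
    for (i in 2:M) { # skip the constant monomial (its derivative is 0)
      alpha <- mono[i, ]
      jp <- .jumpPoly(alpha, net@change[j, ], tgt, kmom)
      poly <- .pmul(pp, jp, S)
      for (k in names(poly)) {
        if (abs(poly[[k]]) < 1e-300) next
        if (!k %in% keys)
          stop("moment system not closed at order ", order, call. = FALSE)
        if (Amat == "A0") A0[i, k] <- A0[i, k] + poly[[k]]
        else A1[i, k] <- A1[i, k] + poly[[k]]
      }
    }
  }
  list(monomials = mono, keys = keys, A0 = A0, A1 = A1, species = net@species)
}

# evaluate all monomials at a deterministic state
.monomialInit <- function(ms, init) {
  apply(ms$monomials, 1, function(a) prod(as.numeric(init)^a))
}

#' Solve moment equations over a time grid
#'
#' @param ms a system from \code{\link{momentEquations}}
#' @param init deterministic initial state (moments of a delta measure)
#' @param times increasing output times (0 is prepended internally)
#' @param sig optional \linkS4class{Signal} for modulated reactions
#' @return matrix times x monomials of raw moments (named columns)
#' @export
solveMoments <- function(ms, init, times, sig = NULL) {
  m0 <- .monomialInit(ms, init)
  rhs <- function(t, y, parms) {
    dy <- ms$A0 %*% y
    if (!is.null(sig)) dy <- dy + signalValue(sig, t) * (ms$A1 %*% y)
    list(as.numeric(dy))
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(y = m0, times = tt, func = rhs, rtol = 1e-10,
                        atol = 1e-12, maxsteps = 50000)
  out <- sol[match(times, tt), -1, drop = FALSE]
  out <- matrix(out, length(times), length(m0))
  colnames(out) <- ms$keys
  out
}

#' Stationary raw moments of an affine network
#'
#' Long-time integration of the moment ODEs from a given initial state
#' (a direct linear solve is singular whenever the network carries
#' conservation laws, whose conserved totals are fixed by the initial
#' state; integration respects them automatically). The horizon is doubled
#' until the moments stop changing.
#'
#' @param ms a system from \code{\link{momentEquations}}
#' @param init deterministic initial state
#' @param tMax starting integration horizon (in units of the reference
#'   degradation rate)
#' @param tol relative stationarity tolerance
#' @return named vector of stationary raw moments
#' @export
stationaryMoments <- function(ms, init, tMax = 60, tol = 1e-6) {
  for (i in 1:8) {
    m <- solveMoments(ms, init, c(tMax, 2 * tMax))
    if (all(abs(m[2, ] - m[1, ]) <= tol * abs(m[1, ]) + 1e-8))
      return(setNames(m[2, ], ms$keys))
    tMax <- tMax * 2
  }
  stop("moments did not reach stationarity; system may be unstable",
       call. = FALSE)
}

#' Linear mapping approximation (LMA)
#'
#' Replaces each bimolecular promoter-protein binding reaction
#' G + P -> ... (propensity sigma g p) by an effective first-order reaction
#' with propensity sigma <P | G = 1> g, keeping the full stoichiometry. The
#' conditional mean <P | G = 1> = E[P G] / E[G] is determined
#' self-consistently by fixed-point iteration on the stationary moments of
#' the linearized network.
#'
#' @param net a \linkS4class{ReactionNetwork} whose only bimolecular
#'   reactions are promoter-protein binding
#' @param theta named parameter vector
#' @param tol relative fixed-point tolerance
#' @param maxIter iteration cap
#' @return list with \code{net} (linearized network, effective rates
#'   embedded as literal constants), \code{effectiveRates},
#'   \code{iterations} and the fixed-point \code{trace}
#' @export
lmaLinearize <- function(net, theta, tol = 1e-8, maxIter = 100L) {
  rates <- .rateValues(net, theta)
  S <- length(net@species)
  bind <- integer(0); gIdx <- integer(0); pIdx <- integer(0)
  for (j in seq_len(nrow(net@change))) {
    tot <- sum(net@orders[j, ]) + sum(net@compOrders[j, ])
    if (tot <= 1) next
    act <- which(net@orders[j, ] == 1)
    if (sum(net@orders[j, ]) == 2 && length(act) == 2 &&
        sum(net@compOrders[j, ]) == 0) {
      g <- act[net@kinds[act] == "promoter-state"]
      p <- act[net@kinds[act] == "count"]
      if (length(g) == 1 && length(p) == 1 && rates[j] > 0) {
        bind <- c(bind, j); gIdx <- c(gIdx, g); pIdx <- c(pIdx, p)
        next
      }
    }
    if (rates[j] > 0)
      stop("non-binding bimolecular reaction: LMA not applicable",
           call. = FALSE)
  }
  if (!length(bind))
    return(list(net = net, effectiveRates = numeric(0), iterations = 0L,
                trace = list()))
  linearize <- function(pbar) {
    out <- net
    for (i in seq_along(bind)) {
      j <- bind[i]
      out@orders[j, pIdx[i]] <- 0L
      out@rateParams[j] <- as.character(rates[j] * pbar[i])
    }
    out
  }
  pbar <- rep(1, length(bind))
  trace <- list()
  for (it in seq_len(maxIter)) {
    lnet <- linearize(pbar)
    ms <- momentEquations(lnet, theta, order = 2L)
    m <- stationaryMoments(ms, net@init)
    pnew <- vapply(seq_along(bind), function(i) {
      eG <- integer(S); eG[gIdx[i]] <- 1L
      eGP <- eG; eGP[pIdx[i]] <- eGP[pIdx[i]] + 1L
      max(m[[.mkey(eGP)]] / max(m[[.mkey(eG)]], 1e-12), 0)
    }, numeric(1))
    trace[[it]] <- pnew
    if (all(abs(pnew - pbar) <= tol * (abs(pbar) + 1e-12))) {
      return(list(net = linearize(pnew), effectiveRates = rates[bind] * pnew,
                  iterations = it, trace = trace))
    }
    pbar <- pnew
  }
  stop("LMA fixed point not reached after ", maxIter, " iterations",
       call. = FALSE)
}
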