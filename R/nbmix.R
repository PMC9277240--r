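## Negative-binomial mixtures: pmf, sampling, and maximum-likelihood
## fitting by EM (the surrogate-fitting step: maximizing the sample
## likelihood, i.e. minimizing KL divergence to the empirical simulation
## distribution). Internal parameterization is (r, p); users mostly see
## (mean, Fano factor) through the accessors.

#' Construct a negative-binomial mixture
#'
#' @param weights mixture weights (normalized if needed)
#' @param r component dispersions
#' @param p component success probabilities; alternatively supply
#'   \code{means} and r (then \code{p = r / (r + mean)})
#' @param means optional component means instead of \code{p}
#' @return an \linkS4class{NBMixture}
#' @export
nbMixture <- function(weights, r, p = NULL, means = NULL) {
  if (is.null(p)) {
    if (is.null(means)) stop("supply p or means")
    p <- r / (r + means)
  }
  new("NBMixture", weights = weights / sum(weights), r = r, p = p)
}

#' Negative binomial log-pmf
#'
#' \eqn{\log[\Gamma(x+r) / (\Gamma(r) x!) \, p^r (1-p)^x]}, computed via
#' log-gamma for numerical stability. With r = 1 this is the geometric
#' distribution; as r grows at fixed mean it approaches Poisson.
#'
#' @param x nonnegative integer counts
#' @param r dispersion (> 0)
#' @param p success probability in (0, 1)
#' @return log-probabilities
#' @export
nbLogpmf <- function(x, r, p) {
  if (any(r <= 0) || any(p <= 0) || any(p >= 1))
    stop("r must be > 0 and p in (0,1)", call. = FALSE)
  if (any(x < 0) || any(x != round(x)))
    stop("x must be nonnegative integers", call. = FALSE)
  dnbinom(x, size = r, prob = p, log = TRUE)
}

#' Mixture of negative binomials log-pmf
#'
#' Log-sum-exp over components of log weight + component log-pmf.
#'
#' @param x nonnegative integer counts
#' @param mix an \linkS4class{NBMixture}
#' @return log-probabilities
#' @export
mnbLogpmf <- function(x, mix) {
  K <- length(mix@weights)
  lp <- vapply(seq_len(K), function(k)
    log(mix@weights[k]) + nbLogpmf(x, mix@r[k], mix@p[k]),
    numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

#' Sample counts from an NB mixture
#'
#' @param mix an \linkS4class{NBMixture}
#' @param n number of draws
#' @param seed RNG seed
#' @return integer counts of length n
#' @export
sampleMNB <- function(mix, n, seed) {
  if (n == 0) return(integer(0))
  .withSeed(seed, {
    k <- sample.int(length(mix@weights), n, replace = TRUE,
                    prob = mix@weights)
    rnbinom(n, size = mix@r[k], prob = mix@p[k])
  })
}

# quantile-based initialization: split sorted samples (by the given key)
# into K blocks and use block moments (method of moments, r clamped)
.quantileInit <- function(X, K, jitter = 0) {
  n <- nrow(X); S <- ncol(X)
  key <- X[, 1]
  ord <- order(key)
  blocks <- if (K == 1) list(ord)
            else split(ord, cut(seq_len(n), K, labels = FALSE))
  r0 <- matrix(1, K, S); p0 <- matrix(0.5, K, S)
  for (k in seq_len(K)) {
    idx <- blocks[[k]]
    for (s in seq_len(S)) {
      mu <- mean(X[idx, s])
      if (jitter > 0) mu <- mu * exp(rnorm(1, 0, jitter))
      v <- if (length(idx) > 1) var(X[idx, s]) else mu
      mu <- max(mu, 1e-3)
      r <- if (is.na(v) || v <= mu) 1e4 else mu^2 / (v - mu)
      r0[k, s] <- min(max(r, 1e-3), 1e4)
      p0[k, s] <- r0[k, s] / (r0[k, s] + mu)
    }
  }
  list(w = rep(1 / K, K), r = r0, p = p0)
}

# merge components whose means all but coincide (relative difference
# below `tol`); extraneous components then show up as merged weight
.mergeComponents <- function(w, r, p, tol = 1e-6) {
  K <- length(w)
  if (K == 1) return(list(w = w, r = r, p = p))
  mu <- r * (1 - p) / p
  keep <- rep(TRUE, K)
  for (k in 2:K) for (j in 1:(k - 1)) {
    if (keep[j] && keep[k] &&
        all(abs(mu[k, ] - mu[j, ]) <= tol * (abs(mu[j, ]) + 1e-12))) {
      w[j] <- w[j] + w[k]
      keep[k] <- FALSE
      break
    }
  }
  list(w = w[keep] / sum(w[keep]), r = r[keep, , drop = FALSE],
       p = p[keep, , drop = FALSE])
}

# EM for K-component product-NB mixtures on an n x S count matrix;
# shared by fitMNBEM (S = 1) and the per-time fits of the synthetic
# likelihood in independent-MNB mode (S >= 1).
.fitProductMNB <- function(X, K, tol = 1e-8, maxIter = 500L, nRestarts = 3L,
                           weightFloor = 1e-6, seed = 1L, merge = TRUE) {
  if (!nrow(X)) stop("samples must be nonempty", call. = FALSE)
  if (any(X < 0) || any(X != round(X)))
    stop("samples must be nonnegative integers", call. = FALSE)
  storage.mode(X) <- "double"
  best <- NULL
  for (rs in seq_len(nRestarts)) {
    init <- if (rs == 1) .quantileInit(X, K)
            else .withSeed(.childSeed(seed, rs), .quantileInit(X, K, 0.3))
    fit <- .cpp_mnb_em(X, init$w, init$r, init$p, as.integer(maxIter), tol,
                       weightFloor)
    if (is.null(best) || max(fit$trace) > max(best$trace)) best <- fit
  }
  if (merge) {
    m <- .mergeComponents(best$weights, best$r, best$p)
    best$weights <- m$w; best$r <- m$r; best$p <- m$p
  }
  best
}

#' Fit an NB mixture by expectation-maximization
#'
#' Maximum-likelihood fit of a K-component negative-binomial mixture to
#' count samples: E-step responsibilities, M-step mixture weights plus
#' weighted NB maximum likelihood per component (p from the weighted mean
#' identity given r, r by safeguarded Newton on the profile score). The
#' returned \code{trace} of sample log-likelihoods is nondecreasing (EM
#' guarantee). Initialization is quantile-based with randomized restarts;
#' the best restart is returned. Components whose fitted means coincide
#' are merged, so extraneous components are absorbed.
#'
#' @param samples nonnegative integer counts
#' @param K number of components
#' @param tol relative log-likelihood convergence tolerance
#' @param maxIter iteration cap
#' @param nRestarts number of EM restarts (first uses the plain quantile
#'   start, the rest perturbed starts)
#' @param weightFloor lower bound on mixture weights
#' @param seed RNG seed for the restarts
#' @return list with \code{mixture} (an \linkS4class{NBMixture}) and
#'   \code{trace} (the log-likelihood trace of the best restart)
#' @export
fitMNBEM <- function(samples, K, tol = 1e-8, maxIter = 500L, nRestarts = 3L,
                     weightFloor = 1e-6, seed = 1L) {
  X <- matrix(as.numeric(samples), ncol = 1)
  fit <- .fitProductMNB(X, K, tol, maxIter, nRestarts, weightFloor, seed)
  mix <- new("NBMixture", weights = fit$weights / sum(fit$weights),
             r = as.numeric(fit$r), p = as.numeric(fit$p))
  list(mixture = mix, trace = fit$trace)
}

#' Serialize / deserialize an NB mixture as JSON
#'
#' Stored user-facing as (weight, mean, fano) triples.
#' @param mix an \linkS4class{NBMixture}
#' @param path file path
#' @return \code{readMixtureJSON} returns an \linkS4class{NBMixture}
#' @export
writeMixtureJSON <- function(mix, path) {
  mu <- nbMeans(mix)
  jsonlite::write_json(
    list(weights = mix@weights, means = mu, fano = fanoFactors(mix)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeMixtureJSON
#' @export
readMixtureJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- o$means
  r <- mu / (o$fano - 1)
  nbMixture(o$weights, r = r, means = mu)
}
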