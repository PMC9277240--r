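## The synthetic model proper: a finite-state HMM over the observation grid
## with negative-binomial emissions per (time, state, species), fitted by
## Baum-Welch to simulated trajectories and evaluated with the scaled
## forward algorithm. Time-inhomogeneous by default (per-time emissions,
## per-interval transitions); tied variants behind config flags.

#' Construct an NB-emission HMM
#'
#' @param pi initial distribution over hidden states
#' @param trans (T-1) x K x K array of row-stochastic transition matrices;
#'   may be a single K x K matrix (replicated) or NULL when T = 1
#' @param r,p T x K x S arrays of NB emission parameters (K x ... matrices
#'   are promoted for T = 1, S = 1 conveniences)
#' @param times optional observation times
#' @param species observed species names
#' @return an \linkS4class{NBHMM}
#' @export
nbhmm <- function(pi, trans, r, p, times = numeric(0), species = NULL) {
  if (is.matrix(r)) r <- array(r, c(dim(r), 1))
  if (is.matrix(p)) p <- array(p, c(dim(p), 1))
  T <- dim(r)[1]; K <- length(pi); S <- dim(r)[3]
  if (is.null(trans)) trans <- array(0, c(max(T - 1, 0), K, K))
  if (is.matrix(trans)) {
    trans <- array(rep(trans, each = T - 1), c(T - 1, K, K))
  }
  if (is.null(species)) species <- paste0("X", seq_len(S))
  new("NBHMM", pi = pi / sum(pi), trans = trans, r = r, p = p,
      times = times, species = species)
}

# coerce one cell's observations to a T x S matrix
.seqMatrix <- function(x, T, S) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (!all(dim(x) == c(T, S)))
    stop(sprintf("sequence must be %d times x %d species", T, S),
         call. = FALSE)
  x
}

#' Forward-algorithm log-likelihood under an NB-HMM
#'
#' Scaled forward recursion (per-step normalization, accumulating log scale
#' factors): exact marginalization over hidden state paths. For K = 1 this
#' is a sum of NB log-pmfs; for T = 1 it is the mixture log-pmf under
#' (pi, emissions).
#'
#' @param hmm an \linkS4class{NBHMM}
#' @param x one cell's counts (length-T vector or T x S matrix), or a
#'   \linkS4class{SnapshotDataset} on the same grid
#' @return scalar log-likelihood, or a per-cell vector for a dataset
#' @export
forwardLoglik <- function(hmm, x) {
  d <- dim(hmm@r)
  if (is(x, "SnapshotDataset")) {
    arr <- x@counts
    storage.mode(arr) <- "double"
    return(as.numeric(.cpp_forward_loglik(arr, hmm@pi, hmm@trans, hmm@r,
                                          hmm@p)))
  }
  m <- .seqMatrix(x, d[1], d[3])
  arr <- array(as.double(m), c(1, d[1], d[3]))
  as.numeric(.cpp_forward_loglik(arr, hmm@pi, hmm@trans, hmm@r, hmm@p))
}

# per-time quantile init aligned across times (blocks sorted by mean)
.hmmInit <- function(arr, K, jitter = 0) {
  T <- dim(arr)[2]; S <- dim(arr)[3]
  r0 <- array(1, c(T, K, S)); p0 <- array(0.5, c(T, K, S))
  for (t in seq_len(T)) {
    qi <- .quantileInit(matrix(arr[, t, ], ncol = S), K, jitter)
    r0[t, , ] <- qi$r
    p0[t, , ] <- qi$p
  }
  trans0 <- array(0, c(max(T - 1, 0), K, K))
  if (T > 1) for (t in seq_len(T - 1))
    trans0[t, , ] <- 0.8 * diag(K) + 0.2 / K
  list(pi = rep(1 / K, K), trans = trans0, r = r0, p = p0)
}

#' Fit an NB-emission HMM by Baum-Welch
#'
#' EM for hidden Markov models: forward-backward responsibilities and
#' pairwise transition posteriors summed over cells (E-step); closed-form
#' initial distribution and per-interval transition rows plus weighted NB
#' emission updates per (time, state, species) (M-step). The log-likelihood
#' trace is nondecreasing. Several restarts with perturbed quantile-based
#' initializations mitigate local optima; the best restart is returned.
#'
#' @param data a \linkS4class{SnapshotDataset} (correlated) or an
#'   n x T x S count array; all cells share the time grid
#' @param K number of hidden states
#' @param tol relative log-likelihood convergence tolerance
#' @param maxIter iteration cap
#' @param nRestarts number of restarts
#' @param weightFloor floor on pi / transition-row entries
#' @param tiedTrans share one transition matrix across intervals
#' @param tiedEmis share emissions across time points
#' @param seed RNG seed for restart perturbations
#' @return list with \code{hmm} (an \linkS4class{NBHMM}), \code{trace},
#'   and \code{loglik} (final fitted log-likelihood)
#' @export
fitBaumWelch <- function(data, K, tol = 1e-6, maxIter = 200L,
                         nRestarts = 3L, weightFloor = 1e-6,
                         tiedTrans = FALSE, tiedEmis = FALSE, seed = 1L) {
  arr <- if (is(data, "SnapshotDataset")) data@counts else data
  times <- if (is(data, "SnapshotDataset")) data@times else numeric(0)
  species <- if (is(data, "SnapshotDataset")) data@speciesNames else NULL
  if (length(dim(arr)) != 3) stop("data must be cells x times x species")
  storage.mode(arr) <- "double"
  best <- NULL
  for (rs in seq_len(nRestarts)) {
    init <- if (rs == 1) .hmmInit(arr, K)
            else .withSeed(.childSeed(seed, rs), .hmmInit(arr, K, 0.3))
    fit <- .cpp_baum_welch(arr, init$pi, init$trans, init$r, init$p,
                           as.integer(maxIter), tol, weightFloor,
                           tiedTrans, tiedEmis)
    if (is.null(best) || max(fit$trace) > max(best$trace)) best <- fit
  }
  T <- dim(arr)[2]; S <- dim(arr)[3]
  hmm <- nbhmm(pi = as.numeric(best$pi),
               trans = array(best$trans, c(max(T - 1, 1), K, K))[seq_len(max(T - 1, 0)), , , drop = FALSE],
               r = array(best$r, c(T, K, S)), p = array(best$p, c(T, K, S)),
               times = times, species = species)
  list(hmm = hmm, trace = best$trace, loglik = max(best$trace))
}

#' Initialize an HMM from per-time NB mixtures
#'
#' Treats the mixture components at each time point as hidden states:
#' emissions come from the per-time mixtures with components matched
#' across times by sorted mean, the initial distribution is the first
#' mixture's weights, and transitions start at 0.8 I + 0.2 uniform.
#'
#' @param perTimeMixtures list of \linkS4class{NBMixture} (equal K)
#' @param times optional observation times
#' @return an \linkS4class{NBHMM}
#' @export
initHMMFromMNB <- function(perTimeMixtures, times = numeric(0)) {
  K <- length(perTimeMixtures[[1]]@weights)
  if (!all(vapply(perTimeMixtures, function(m) length(m@weights),
                  integer(1)) == K))
    stop("all mixtures must have the same number of components",
         call. = FALSE)
  T <- length(perTimeMixtures)
  r <- array(0, c(T, K, 1)); p <- array(0, c(T, K, 1))
  pi <- NULL
  for (t in seq_len(T)) {
    mix <- perTimeMixtures[[t]]
    ord <- order(nbMeans(mix))
    r[t, , 1] <- mix@r[ord]
    p[t, , 1] <- mix@p[ord]
    if (t == 1) pi <- mix@weights[ord]
  }
  trans <- if (T > 1) 0.8 * diag(K) + 0.2 / K else NULL
  nbhmm(pi = pi, trans = trans, r = r, p = p, times = times)
}

#' Ancestral sampling from an NB-HMM
#'
#' @param hmm an \linkS4class{NBHMM}
#' @param nCells number of cells
#' @param seed RNG seed
#' @return a \linkS4class{SnapshotDataset} (correlated)
#' @export
sampleHMM <- function(hmm, nCells, seed) {
  d <- dim(hmm@r); T <- d[1]; K <- d[2]; S <- d[3]
  .withSeed(seed, {
    z <- matrix(0L, nCells, T)
    z[, 1] <- sample.int(K, nCells, replace = TRUE, prob = hmm@pi)
    if (T > 1) for (t in 2:T) {
      for (k in seq_len(K)) {
        idx <- which(z[, t - 1] == k)
        if (length(idx))
          z[idx, t] <- sample.int(K, length(idx), replace = TRUE,
                                  prob = hmm@trans[t - 1, k, ])
      }
    }
    out <- array(0L, c(nCells, T, S))
    for (t in seq_len(T)) for (s in seq_len(S)) {
      out[, t, s] <- rnbinom(nCells, size = hmm@r[t, z[, t], s],
                             prob = hmm@p[t, z[, t], s])
    }
  })
  tm <- if (length(hmm@times)) hmm@times else seq_len(T)
  new("SnapshotDataset", counts = out, times = as.numeric(tm),
      speciesNames = hmm@species, correlated = TRUE)
}

#' Marginal NB mixture of an HMM at one time point
#'
#' Propagates the initial distribution through the interval transition
#' matrices; paired with that time's emissions the marginal is a mixture
#' of negative binomials (single observed species).
#'
#' @param hmm an \linkS4class{NBHMM} with one observed species
#' @param tIndex time index
#' @return an \linkS4class{NBMixture}
#' @export
hmmMarginal <- function(hmm, tIndex) {
  if (dim(hmm@r)[3] != 1)
    stop("marginal mixture defined for a single observed species",
         call. = FALSE)
  w <- hmm@pi
  if (tIndex > 1) for (t in seq_len(tIndex - 1)) w <- as.numeric(w %*% hmm@trans[t, , ])
  new("NBMixture", weights = w / sum(w), r = hmm@r[tIndex, , 1],
      p = hmm@p[tIndex, , 1])
}

#' Serialize / deserialize an NB-HMM as JSON
#' @param hmm an \linkS4class{NBHMM}
#' @param path file path
#' @return \code{readHMMJSON} returns an \linkS4class{NBHMM}
#' @export
writeHMMJSON <- function(hmm, path) {
  d <- dim(hmm@r)
  jsonlite::write_json(
    list(pi = hmm@pi, trans = hmm@trans, r = hmm@r, p = hmm@p,
         times = hmm@times, species = hmm@species, dim = d),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeHMMJSON
#' @export
readHMMJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(o$dim)
  nbhmm(pi = as.numeric(o$pi),
        trans = array(as.numeric(o$trans), c(max(d[1] - 1, 0), d[2], d[2])),
        r = array(as.numeric(o$r), d), p = array(as.numeric(o$p), d),
        times = as.numeric(o$times), species = as.character(o$species))
}
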