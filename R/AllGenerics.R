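#' @name accessors
#' @title Accessors for nbsynlik classes
#' @param object,x an object of the documented class
#' @param ... unused
#' @description Accessor functions are preferred over direct slot access.
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("obsTimes", function(object, ...) standardGeneric("obsTimes"))

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object, ...) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("isCorrelated", function(object, ...) standardGeneric("isCorrelated"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(object, ...) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(object, ...) standardGeneric("mixtureWeights"))

#' Component means of an NB mixture / HMM emission table
#' @rdname accessors
#' @export
setGeneric("nbMeans", function(object, ...) standardGeneric("nbMeans"))

#' Component Fano factors (variance / mean = 1 + mean/r)
#' @rdname accessors
#' @export
setGeneric("fanoFactors", function(object, ...) standardGeneric("fanoFactors"))

#' @rdname accessors
#' @export
setGeneric("draws", function(object, ...) standardGeneric("draws"))

#' @rdname accessors
#' @export
setGeneric("logLiks", function(object, ...) standardGeneric("logLiks"))

#' @rdname accessors
#' @export
setGeneric("acceptanceRate", function(object, ...) standardGeneric("acceptanceRate"))

#' @rdname accessors
#' @export
setGeneric("massDefect", function(object, ...) standardGeneric("massDefect"))

#' @rdname accessors
#' @export
setMethod("counts", "SnapshotDataset", function(object, ...) object@counts)

#' @rdname accessors
#' @export
setMethod("obsTimes", "SnapshotDataset", function(object, ...) object@times)

#' @rdname accessors
#' @export
setMethod("speciesNames", "SnapshotDataset", function(object, ...) object@speciesNames)

#' @rdname accessors
#' @export
setMethod("speciesNames", "ReactionNetwork", function(object, ...) object@species)

#' @rdname accessors
#' @export
setMethod("isCorrelated", "SnapshotDataset", function(object, ...) object@correlated)

#' @rdname accessors
#' @export
setMethod("nCells", "SnapshotDataset", function(object, ...) dim(object@counts)[1])

#' @rdname accessors
#' @export
setMethod("mixtureWeights", "NBMixture", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("nbMeans", "NBMixture", function(object, ...)
  object@r * (1 - object@p) / object@p)

#' @rdname accessors
#' @export
setMethod("fanoFactors", "NBMixture", function(object, ...)
  1 + (1 - object@p) / object@p)

#' @rdname accessors
#' @export
setMethod("nbMeans", "NBHMM", function(object, ...)
  object@r * (1 - object@p) / object@p)

#' @rdname accessors
#' @export
setMethod("draws", "Chain", function(object, ...) object@draws)

#' @rdname accessors
#' @export
setMethod("logLiks", "Chain", function(object, ...) object@logliks)

#' @rdname accessors
#' @export
setMethod("acceptanceRate", "Chain", function(object, ...) mean(object@accepted))

#' @rdname accessors
#' @export
setMethod("massDefect", "FSPSolution", function(object, ...) object@massDefect)

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork '%s': %d species, %d reactions\n",
              object@name, length(object@species), nrow(object@change)))
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  cat("  observed:", paste(object@species[object@observed], collapse = ", "), "\n")
  if (!is.na(object@feedback)) cat("  feedback regime:", object@feedback, "\n")
  invisible(NULL)
})

setMethod("show", "SnapshotDataset", function(object) {
  d <- dim(object@counts)
  cat(sprintf("SnapshotDataset: %d cells x %d times x %d species (%s)\n",
              d[1], d[2], d[3],
              if (object@correlated) "time-correlated" else "independent snapshots"))
  cat("  times:", paste(signif(object@times, 4), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "NBMixture", function(object) {
  cat(sprintf("NBMixture with %d component(s)\n", length(object@weights)))
  print(data.frame(weight = signif(object@weights, 4),
                   mean = signif(nbMeans(object), 4),
                   fano = signif(fanoFactors(object), 4)))
  invisible(NULL)
})

setMethod("show", "NBHMM", function(object) {
  d <- dim(object@r)
  cat(sprintf("NBHMM: %d hidden states, %d time points, %d species\n",
              d[2], d[1], d[3]))
  cat("  pi:", paste(signif(object@pi, 3), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "Chain", function(object) {
  cat(sprintf("Chain (%s): %d iterations, %d parameters, acceptance %.1f%%\n",
              object@method, nrow(object@draws), ncol(object@draws),
              100 * mean(object@accepted)))
  invisible(NULL)
})

setMethod("show", "PriorBox", function(object) {
  cat("PriorBox:\n")
  print(data.frame(lower = object@lower, upper = object@upper))
  invisible(NULL)
})

setMethod("show", "FSPSolution", function(object) {
  cat(sprintf("FSPSolution: %d states, %d times, max mass defect %.3g\n",
              nrow(object@probs), length(object@times), max(object@massDefect)))
  invisible(NULL)
})

#' Construct a uniform box prior
#'
#' @param lower,upper named numeric vectors of per-parameter bounds
#' @return a \linkS4class{PriorBox}
#' @examples
#' priorBox(c(rho = 0), c(rho = 10))
#' @export
priorBox <- function(lower, upper) {
  if (is.null(names(upper))) names(upper) <- names(lower)
  new("PriorBox", lower = lower, upper = upper[names(lower)])
}

#' Draw parameter sets uniformly from a box prior
#'
#' @param prior a \linkS4class{PriorBox}
#' @param n number of draws
#' @param seed RNG seed
#' @return n x P matrix of parameter draws (named columns)
#' @export
priorSample <- function(prior, n, seed) {
  P <- length(prior@lower)
  .withSeed(seed, {
    m <- matrix(runif(n * P), n, P)
  })
  out <- sweep(m, 2, prior@upper - prior@lower, "*")
  out <- sweep(out, 2, prior@lower, "+")
  colnames(out) <- names(prior@lower)
  out
}

#' Test whether parameters lie inside a box prior
#' @param prior a \linkS4class{PriorBox}
#' @param theta named parameter vector
#' @return logical
#' @export
inPrior <- function(prior, theta) {
  theta <- theta[names(prior@lower)]
  all(theta >= prior@lower & theta <= prior@upper)
}
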