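## Built-in reaction networks and propensity evaluation.
## Rate "parameters" that parse as numbers (e.g. "1") are literal constants,
## used for rates fixed by convention (dilution rescaled to 1) or fixed
## experimentally (toggle-switch translocation/degradation rates).

# internal reaction constructor: named vectors over `species`
.rxn <- function(species, change = NULL, orders = NULL, comp = NULL,
                 rate, burstTarget = NA_character_, burstMean = NA_character_,
                 modulated = FALSE) {
  vec <- function(x) {
    v <- setNames(integer(length(species)), species)
    if (!is.null(x)) v[names(x)] <- as.integer(x)
    v
  }
  list(change = vec(change), orders = vec(orders), comp = vec(comp),
       rate = rate, burstTarget = burstTarget, burstMean = burstMean,
       modulated = modulated)
}

# assemble a ReactionNetwork from a list of .rxn() reactions
.makeNetwork <- function(name, species, kinds, rxns, observed,
                         conservation = list(), init,
                         maxHints = rep(NA_real_, length(species)),
                         feedback = NA_character_) {
  R <- length(rxns)
  grab <- function(f) do.call(rbind, lapply(rxns, `[[`, f))
  bt <- vapply(rxns, function(r)
    if (is.na(r$burstTarget)) NA_integer_ else match(r$burstTarget, species),
    integer(1))
  new("ReactionNetwork",
      name = name, species = species, kinds = kinds, maxHints = maxHints,
      change = grab("change"), orders = grab("orders"), compOrders = grab("comp"),
      rateParams = vapply(rxns, `[[`, character(1), "rate"),
      burstTarget = bt,
      burstMeanParam = vapply(rxns, `[[`, character(1), "burstMean"),
      modulated = vapply(rxns, `[[`, logical(1), "modulated"),
      observed = vapply(observed, function(s) match(s, species), integer(1)),
      conservation = conservation, init = as.integer(init),
      feedback = feedback)
}

# resolve a parameter name to a value; numeric-literal names are constants
.paramValue <- function(name, params, what = "rate") {
  if (is.na(name)) return(NA_real_)
  if (name %in% names(params)) return(unname(params[[name]]))
  v <- suppressWarnings(as.numeric(name))
  if (!is.na(v)) return(v)
  stop(sprintf("missing %s parameter '%s'", what, name), call. = FALSE)
}

.rateValues <- function(net, params)
  vapply(net@rateParams, .paramValue, numeric(1), params = params)

.burstMeans <- function(net, params)
  vapply(net@burstMeanParam, function(nm)
    if (is.na(nm)) 0 else .paramValue(nm, params, "burst-mean"),
    numeric(1))

.checkParams <- function(params, required) {
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(params < 0)) stop("parameters must be nonnegative", call. = FALSE)
  invisible(TRUE)
}

#' Autoregulatory genetic feedback loop
#'
#' A gene with two promoter states (unbound \code{Gu}, bound \code{Gb}) and
#' a protein \code{P} produced in geometrically distributed bursts with mean
#' \code{b}, at rate \code{rho_u} (unbound) or \code{rho_b} (bound). A
#' protein molecule binds the promoter at rate \code{sigma_b} (bimolecular)
#' and unbinds at rate \code{sigma_u}, releasing the protein. Protein
#' dilution has rate 1: all rates are in units of the dilution rate. The
#' observed species is \code{P}.
#'
#' @param params named vector with \code{rho_u, rho_b, sigma_b, sigma_u, b}
#' @return a \linkS4class{ReactionNetwork}; the feedback slot is tagged
#'   \code{"negative"} when \code{rho_b < rho_u} (production drops upon
#'   binding) and \code{"positive"} when \code{rho_b > rho_u}
#' @examples
#' net <- buildAutoreg(c(rho_u = 5, rho_b = 0, sigma_b = 0.05,
#'                       sigma_u = 1, b = 2))
#' @export
buildAutoreg <- function(params) {
  .checkParams(params, c("rho_u", "rho_b", "sigma_b", "sigma_u", "b"))
  sp <- c("Gu", "Gb", "P")
  rxns <- list(
    .rxn(sp, orders = c(Gu = 1), rate = "rho_u",
         burstTarget = "P", burstMean = "b"),
    .rxn(sp, orders = c(Gb = 1), rate = "rho_b",
         burstTarget = "P", burstMean = "b"),
    .rxn(sp, change = c(Gu = -1, Gb = 1, P = -1),
         orders = c(Gu = 1, P = 1), rate = "sigma_b"),
    .rxn(sp, change = c(Gu = 1, Gb = -1, P = 1),
         orders = c(Gb = 1), rate = "sigma_u"),
    .rxn(sp, change = c(P = -1), orders = c(P = 1), rate = "1")
  )
  fb <- if (params[["rho_b"]] < params[["rho_u"]]) "negative"
        else if (params[["rho_b"]] > params[["rho_u"]]) "positive"
        else NA_character_
  .makeNetwork("autoreg", sp, c("promoter-state", "promoter-state", "count"),
               rxns, observed = "P",
               conservation = list(list(species = 1:2, total = 1)),
               init = c(1L, 0L, 0L), maxHints = c(1, 1, NA), feedback = fb)
}

#' Two-gene toggle switch in a eukaryotic cell
#'
#' Two promoters, each either free or bound; the nuclear protein of each
#' gene represses the other by binding (and being sequestered at) the
#' opposing promoter. Transcription occurs only from free promoters;
#' nuclear mRNA is exported to the cytoplasm, translated there, and the
#' protein translocates to the nucleus. Bound promoter states are
#' eliminated via conservation, leaving 10 species; unbinding propensities
#' use the complement occupancy (1 - free).
#'
#' @param params the 8 inferred rates: transcription \code{rho_A, rho_B},
#'   translation \code{beta_A, beta_B}, promoter binding
#'   \code{sigma_bA, sigma_bB}, unbinding \code{sigma_uA, sigma_uB}
#' @param fixed experimentally fixed rates: mRNA export \code{lambda_m},
#'   mRNA degradation \code{delta_m}, protein nuclear import
#'   \code{kappa_p}, cytoplasmic/nuclear protein degradation
#'   \code{delta_pc, delta_pn}
#' @return a \linkS4class{ReactionNetwork}; observed species are the
#'   cytoplasmic proteins \code{PcA}, \code{PcB}
#' @export
buildToggle <- function(params, fixed) {
  .checkParams(params, c("rho_A", "rho_B", "beta_A", "beta_B",
                         "sigma_bA", "sigma_bB", "sigma_uA", "sigma_uB"))
  .checkParams(fixed, c("lambda_m", "delta_m", "kappa_p", "delta_pc",
                        "delta_pn"))
  lit <- function(nm) as.character(unname(fixed[[nm]]))
  sp <- c("gA", "MnA", "McA", "PcA", "PnA",
          "gB", "MnB", "McB", "PcB", "PnB")
  gene <- function(g, other) {
    G <- paste0("g", g); Mn <- paste0("Mn", g); Mc <- paste0("Mc", g)
    Pc <- paste0("Pc", g); PnO <- paste0("Pn", other)
    Pn <- paste0("Pn", g)
    list(
      .rxn(sp, change = setNames(1, Mn), orders = setNames(1, G),
           rate = paste0("rho_", g)),
      .rxn(sp, change = setNames(c(-1, 1), c(Mn, Mc)),
           orders = setNames(1, Mn), rate = lit("lambda_m")),
      .rxn(sp, change = setNames(-1, Mc), orders = setNames(1, Mc),
           rate = lit("delta_m")),
      .rxn(sp, change = setNames(1, Pc), orders = setNames(1, Mc),
           rate = paste0("beta_", g)),
      .rxn(sp, change = setNames(c(-1, 1), c(Pc, Pn)),
           orders = setNames(1, Pc), rate = lit("kappa_p")),
      .rxn(sp, change = setNames(-1, Pc), orders = setNames(1, Pc),
           rate = lit("delta_pc")),
      .rxn(sp, change = setNames(-1, Pn), orders = setNames(1, Pn),
           rate = lit("delta_pn")),
      # repression: the *nuclear* protein of the other gene binds promoter g
      .rxn(sp, change = setNames(c(-1, -1), c(G, PnO)),
           orders = setNames(c(1, 1), c(G, PnO)),
           rate = paste0("sigma_b", g)),
      .rxn(sp, change = setNames(c(1, 1), c(G, PnO)),
           comp = setNames(1, G), rate = paste0("sigma_u", g))
    )
  }
  rxns <- c(gene("A", "B"), gene("B", "A"))
  kinds <- ifelse(sp %in% c("gA", "gB"), "promoter-state", "count")
  .makeNetwork("toggle", sp, kinds, rxns, observed = c("PcA", "PcB"),
               init = c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
               maxHints = ifelse(sp %in% c("gA", "gB"), 1, NA))
}

#' Four-state gene model of the MAPK (STL1) response
#'
#' A single gene in four states \code{G1..G4} plus its mRNA \code{M}. Gene
#' states form a nearest-neighbour chain; each state produces mRNA at its
#' own rate and mRNA degrades at rate \code{delta_m}. The G2 -> G1
#' transition has a basal component \code{k21} plus a kinase-driven
#' component \code{k21s} modulated by the time-dependent input signal. The
#' default structure has 12 free parameters (7 transition, 4 production,
#' 1 degradation). All propensities are (at most) first order, so the
#' network is linear and its moment equations are exact.
#'
#' @param params named vector with \code{k12, k21, k21s, k23, k32, k34,
#'   k43, rho1, rho2, rho3, rho4, delta_m}
#' @param signal a \linkS4class{Signal} giving the kinase concentration;
#'   only used for validation here (simulators take it separately)
#' @param structure optional data.frame with columns \code{from, to, rate,
#'   modulated} overriding the default gene-state transition graph
#' @return a \linkS4class{ReactionNetwork} with attribute
#'   \code{"freeParams"} giving the free-parameter count
#' @export
buildMapk <- function(params, signal = NULL, structure = NULL) {
  if (is.null(structure)) {
    structure <- data.frame(
      from = c(1, 2, 2, 2, 3, 3, 4),
      to   = c(2, 1, 1, 3, 2, 4, 3),
      rate = c("k12", "k21", "k21s", "k23", "k32", "k34", "k43"),
      modulated = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  }
  if (!any(structure$modulated) && !is.null(signal))
    stop("modulated edge not present in the transition structure",
         call. = FALSE)
  prod <- paste0("rho", 1:4)
  .checkParams(params, c(unique(structure$rate), prod, "delta_m"))
  sp <- c(paste0("G", 1:4), "M")
  rxns <- c(
    lapply(seq_len(nrow(structure)), function(i) {
      f <- paste0("G", structure$from[i]); t <- paste0("G", structure$to[i])
      .rxn(sp, change = setNames(c(-1, 1), c(f, t)),
           orders = setNames(1, f), rate = structure$rate[i],
           modulated = structure$modulated[i])
    }),
    lapply(1:4, function(i)
      .rxn(sp, change = c(M = 1), orders = setNames(1, paste0("G", i)),
           rate = prod[i])),
    list(.rxn(sp, change = c(M = -1), orders = c(M = 1), rate = "delta_m"))
  )
  net <- .makeNetwork("mapk", sp,
                      c(rep("promoter-state", 4), "count"), rxns,
                      observed = "M",
                      conservation = list(list(species = 1:4, total = 1)),
                      init = c(1L, 0L, 0L, 0L, 0L),
                      maxHints = c(1, 1, 1, 1, NA))
  attr(net, "freeParams") <- length(unique(c(structure$rate, prod, "delta_m")))
  net
}

#' Immigration-death (birth-death) process
#'
#' Production at constant rate \code{rho}, first-order decay at rate 1
#' (optionally with geometric bursts of mean \code{b}). The workhorse toy
#' model: its time-t distribution from an empty initial state is
#' Poisson(rho (1 - exp(-t))), and the bursty variant has stationary mean
#' rho * b.
#'
#' @param bursty if TRUE, production arrives in geometric bursts of mean b
#' @return a \linkS4class{ReactionNetwork} with single species \code{P}
#' @export
buildBirthDeath <- function(bursty = FALSE) {
  sp <- "P"
  rxns <- if (bursty) list(
    .rxn(sp, rate = "rho", burstTarget = "P", burstMean = "b"),
    .rxn(sp, change = c(P = -1), orders = c(P = 1), rate = "1"))
  else list(
    .rxn(sp, change = c(P = 1), rate = "rho"),
    .rxn(sp, change = c(P = -1), orders = c(P = 1), rate = "1"))
  .makeNetwork(if (bursty) "bursty-birth-death" else "birth-death",
               sp, "count", rxns, observed = "P", init = 0L)
}

#' Construct a time-dependent input signal
#'
#' @param times increasing time points
#' @param values nonnegative values at those times
#' @param interpolation \code{"linear"} or \code{"previous"}; outside the
#'   given range the boundary value is used
#' @param upperBound optional explicit bound (defaults to \code{max(values)});
#'   required by Extrande thinning
#' @return a \linkS4class{Signal}
#' @export
signal <- function(times, values, interpolation = c("linear", "previous"),
                   upperBound = max(values)) {
  interpolation <- match.arg(interpolation)
  new("Signal", times = as.numeric(times), values = as.numeric(values),
      interpolation = interpolation, upperBound = upperBound)
}

#' Evaluate a signal at given times
#' @param sig a \linkS4class{Signal}
#' @param t times
#' @return interpolated values (boundary values outside the range)
#' @export
signalValue <- function(sig, t) {
  n <- length(sig@times)
  vapply(t, function(ti) {
    if (ti <= sig@times[1]) return(sig@values[1])
    if (ti >= sig@times[n]) return(sig@values[n])
    i <- findInterval(ti, sig@times)
    if (sig@interpolation == "previous") return(sig@values[i])
    w <- (ti - sig@times[i]) / (sig@times[i + 1] - sig@times[i])
    sig@values[i] * (1 - w) + sig@values[i + 1] * w
  }, numeric(1))
}

.signalToCpp <- function(sig) {
  if (is.null(sig)) return(NULL)
  list(times = sig@times, values = sig@values,
       interp = if (sig@interpolation == "previous") 0L else 1L,
       upper = sig@upperBound)
}

#' Reaction propensities at a state
#'
#' Mass-action propensity \eqn{rate \prod_s x_s^{(order_s)}} (falling
#' factorials), times \eqn{(1-x_s)} complement factors for promoter-state
#' species, times the interpolated signal value for modulated reactions.
#' Pure: identical inputs give identical output.
#'
#' @param net a \linkS4class{ReactionNetwork}
#' @param state nonnegative integer state vector
#' @param t time (only used for signal-modulated reactions)
#' @param params named parameter vector
#' @param sig optional \linkS4class{Signal}
#' @return nonnegative numeric vector, one entry per reaction
#' @export
propensities <- function(net, state, t = 0, params, sig = NULL) {
  if (any(state < 0)) stop("negative state", call. = FALSE)
  rates <- .rateValues(net, params)
  R <- nrow(net@change)
  a <- numeric(R)
  for (j in seq_len(R)) {
    v <- rates[j]
    for (s in seq_along(state)) {
      o <- net@orders[j, s]
      if (o > 0) {
        for (i in seq_len(o)) v <- v * max(state[s] - i + 1, 0)
      }
      if (net@compOrders[j, s] > 0) v <- v * as.numeric(state[s] == 0)
    }
    if (net@modulated[j]) {
      if (is.null(sig)) stop("modulated reaction needs a signal", call. = FALSE)
      v <- v * signalValue(sig, t)
    }
    a[j] <- v
  }
  a
}

#' Net stoichiometry matrix
#' @param net a \linkS4class{ReactionNetwork}
#' @return integer matrix, reactions x species (burst jumps not included)
#' @export
stoichiometry <- function(net) {
  m <- net@change
  colnames(m) <- net@species
  m
}

#' Apply one reaction firing to a state
#' @param net a \linkS4class{ReactionNetwork}
#' @param state current state
#' @param j reaction index
#' @param burst burst size for burst reactions (default 0)
#' @return the new state
#' @export
applyReaction <- function(net, state, j, burst = 0L) {
  out <- state + net@change[j, ]
  tgt <- net@burstTarget[j]
  if (!is.na(tgt)) out[tgt] <- out[tgt] + burst
  if (any(out < 0)) stop("reaction would produce a negative state", call. = FALSE)
  out
}
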