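## Long-format CSV datasets with JSON metadata sidecars, signal tables,
## network/experiment configuration (JSON, or YAML when the yaml package
## is available), and chain export.

#' Write / read a dataset as long-format CSV
#'
#' Columns \code{cell, time, species, count} with mandatory header; a
#' sidecar JSON (\code{<path>.json}) stores times, species, the correlated
#' flag and optional provenance (seed, parameters). The round trip is
#' lossless.
#'
#' @param data a \linkS4class{SnapshotDataset}
#' @param path CSV path
#' @param meta optional named list merged into the sidecar metadata
#' @return \code{readDataset} returns a \linkS4class{SnapshotDataset}
#' @export
writeDataset <- function(data, path, meta = list()) {
  arr <- data@counts
  d <- dim(arr)
  df <- data.frame(
    cell = rep(seq_len(d[1]), times = d[2] * d[3]),
    time = rep(rep(data@times, each = d[1]), times = d[3]),
    species = rep(data@speciesNames, each = d[1] * d[2]),
    count = as.integer(arr))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- c(list(times = data@times, species = data@speciesNames,
                 correlated = data@correlated), meta)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  df <- read.csv(path)
  need <- c("cell", "time", "species", "count")
  if (!all(need %in% names(df)))
    stop("dataset CSV must have columns cell, time, species, count",
         call. = FALSE)
  if (any(df$count != round(df$count)) || any(df$count < 0))
    stop("counts must be nonnegative integers", call. = FALSE)
  sidePath <- paste0(path, ".json")
  side <- if (file.exists(sidePath))
    jsonlite::read_json(sidePath, simplifyVector = TRUE) else NULL
  times <- if (!is.null(side)) as.numeric(side$times) else sort(unique(df$time))
  species <- if (!is.null(side)) as.character(side$species) else unique(df$species)
  cells <- sort(unique(df$cell))
  arr <- array(0L, c(length(cells), length(times), length(species)))
  idx <- cbind(match(df$cell, cells), match(df$time, times),
               match(df$species, species))
  arr[idx] <- as.integer(df$count)
  new("SnapshotDataset", counts = arr, times = times,
      speciesNames = species,
      correlated = if (!is.null(side)) isTRUE(side$correlated) else TRUE)
}

#' Read a signal from a two-column CSV (time, value)
#'
#' @param path CSV path with columns \code{time} and \code{value}
#' @param interpolation \code{"linear"} or \code{"previous"}
#' @param upperBound optional explicit bound
#' @return a \linkS4class{Signal}
#' @export
readSignal <- function(path, interpolation = "linear", upperBound = NULL) {
  df <- read.csv(path)
  if (!all(c("time", "value") %in% names(df)))
    stop("signal CSV must have columns time, value", call. = FALSE)
  signal(df$time, df$value, interpolation,
         upperBound = upperBound %||% max(df$value))
}

#' Write a chain to CSV (one row per iteration)
#'
#' @param chain a \linkS4class{Chain}
#' @param path CSV path
#' @return the path, invisibly
#' @export
writeChainCSV <- function(chain, path) {
  df <- as.data.frame(chain@draws)
  df$loglik <- chain@logliks
  df$accepted <- chain@accepted
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# read a config file: JSON always, YAML when yaml is installed.
# simplifyVector is off so nested specs keep their list-of-lists shape
# (matching what yaml::read_yaml produces).
.readConfig <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Load a reaction network from a configuration list or file
#'
#' Built-ins are addressed by name (\code{autoreg}, \code{toggle},
#' \code{mapk}, \code{birth-death}) with their parameters supplied under
#' \code{params} (and \code{fixed} for the toggle); fully custom networks
#' list species/reactions explicitly.
#'
#' @param spec list, or path to a JSON/YAML file
#' @return a \linkS4class{ReactionNetwork}
#' @export
loadNetwork <- function(spec) {
  if (is.character(spec)) spec <- .readConfig(spec)
  params <- unlist(spec$params)
  if (!is.null(spec$builtin)) {
    return(switch(spec$builtin,
      autoreg = buildAutoreg(params),
      toggle = buildToggle(params, unlist(spec$fixed)),
      mapk = buildMapk(params),
      `birth-death` = buildBirthDeath(isTRUE(spec$bursty)),
      stop("unknown built-in network '", spec$builtin, "'", call. = FALSE)))
  }
  sp <- vapply(spec$species, function(s) s$name, character(1))
  kinds <- vapply(spec$species, function(s) s$kind %||% "count", character(1))
  rxns <- lapply(spec$reactions, function(r)
    .rxn(sp, change = unlist(r$change), orders = unlist(r$orders),
         comp = unlist(r$comp), rate = r$rate,
         burstTarget = r$burst_target %||% NA_character_,
         burstMean = r$burst_mean %||% NA_character_,
         modulated = isTRUE(r$modulated)))
  cons <- lapply(spec$conservation %||% list(), function(cl)
    list(species = match(unlist(cl$species), sp), total = cl$total))
  .makeNetwork(spec$name %||% "custom", sp, kinds, rxns,
               observed = unlist(spec$observed),
               conservation = cons,
               init = unlist(spec$init) %||% integer(length(sp)))
}

#' Run an experiment from a configuration
#'
#' Configuration keys: \code{model} (built-in name or network spec),
#' \code{params} (fixed/true model parameters for fixture generation),
#' \code{dataset} (path) or \code{fixture} (name), \code{prior}
#' (lower/upper lists), \code{method} (\code{sm}, \code{gsl}, \code{mbi},
#' \code{fsp}, \code{abc}), method options, \code{sampler} options
#' (\code{n_iter}, \code{proposal_frac}), and a mandatory \code{seed}.
#' Writes a chain CSV (or ABC rounds) plus a JSON run manifest when
#' \code{outPrefix} is given.
#'
#' @param config list or path to JSON/YAML
#' @param outPrefix optional output path prefix
#' @return list with the result (\code{chain} or \code{rounds}) and the
#'   manifest
#' @export
runExperiment <- function(config, outPrefix = NULL) {
  if (is.character(config)) config <- .readConfig(config)
  if (is.null(config$seed)) stop("config must set a seed", call. = FALSE)
  seed <- as.integer(config$seed)
  method <- match.arg(config$method, c("sm", "gsl", "mbi", "fsp", "abc"))
  if (!is.null(config$fixture)) {
    fx <- generateFixture(config$fixture, seed = .childSeed(seed, 1))
    data <- fx$data; net <- fx$network; sig <- fx$signal
    prior <- fx$prior
    theta0 <- fx$truth$params
  } else {
    net <- loadNetwork(config$model)
    data <- readDataset(config$dataset)
    sig <- if (!is.null(config$signal)) readSignal(config$signal) else NULL
    prior <- priorBox(unlist(config$prior$lower), unlist(config$prior$upper))
    theta0 <- NULL
  }
  if (!is.null(config$prior))
    prior <- priorBox(unlist(config$prior$lower), unlist(config$prior$upper))
  if (is.null(theta0)) theta0 <- (prior@lower + prior@upper) / 2
  opts <- config$options %||% list()
  result <- if (method == "abc") {
    cfg <- abcConfig(nRounds = opts$n_rounds %||% 4L,
                     nAccept = opts$n_accept %||% 100L)
    list(rounds = abcSMC(net, prior, data, cfg, seed = .childSeed(seed, 2),
                         sig = sig))
  } else {
    cfg <- switch(method,
      sm = synlikConfig(nSim = opts$n_sim %||% 10000L, K = opts$K %||% 2L,
                        mode = opts$mode %||% "hmm",
                        nRestarts = opts$restarts %||% 3L),
      gsl = gslConfig(nSim = opts$n_sim %||% 10000L,
                      mode = opts$mode %||% "joint"),
      NULL)
    fn <- makeLoglikFn(net, data, method, seed = .childSeed(seed, 3),
                       cfg = cfg, sig = sig)
    nIter <- config$sampler$n_iter %||% 5000L
    frac <- config$sampler$proposal_frac %||% 0.02
    list(chain = mhSample(fn, prior, theta0[names(prior@lower)], nIter,
                          proposalSd = frac * (prior@upper - prior@lower),
                          seed = .childSeed(seed, 4), method = method))
  }
  manifest <- list(method = method, seed = seed,
                   package_version = as.character(utils::packageVersion("nbsynlik")),
                   n_cells = nCells(data), times = data@times,
                   options = opts)
  if (!is.null(outPrefix)) {
    if (!is.null(result$chain))
      writeChainCSV(result$chain, paste0(outPrefix, "_chain.csv"))
    jsonlite::write_json(manifest, paste0(outPrefix, "_manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  c(result, list(manifest = manifest))
}
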