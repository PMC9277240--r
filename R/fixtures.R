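## Seeded fixture generator emulating the study setups: 25 cells observed
## at t = 4, 8, 12, 16 for the autoregulatory loop (negative and positive
## feedback), 100 cells at t = 1..8 for the toggle switch (two observed
## species), and independent mRNA snapshots under a step-like kinase input
## for the MAPK model. "True" parameter values are repository choices and
## are labelled source = "fixture_choice" in the truth manifest.

.fixtureSpecs <- function() {
  list(
    # slow promoter switching relative to dilution: the regime of the
    # reference experiments (bimodal protein distributions; production
    # rates of the two promoter states separately identifiable)
    autoreg_negfb = list(
      params = c(rho_u = 5, rho_b = 0, sigma_b = 0.02, sigma_u = 0.1,
                 b = 2),
      prior = priorBox(
        c(rho_u = 0, rho_b = 0, sigma_b = 0, sigma_u = 0, b = 0.5),
        c(rho_u = 10, rho_b = 10, sigma_b = 0.1, sigma_u = 0.5, b = 5)),
      times = c(4, 8, 12, 16), nCells = 25L, correlated = TRUE),
    autoreg_posfb = list(
      params = c(rho_u = 1, rho_b = 8, sigma_b = 0.02, sigma_u = 0.1,
                 b = 2),
      prior = priorBox(
        c(rho_u = 0, rho_b = 0, sigma_b = 0, sigma_u = 0, b = 0.5),
        c(rho_u = 10, rho_b = 10, sigma_b = 0.1, sigma_u = 0.5, b = 5)),
      times = c(4, 8, 12, 16), nCells = 25L, correlated = TRUE),
    toggle = list(
      params = c(rho_A = 2, rho_B = 2, beta_A = 6, beta_B = 6,
                 sigma_bA = 0.2, sigma_bB = 0.2,
                 sigma_uA = 1, sigma_uB = 1),
      fixed = c(lambda_m = 1, delta_m = 1, kappa_p = 0.5,
                delta_pc = 0.25, delta_pn = 0.25),
      prior = priorBox(
        c(rho_A = 0, rho_B = 0, beta_A = 0, beta_B = 0,
          sigma_bA = 0, sigma_bB = 0, sigma_uA = 0, sigma_uB = 0),
        c(rho_A = 8, rho_B = 8, beta_A = 12, beta_B = 12,
          sigma_bA = 1, sigma_bB = 1, sigma_uA = 4, sigma_uB = 4)),
      times = 1:8, nCells = 100L, correlated = TRUE),
    mapk_snapshots = list(
      params = c(k12 = 1, k21 = 0.5, k21s = 4, k23 = 1, k32 = 0.5,
                 k34 = 0.5, k43 = 0.5, rho1 = 0.1, rho2 = 2, rho3 = 8,
                 rho4 = 20, delta_m = 1),
      prior = priorBox(
        c(k12 = 0, k21 = 0, k21s = 0, k23 = 0, k32 = 0, k34 = 0, k43 = 0,
          rho1 = 0, rho2 = 0, rho3 = 0, rho4 = 0, delta_m = 0.2),
        c(k12 = 4, k21 = 4, k21s = 10, k23 = 4, k32 = 4, k34 = 4, k43 = 4,
          rho1 = 2, rho2 = 10, rho3 = 20, rho4 = 40, delta_m = 4)),
      signal = signal(c(0, 0.5, 1, 2, 4, 6, 8),
                      c(0, 1, 0.8, 0.5, 0.3, 0.2, 0.1), "linear",
                      upperBound = 1),
      times = c(1, 2, 3, 4, 6), nCells = 200L, correlated = FALSE)
  )
}

#' Names of the built-in fixtures
#' @return character vector
#' @export
fixtureNames <- function() names(.fixtureSpecs())

#' Generate a built-in synthetic dataset
#'
#' Simulates one of the built-in experimental setups by SSA (Extrande for
#' the MAPK snapshots) from the all-genes-unbound, zero-molecule initial
#' state. \code{autoreg_negfb} has true rho_b = 0 exactly, exercising the
#' leaky-expression identifiability question.
#'
#' @param name one of \code{fixtureNames()}
#' @param seed master seed (datasets regenerate bit-for-bit)
#' @return list with \code{data} (a \linkS4class{SnapshotDataset}),
#'   \code{network}, \code{prior}, \code{signal} (or NULL), and a
#'   \code{truth} manifest (parameters, seed, initial-state note, and
#'   \code{source = "fixture_choice"} marking the values as repository
#'   choices rather than literature estimates)
#' @export
generateFixture <- function(name, seed) {
  specs <- .fixtureSpecs()
  if (!name %in% names(specs))
    stop("unknown fixture '", name, "'; see fixtureNames()", call. = FALSE)
  sp <- specs[[name]]
  net <- switch(name,
    autoreg_negfb = , autoreg_posfb = buildAutoreg(sp$params),
    toggle = buildToggle(sp$params, sp$fixed),
    mapk_snapshots = buildMapk(sp$params))
  sig <- sp$signal
  data <- simulateDataset(net, c(sp$params, sp$fixed), obsTimes = sp$times,
                          nCells = sp$nCells, seed = seed,
                          correlated = sp$correlated, sig = sig)
  truth <- list(name = name, params = sp$params, fixed = sp$fixed,
                seed = seed, source = "fixture_choice",
                init = "all genes unbound, zero molecules",
                correlated = sp$correlated)
  list(data = data, network = net, prior = sp$prior, signal = sig,
       truth = truth)
}
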