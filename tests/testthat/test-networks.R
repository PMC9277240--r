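test_that("autoregulatory loop has the documented structure and propensities", {
  net <- buildAutoreg(autoregTruth)
  expect_s4_class(net, "ReactionNetwork")
  expect_identical(speciesNames(net), c("Gu", "Gb", "P"))
  expect_identical(net@species[net@observed], "P")
  expect_identical(net@feedback, "negative")
  pos <- buildAutoreg(c(rho_u = 1, rho_b = 8, sigma_b = 0.05, sigma_u = 1,
                        b = 2))
  expect_identical(pos@feedback, "positive")

  # binding propensity sigma_b * Gu * P: zero at P = 0, 2*1*3 = 6 otherwise
  a0 <- propensities(net, c(1, 0, 0), params = autoregTruth)
  expect_equal(a0[3], 0)
  a <- propensities(net, c(1, 0, 3),
                    params = c(autoregTruth[c("rho_u", "rho_b", "sigma_u",
                                              "b")], sigma_b = 2))
  expect_equal(a[3], 2 * 1 * 3)

  # unbinding from (Gb=1, P=5) fires at rate sigma_u and yields (Gu=1, P=6)
  ab <- propensities(net, c(0, 1, 5), params = autoregTruth)
  expect_equal(ab[4], autoregTruth[["sigma_u"]])
  expect_equal(unname(applyReaction(net, c(0, 1, 5), 4)), c(1, 0, 6))

  expect_error(buildAutoreg(autoregTruth[-1]), "missing parameter")
})

test_that("toggle switch has 10 species, 8 inferred rates, promoter conservation", {
  params <- c(rho_A = 2, rho_B = 2, beta_A = 6, beta_B = 6, sigma_bA = 0.2,
              sigma_bB = 0.2, sigma_uA = 1, sigma_uB = 1)
  fixed <- c(lambda_m = 1, delta_m = 1, kappa_p = 0.5, delta_pc = 0.25,
             delta_pn = 0.25)
  net <- buildToggle(params, fixed)
  expect_length(speciesNames(net), 10)
  inferred <- intersect(unique(net@rateParams), names(params))
  expect_length(inferred, 8)
  expect_identical(net@species[net@observed], c("PcA", "PcB"))
  expect_error(buildToggle(params[-1], fixed), "missing parameter")

  # promoter occupancy: the free-promoter slot stays in {0, 1} along SSA
  # trajectories (bound state eliminated by conservation)
  tr <- simulateSSA(net, params, obsTimes = seq(0.5, 6, by = 0.5), seed = 3)
  expect_true(all(tr$states >= 0))
  expect_true(all(tr$states[, c("gA", "gB")] %in% 0:1))
})

test_that("mapk model exposes 12 free parameters and respects its signal", {
  params <- c(k12 = 1, k21 = 0.5, k21s = 4, k23 = 1, k32 = 0.5, k34 = 0.5,
              k43 = 0.5, rho1 = 0.1, rho2 = 2, rho3 = 8, rho4 = 20,
              delta_m = 1)
  net <- buildMapk(params)
  expect_identical(attr(net, "freeParams"), 12L)
  expect_identical(net@species[net@observed], "M")

  # zero signal silences the kinase-driven transition at all times
  zsig <- signal(c(0, 10), c(0, 0), upperBound = 1)
  a <- propensities(net, c(0, 1, 0, 0, 0), t = 3, params = params,
                    sig = zsig)
  expect_equal(a[net@modulated], 0)

  # 'previous' interpolation holds the last value beyond the table
  psig <- signal(c(0, 1, 2), c(0.2, 0.8, 0.3), "previous", upperBound = 1)
  expect_equal(signalValue(psig, 99), 0.3)
  expect_equal(signalValue(psig, 1.5), 0.8)
  expect_equal(signalValue(psig, -1), 0.2)
})

test_that("propensity evaluation is pure and validates states", {
  net <- buildAutoreg(autoregTruth)
  a1 <- propensities(net, c(1, 0, 7), params = autoregTruth)
  a2 <- propensities(net, c(1, 0, 7), params = autoregTruth)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0))
  expect_error(propensities(net, c(1, 0, -1), params = autoregTruth),
               "negative state")
})

test_that("reactions preserve validity and conservation along trajectories", {
  net <- buildAutoreg(autoregTruth)
  tr <- simulateSSA(net, autoregTruth, obsTimes = seq(1, 16), seed = 12)
  expect_true(all(tr$states >= 0))
  expect_true(all(rowSums(tr$states[, c("Gu", "Gb")]) == 1))

  params <- c(k12 = 1, k21 = 0.5, k21s = 4, k23 = 1, k32 = 0.5, k34 = 0.5,
              k43 = 0.5, rho1 = 0.1, rho2 = 2, rho3 = 8, rho4 = 20,
              delta_m = 1)
  mnet <- buildMapk(params)
  sig <- signal(c(0, 4), c(1, 0.2), upperBound = 1)
  tr2 <- simulateExtrande(mnet, params, obsTimes = seq(0.5, 4, 0.5),
                          sig = sig, seed = 5)
  expect_true(all(rowSums(tr2$states[, 1:4]) == 1))
})
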