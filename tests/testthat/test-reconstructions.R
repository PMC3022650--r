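# The curated species cores: validation, balances, and the hand-derived
# fermentation stoichiometries.

test_that("both core models validate with zero violations, charges included", {
  expect_length(validateModel(pcarDefault, checkCharge = TRUE), 0)
  expect_length(validateModel(pproDefault, checkCharge = TRUE), 0)
})

test_that("every internal reaction is elementally balanced for CHONS/Fe", {
  for (m in list(pcarDefault, pproDefault)) {
    exch <- exchangeReactions(m)
    exempt <- c(exch, biomassReaction(m), atpmReaction(m))
    comp <- lapply(metabolites(m)$formula, parseFormula)
    names(comp) <- metabolites(m)$id
    for (j in seq_len(nrow(reactions(m)))) {
      rid <- reactions(m)$id[j]
      if (rid %in% exempt) next
      st <- m@S[, j]
      part <- names(st)[st != 0]
      bal <- numeric(0)
      for (p in part) {
        f <- comp[[p]] * st[[p]]
        bal <- c(bal, f)
      }
      tot <- tapply(bal, names(bal), sum)
      expect_true(all(abs(tot) < 1e-9),
                  info = paste("unbalanced:", rid))
    }
  }
})

test_that("acetoin ferments to acetate + ethanol 1:1 with 1 ATP/acetoin", {
  m0 <- buildPcarCore(energyParams(ngam = 0))
  cond <- fermCondition(m0, atpmReaction(m0),
                        uptakeLimits = c(actn_e = 5),
                        fixedFluxes = c(BIOMASS = 0))
  sol <- maxATP(m0, condition = cond, keepGAM = TRUE)
  expect_equal(objectiveValue(sol), 5, tolerance = 1e-8)
  fx <- fluxes(sol)
  expect_equal(unname(fx["EX_ac_e"]), 5, tolerance = 1e-8)
  expect_equal(unname(fx["EX_etoh_e"]), 5, tolerance = 1e-8)
})

test_that("butanediol with H2 venting gives 2 acetate + 3 H2 + 2 ATP", {
  m0 <- buildPcarCore(energyParams(ngam = 0))
  cond <- makeCondition(atpmReaction(m0), uptakeLimits = c(btd_e = 5),
                        fixedFluxes = c(BIOMASS = 0))
  sol <- maxATP(m0, condition = cond, keepGAM = TRUE)
  expect_equal(objectiveValue(sol), 10, tolerance = 1e-8)
  fx <- fluxes(sol)
  expect_equal(unname(fx["EX_ac_e"]), 10, tolerance = 1e-8)
  expect_equal(unname(fx["EX_h2_e"]), 15, tolerance = 1e-8)
  expect_equal(unname(fx["EX_etoh_e"]), 0, tolerance = 1e-8)
})

test_that("acetate cannot be oxidised to CO2 with elemental sulfur", {
  # quinol from succinate oxidation has no route to S0, so the full TCA
  # cycle cannot turn and no net CO2 leaves on acetate + S0
  m0 <- buildPcarCore(energyParams(ngam = 0))
  cond <- makeCondition("EX_co2_e",
                        uptakeLimits = c(ac_e = 10, s0_e = 1000),
                        closeReactions = c("EX_h2_e", "EX_for_e"),
                        freeExchanges = setdiff(FREE_EXCHANGE_METS, "co2_e"),
                        fixedFluxes = c(BIOMASS = 0))
  sol <- solveFBA(m0, cond)
  expect_identical(solverStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 0, tolerance = 1e-7)
  # and with the maintenance requirement in place growth is impossible
  sc <- scenario("acetate + S0", "pcar", c(ac_e = 10), acceptor = "s0",
                 objectiveMode = "max-biomass")
  r <- runScenario(sc)
  expect_identical(solverStatus(r$solution), "infeasible")
})

test_that("P. propionicus ferments ethanol and lactate to acetate:propionate 1:2", {
  m0 <- buildPproCore(energyParams(ngam = 0))
  for (sub in c("etoh_e", "lac_e")) {
    cond <- fermCondition(m0, atpmReaction(m0),
                          uptakeLimits = stats::setNames(10, sub),
                          fixedFluxes = c(BIOMASS = 0))
    sol <- maxATP(m0, condition = cond, keepGAM = TRUE)
    fx <- fluxes(sol)
    expect_equal(unname(fx["EX_ppa_e"] / fx["EX_ac_e"]), 2,
                 tolerance = 1e-6, label = sub)
  }
})

test_that("propanol and butanol fermentation consume acetate", {
  for (nm in c("ppro_ppoh_ferm", "ppro_btoh_ferm")) {
    r <- runScenario(paperScenarios()[[nm]], epPpro, calibBS)
    expect_identical(solverStatus(r$solution), "optimal")
    expect_lt(r$ratios[["ac"]], 0)      # acetate consumed
    expect_gt(r$ratios[["ppa"]], 0)     # propionate produced
  }
})

test_that("Fe(III) shifts butanediol fermentation toward acetate", {
  rNo <- runScenario(paperScenarios()$pcar_btd_ferm, bs = calibBS)
  rFe <- runScenario(paperScenarios()$pcar_btd_fe3, bs = calibBS)
  expect_gt(rFe$ratios[["ac"]], rNo$ratios[["ac"]] + 1e-6)
  expect_lt(rFe$ratios[["etoh"]], rNo$ratios[["etoh"]] - 1e-6)
  expect_gt(rFe$ratios[["fe2"]], 0)
})

test_that("Fe(III) reduction runs only through the sulfide shuttle", {
  for (del in list("FE3Rs", c("SRE", "SRE2"))) {
    m <- setBounds(buildPcarCore(bs = calibBS), del, lower = 0, upper = 0)
    r <- runScenario(paperScenarios()$pcar_btd_fe3, bs = calibBS, model = m)
    fe2 <- if (solverStatus(r$solution) == "optimal") r$ratios[["fe2"]] else 0
    expect_equal(unname(fe2), 0, tolerance = 1e-8)
  }
})

test_that("carrier pools are redox-closed in every optimal solution", {
  cond <- fermCondition(pcarDefault, uptakeLimits = c(actn_e = 10),
                        fixedFluxes = c(BIOMASS = 0.05))
  sol <- solveFBA(pcarDefault, fermCondition(pcarDefault,
                                             uptakeLimits = c(actn_e = 10)))
  v <- fluxes(sol)
  for (row in c("nad", "nadh", "nadp", "nadph")) {
    expect_lt(abs(sum(pcarDefault@S[row, ] * v)), 1e-7)
  }
})

test_that("biomass coefficient perturbations move growth by at most 15%", {
  s <- scenario("acetoin growth", "pcar", c(actn_e = 10),
                objectiveMode = "max-biomass")
  sens <- biomassSensitivity(s, 0.1, bs = calibBS)
  expect_lte(sens$maxRelChange, 0.15)
})

test_that("biomass calibration is a fixed point on self-generated targets", {
  bs0 <- biomassSpec()
  r <- runScenario(paperScenarios()$pcar_btd_h2, bs = bs0)
  tg <- list(scenario = paperScenarios()$pcar_btd_h2,
             numerator = "EX_ac_e", denominator = "EX_btd_e",
             observed = unname(r$ratios[["ac"]]))
  out <- calibrateBiomass(list(tg), bs = bs0, free = "accoa")
  expect_equal(out@accoa, bs0@accoa, tolerance = 1e-3)
})

test_that("a single ratio target is matched within grid resolution", {
  expect_equal(attr(calibBS, "objective"), 0, tolerance = 1e-6)
  r <- runScenario(paperScenarios()$pcar_btd_h2, bs = calibBS)
  expect_equal(unname(r$ratios[["ac"]]), 1.80, tolerance = 1e-3)
})

test_that("an empty free set returns the input unchanged", {
  bs0 <- biomassSpec(accoa = 17)
  tg <- list(scenario = paperScenarios()$pcar_btd_h2,
             numerator = "EX_ac_e", denominator = "EX_btd_e",
             observed = 1.8)
  out <- calibrateBiomass(list(tg), bs = bs0, free = character(0))
  expect_identical(out, bs0)
})
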