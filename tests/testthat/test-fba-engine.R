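# The published objective modes and the gap (producibility) analysis.

test_that("no substrate means no growth once maintenance is positive", {
  sol <- solveFBA(pcarDefault, makeCondition(biomassReaction(pcarDefault)))
  expect_identical(solverStatus(sol), "infeasible")
  # with nGAM = 0 the model idles at zero growth instead
  m0 <- buildPcarCore(energyParams(ngam = 0))
  sol0 <- solveFBA(m0, makeCondition(biomassReaction(m0)))
  expect_identical(solverStatus(sol0), "optimal")
  expect_equal(objectiveValue(sol0), 0, tolerance = 1e-9)
})

test_that("optimal growth on acetoin secretes acetate and ethanol", {
  sol <- optimalGrowth(pcarDefault, "actn_e", 5,
                       condition = fermCondition(pcarDefault))
  expect_identical(solverStatus(sol), "optimal")
  expect_gt(objectiveValue(sol), 0)
  fx <- fluxes(sol)
  expect_gt(fx[["EX_ac_e"]], 0)
  expect_gt(fx[["EX_etoh_e"]], 0)
})

test_that("growth needs the maintenance floor and is monotone in uptake", {
  expect_identical(solverStatus(optimalGrowth(pcarDefault, "actn_e", 0.2)),
                   "infeasible")
  g1 <- objectiveValue(optimalGrowth(pcarDefault, "actn_e", 2))
  g2 <- objectiveValue(optimalGrowth(pcarDefault, "actn_e", 4))
  expect_gt(g1, 0)
  expect_gt(g2, g1 + 1e-6)
})

test_that("minimal uptake covers exactly the maintenance ATP at zero growth", {
  m0 <- buildPcarCore(energyParams(ngam = 0))
  s0 <- minSubstrateAtGrowth(m0, "actn_e", 0, condition = fermCondition(m0))
  expect_equal(unname(fluxes(s0)[["EX_actn_e"]]), 0, tolerance = 1e-9)
  # acetoin catabolism nets 1 ATP per acetoin, so nGAM = 0.844 demands
  # exactly 0.844 mmol acetoin/gdw/h
  s1 <- minSubstrateAtGrowth(pcarDefault, "actn_e", 0,
                             condition = fermCondition(pcarDefault))
  expect_equal(unname(fluxes(s1)[["EX_actn_e"]]), -0.844, tolerance = 1e-8)
})

test_that("min-uptake and max-growth are mutually consistent", {
  for (sub in c("actn_e", "btd_e")) {
    mu <- 0.05
    s <- minSubstrateAtGrowth(pcarDefault, sub, mu)
    u <- -fluxes(s)[[paste0("EX_", sub)]]
    g <- optimalGrowth(pcarDefault, sub, u)
    expect_gte(objectiveValue(g), mu - 1e-6)
  }
})

test_that("fixed-growth syntrophic butanediol growth has finite uptake", {
  sol <- minSubstrateAtGrowth(pcarDefault, "btd_e", 0.087)
  expect_identical(solverStatus(sol), "optimal")
  u <- -fluxes(sol)[["EX_btd_e"]]
  expect_gt(u, 0)
  expect_lt(u, 100)
})

test_that("maximal ATP flux follows the hand stoichiometry oracle", {
  # 1 ATP per acetoin through the acetate branch at zero growth
  m0 <- buildPcarCore(energyParams(ngam = 0))
  cond <- fermCondition(m0, atpmReaction(m0))
  sol <- maxATP(m0, fixed = c(EX_actn_e = -5, EX_ac_e = 5), mu = 0,
                condition = cond)
  expect_equal(objectiveValue(sol), 5, tolerance = 1e-8)
  # everything fixed to zero: no ATP
  sol0 <- maxATP(m0, fixed = c(EX_actn_e = 0, EX_ac_e = 0, EX_etoh_e = 0),
                 mu = 0, condition = cond)
  expect_equal(objectiveValue(sol0), 0, tolerance = 1e-9)
})

test_that("maximal ATP is nonincreasing in growth and increasing in uptake", {
  q <- vapply(c(0, 0.05, 0.1), function(mm) {
    objectiveValue(maxATP(pcarDefault, fixed = c(EX_actn_e = -5), mu = mm))
  }, numeric(1))
  expect_true(all(diff(q) < 1e-9))
  expect_true(all(q >= 0))
  q2 <- vapply(c(2, 4, 6), function(u) {
    objectiveValue(maxATP(pcarDefault, fixed = c(EX_actn_e = -u), mu = 0.05))
  }, numeric(1))
  expect_true(all(diff(q2) > 1e-9))
})

test_that("fixed fluxes outside a reaction's bounds are rejected", {
  expect_error(
    solveFBA(pcarDefault,
             makeCondition(biomassReaction(pcarDefault),
                           fixedFluxes = c(EX_actn_e = -2000))),
    "outside")
})

test_that("all biomass precursors are producible on acetoin medium", {
  cond <- makeCondition("BIOMASS", uptakeLimits = c(actn_e = 10))
  rep <- biomassProducibility(pcarDefault, cond)
  expect_true(all(rep$producible))
})

test_that("deleting the acetyl-CoA supply blocks its derived precursors", {
  m <- setBounds(pcarDefault, c("ACTNOR", "ACALD"), lower = 0, upper = 0)
  cond <- makeCondition("BIOMASS", uptakeLimits = c(actn_e = 10))
  rep <- biomassProducibility(m, cond)
  expect_false(rep$producible[rep$precursor == "accoa"])
})

test_that("an empty medium blocks every carbon precursor", {
  rep <- biomassProducibility(pcarDefault, makeCondition("BIOMASS"))
  expect_false(rep$producible[rep$precursor == "accoa"])
  expect_false(rep$producible[rep$precursor == "atp"])
  expect_false(rep$producible[rep$precursor == "nadph"])
})
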