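# The named validation scenarios and the suite report.

test_that("acetoin fermentation ratios are near one minus biomass diversion", {
  r <- runScenario(paperScenarios()$pcar_actn_ferm, bs = calibBS)
  expect_identical(solverStatus(r$solution), "optimal")
  expect_gt(r$ratios[["ac"]], 0.75)
  expect_lt(r$ratios[["ac"]], 1)
  expect_gt(r$ratios[["etoh"]], 0.75)
  expect_lt(r$ratios[["etoh"]], 1.05)
})

test_that("the zero-growth limit reproduces pure catabolic stoichiometry", {
  # at mu = 0 only the maintenance ATP drives flux, so the exchange ratios
  # collapse to the catabolic stoichiometry: acetoin -> acetate + ethanol
  s <- paperScenarios()$pcar_actn_ferm
  s@mu <- 0
  r <- runScenario(s, energyParams(), calibBS)
  expect_equal(unname(r$uptake), 0.844, tolerance = 1e-6)
  expect_equal(unname(r$ratios[["ac"]]), 1, tolerance = 1e-6)
  expect_equal(unname(r$ratios[["etoh"]]), 1, tolerance = 1e-6)
})

test_that("the validation suite reports the printed quantities", {
  rep <- validationSuite(bs = calibBS, tolerance = 0.1)
  expect_identical(nrow(rep), 7L)
  expect_true(all(is.finite(rep$simulated)))
  # the P. carbinolicus rows reproduce the printed values within 10%
  pcarRows <- grepl("^pcar", rep$scenario)
  expect_true(all(rep$pass[pcarRows]))
  # with infinite tolerance every row passes
  repInf <- validationSuite(bs = calibBS, tolerance = Inf)
  expect_true(all(repInf$pass))
})

test_that("propionate dominates P. propionicus fermentations at growth", {
  for (nm in c("ppro_etoh_ferm", "ppro_lac_ferm")) {
    r <- runScenario(paperScenarios()[[nm]], epPpro, calibBS)
    ratio <- r$ratios[["ppa"]] / r$ratios[["ac"]]
    expect_gt(ratio, 1.5)
    expect_lt(ratio, 3.5)
  }
})

test_that("fermentation yields rank acetoin > butanediol ~ lactate > alcohols", {
  sc <- paperScenarios()
  y <- vapply(c("ppro_actn_ferm", "ppro_btd_ferm", "ppro_lac_ferm",
                "ppro_etoh_ferm", "ppro_ppoh_ferm", "ppro_btoh_ferm"),
              function(nm) runScenario(sc[[nm]], epPpro, calibBS)$yield,
              numeric(1))
  expect_gt(y[["ppro_actn_ferm"]], y[["ppro_btd_ferm"]])
  expect_gt(y[["ppro_btd_ferm"]], y[["ppro_etoh_ferm"]])
  expect_gt(y[["ppro_lac_ferm"]], y[["ppro_etoh_ferm"]])
  expect_gt(y[["ppro_lac_ferm"]], y[["ppro_ppoh_ferm"]])
  # butanediol and lactate yields are of the same order
  expect_lt(abs(y[["ppro_btd_ferm"]] / y[["ppro_lac_ferm"]] - 1), 0.5)
})

test_that("acetoin yields twice the biomass per mole of butanediol", {
  sc <- paperScenarios()
  ya <- runScenario(sc$pcar_actn_ferm, bs = calibBS)$yield
  yb <- runScenario(sc$pcar_btd_ferm, bs = calibBS)$yield
  expect_equal(ya / yb, 2, tolerance = 0.1)
})

test_that("the lactate antiporter outperforms both alternative transporters", {
  ys <- vapply(c("antiport", "symport", "diffusion"), function(v) {
    runScenario(paperScenarios()$ppro_lac_ferm, epPpro, calibBS,
                lactateTransport = v)$yield
  }, numeric(1))
  expect_gt(ys[["antiport"]], ys[["symport"]])
  expect_gt(ys[["antiport"]], ys[["diffusion"]])
  # the alternatives fall well short, as in the published comparison
  expect_lt(ys[["symport"]] / ys[["antiport"]], 0.8)
  expect_lt(ys[["diffusion"]] / ys[["antiport"]], 0.8)
})

test_that("sensitivity is zero at zero perturbation and GAM acts inversely", {
  s <- scenario("acetoin growth", "pcar", c(actn_e = 10),
                objectiveMode = "max-biomass")
  sens0 <- biomassSensitivity(s, 0, bs = calibBS)
  expect_equal(sens0$maxRelChange, 0, tolerance = 1e-9)
  sens <- biomassSensitivity(s, 0.1, bs = calibBS)
  tab <- sens$table
  gamUp <- tab$relChange[tab$coefficient == "gam" & tab$direction == 1]
  gamDn <- tab$relChange[tab$coefficient == "gam" & tab$direction == -1]
  expect_lt(gamUp, 0)
  expect_gt(gamDn, 0)
})
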