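# Maintenance regression, yield-based nGAM estimation, and the sulfur-
# reductase stoichiometry scan.

test_that("the maintenance regression recovers GAM and nGAM exactly", {
  obs <- genChemostatObs(pcarDefault, generatorConfig(seed = 11))
  fit <- fitMaintenance(pcarDefault, obs)
  expect_equal(fit@gam, 97.5, tolerance = 1e-6)
  expect_equal(fit@ngam, 0.844, tolerance = 1e-6)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  expect_identical(nrow(fit@points), 4L)
})

test_that("identical qATP at different dilution rates gives slope zero", {
  # acetate chosen so qATP comes out constant: the NADPH-proton correction
  # scales as (nadph coefficient) * mu / 3
  bn <- biomassSpec()@nadph
  mus <- c(0.03, 0.06)
  obs <- data.frame(mu = mus,
                    EX_actn_e = -8,
                    EX_ac_e = 5 + bn * mus / 3)
  fit <- fitMaintenance(pcarDefault, obs)
  expect_equal(fit@gam, 0, tolerance = 1e-6)
  expect_equal(fit@ngam, 5, tolerance = 1e-6)
})

test_that("an observation violating mass balance raises a named error", {
  obs <- data.frame(mu = c(0.03, 0.04),
                    EX_actn_e = c(5, -5),   # first row secretes substrate
                    EX_ac_e = c(3, 4))
  expect_error(fitMaintenance(pcarDefault, obs), "observation 1")
  expect_error(fitMaintenance(pcarDefault,
                              data.frame(mu = c(0.03, 0.03),
                                         EX_actn_e = -5, EX_ac_e = 4)),
               "singular")
})

test_that("noisy observations still give nearly unbiased estimates", {
  nrep <- 200
  gams <- numeric(nrep)
  ngams <- numeric(nrep)
  for (s in seq_len(nrep)) {
    obs <- genChemostatObs(pcarDefault,
                           generatorConfig(seed = s, noiseSd = 0.05))
    f <- fitMaintenance(pcarDefault, obs)
    gams[s] <- f@gam
    ngams[s] <- f@ngam
  }
  expect_lt(abs(mean(gams) - 97.5), 3 * stats::sd(gams) / sqrt(nrep))
  expect_lt(abs(mean(ngams) - 0.844), 3 * stats::sd(ngams) / sqrt(nrep))
})

test_that("the yield-based estimator recovers the embedded nGAM", {
  yr <- genYieldRecords(pproDefault, c("btd_e", "actn_e", "lac_e"),
                        mu = 0.144)
  est <- estimateNgamFromYields(pproDefault, yr)
  expect_equal(as.numeric(est), 2.80, tolerance = 1e-6)
  expect_length(attr(est, "perRecord"), 3)
  # a single record is its own mean
  est1 <- estimateNgamFromYields(pproDefault, yr[1, ])
  expect_equal(as.numeric(est1), 2.80, tolerance = 1e-6)
})

test_that("a yield above the thermodynamic maximum is an error", {
  yr <- genYieldRecords(pproDefault, "btd_e", mu = 0.144)
  yr$yield <- yr$yield * 10
  expect_error(estimateNgamFromYields(pproDefault, yr), "record 1")
})

test_that("the 2x2 scan recovers the generating stoichiometry (2, 1)", {
  rEth <- runScenario(paperScenarios()$pcar_etoh_fe3, bs = calibBS)
  rH2 <- runScenario(paperScenarios()$pcar_h2_fe3, bs = calibBS)
  target <- rEth$yield / rH2$yield
  sc <- scanSreStoichiometry(target, bs = calibBS)
  expect_identical(as.numeric(sc$selected$sre), 2)
  expect_identical(as.numeric(sc$selected$sre2), 1)
  expect_false(sc$tie)
  expect_equal(min(sc$table$residual), 0, tolerance = 1e-6)
  # monotonicity: raising the SRE ratio raises the hydrogen-scenario yield
  # and lowers the ethanol:hydrogen ratio
  tab <- sc$table
  for (s2 in c(1, 2)) {
    y1 <- tab$yieldHydrogen[tab$sre == 1 & tab$sre2 == s2]
    y2 <- tab$yieldHydrogen[tab$sre == 2 & tab$sre2 == s2]
    expect_gt(y2, y1)
    expect_lt(tab$ratio[tab$sre == 2 & tab$sre2 == s2],
              tab$ratio[tab$sre == 1 & tab$sre2 == s2])
  }
})

test_that("scan ties are reported deterministically with a flag", {
  grid <- data.frame(sre = c(2, 1, 1), sre2 = c(1, 1, 1))
  rEth <- runScenario(paperScenarios()$pcar_etoh_fe3, bs = calibBS)
  rH2 <- runScenario(paperScenarios()$pcar_h2_fe3, bs = calibBS)
  # duplicate cells tie exactly; ordering is sre ascending then sre2
  sc <- scanSreStoichiometry(rEth$yield / rH2$yield * 2, bs = calibBS,
                             grid = grid)
  expect_identical(nrow(sc$table), 3L)
  expect_true(sc$tie)
  expect_identical(as.numeric(sc$selected$sre), 1)
})
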